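#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.crosstalk_model <- function(x, ...) {
  s <- suppressWarnings(summary(x$fit))$coefficients
  tibble::tibble(term = c("intercept", "rho"),
                 estimate = c(x$intercept, x$rho),
                 std.error = unname(s[, "Std. Error"]),
                 statistic = unname(s[, "t value"]),
                 p.value = unname(s[, "Pr(>|t|)"]))
}

#' @export
glance.crosstalk_model <- function(x, ...) {
  tibble::tibble(rho = x$rho, intercept = x$intercept,
                 residual_sd = x$residual_sd, n = x$n_points,
                 r.squared = suppressWarnings(summary(x$fit))$r.squared)
}

#' @export
tidy.sigmoid_fit <- function(x, ...) {
  tibble::tibble(term = c("lower", "upper", "t50", "slope"),
                 estimate = c(x$lower, x$upper, x$t50, x$slope))
}

#' @export
glance.sigmoid_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, degenerate = x$degenerate)
}

#' @export
tidy.commitment_boundary <- function(x, ...) {
  tibble::tibble(term = "boundary", estimate = x$boundary,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @export
glance.commitment_boundary <- function(x, ...) {
  tibble::tibble(boundary = x$boundary, conf.low = x$ci[1],
                 conf.high = x$ci[2], n = x$n, separation = x$separation)
}

#' @export
tidy.threshold_model <- function(x, ...) {
  tibble::tibble(term = "threshold", estimate = x$threshold,
                 method = x$method, fallback = x$fallback)
}
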