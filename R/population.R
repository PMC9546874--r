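#' Fit a classification threshold to a 1D sample
#'
#' `otsu` maximizes the inter-class variance on a 256-bin histogram; `gmm2`
#' fits a two-component Gaussian mixture and takes the equal-posterior
#' crossing between the component means (falling back to Otsu, flagged, when
#' the mixture fit degenerates); `manual` passes `value` through.
#'
#' @param values Numeric sample (n >= 10 for the automatic methods).
#' @param method One of `"otsu"`, `"gmm2"`, `"manual"`.
#' @param value Threshold for `method = "manual"`.
#' @return An object of class `threshold_model`: `threshold`, `method`,
#'   `fallback` flag, and mixture `components` when fitted.
#' @export
fit_threshold <- function(values, method = c("otsu", "gmm2", "manual"),
                          value = NULL) {
  method <- match.arg(method)
  if (method == "manual") {
    stopifnot(is.numeric(value), length(value) == 1)
    return(structure(list(threshold = value, method = "manual",
                          fallback = FALSE, components = NULL),
                     class = "threshold_model"))
  }
  values <- values[is.finite(values)]
  if (length(values) < 10)
    stop("need at least 10 values to fit a threshold", call. = FALSE)
  if (diff(range(values)) == 0)
    stop("cannot threshold a constant sample", call. = FALSE)
  if (method == "otsu") {
    return(structure(list(threshold = otsu_threshold(values),
                          method = "otsu", fallback = FALSE,
                          components = NULL),
                     class = "threshold_model"))
  }
  fit <- tryCatch(
    Mclust(values, G = 2, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  ok <- !is.null(fit) && length(unique(fit$parameters$mean)) == 2
  if (ok) {
    mu <- fit$parameters$mean
    sd_ <- sqrt(fit$parameters$variance$sigmasq)
    if (length(sd_) == 1) sd_ <- rep(sd_, 2)
    w <- fit$parameters$pro
    o <- order(mu)
    mu <- mu[o]; sd_ <- sd_[o]; w <- w[o]
    g <- function(x) w[1] * stats::dnorm(x, mu[1], sd_[1]) -
      w[2] * stats::dnorm(x, mu[2], sd_[2])
    thr <- tryCatch(stats::uniroot(g, c(mu[1], mu[2]))$root,
                    error = function(e) NA_real_)
    if (is.finite(thr)) {
      return(structure(list(
        threshold = thr, method = "gmm2", fallback = FALSE,
        components = tibble::tibble(mean = mu, sd = sd_, weight = w)),
        class = "threshold_model"))
    }
  }
  structure(list(threshold = otsu_threshold(values), method = "gmm2",
                 fallback = TRUE, components = NULL),
            class = "threshold_model")
}

#' @export
print.threshold_model <- function(x, ...) {
  cat(sprintf("<threshold_model> %s threshold = %.4f%s\n", x$method,
              x$threshold, if (x$fallback) " (otsu fallback)" else ""))
  invisible(x)
}

#' Percentage of threshold-positive cells per timepoint
#'
#' @param samples Data frame with columns `t` and `value` (one row per
#'   cell per timepoint).
#' @param model A `threshold_model` (or bare numeric threshold).
#' @param polarity `"above"` counts values at or above the threshold as
#'   positive (active kinases, degron-high cells); `"below"` counts values
#'   below it (e.g. "inactive" readouts scored low).
#' @return Tibble `t`, `n`, `percent`.
#' @export
fraction_positive_timecourse <- function(samples, model,
                                         polarity = c("above", "below")) {
  polarity <- match.arg(polarity)
  thr <- if (inherits(model, "threshold_model")) model$threshold else
    as.numeric(model)
  df <- tibble::as_tibble(samples)
  stopifnot(all(c("t", "value") %in% names(df)))
  empty <- df |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(n = sum(is.finite(.data$value)), .groups = "drop")
  if (any(empty$n == 0))
    warning("omitting timepoint(s) with no finite values: ",
            paste(empty$t[empty$n == 0], collapse = ", "), call. = FALSE)
  df |>
    dplyr::filter(is.finite(.data$value)) |>
    dplyr::group_by(.data$t) |>
    dplyr::summarise(
      n = dplyr::n(),
      percent = 100 * mean(if (polarity == "above") .data$value >= thr
                           else .data$value < thr),
      .groups = "drop")
}

#' Fit a four-parameter sigmoid to a time course
#'
#' Least squares fit of
#' `lower + (upper - lower) / (1 + exp(-slope * (t - t50)))` with
#' multi-start over `t50` (best residual sum of squares kept).
#' Deterministic given the data. A fit with `upper ~ lower` is flagged
#' degenerate.
#'
#' @param t Times (h).
#' @param p Responses (e.g. percentages), same length, n >= 4.
#' @return An object of class `sigmoid_fit`: `lower`, `upper`, `t50`,
#'   `slope`, `rss`, `degenerate`, `fit`.
#' @export
fit_sigmoid <- function(t, p) {
  stopifnot(length(t) == length(p), length(t) >= 4)
  df <- tibble::tibble(t = t, p = p)
  starts <- unique(stats::quantile(t, c(0.2, 0.35, 0.5, 0.65, 0.8),
                                   names = FALSE))
  rng <- diff(range(p))
  best <- NULL
  for (t50_0 in starts) {
    for (sl0 in c(0.5, 1, 2)) {
      fit <- tryCatch(
        minpack.lm::nlsLM(
          p ~ lower + (upper - lower) / (1 + exp(-slope * (t - t50))),
          data = df,
          start = list(lower = min(p), upper = max(p), t50 = t50_0,
                       slope = sl0),
          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        rss <- sum(stats::residuals(fit)^2)
        if (is.null(best) || rss < best$rss - 1e-12) best <- list(fit = fit,
                                                                  rss = rss)
      }
    }
  }
  if (is.null(best)) {
    if (stats::sd(p) < max(1e-10, 1e-6 * abs(mean(p)))) {
      # flat response: degenerate constant fit
      return(structure(list(lower = mean(p), upper = mean(p), t50 = NA_real_,
                            slope = 0, rss = sum((p - mean(p))^2),
                            degenerate = TRUE, fit = NULL),
                       class = "sigmoid_fit"))
    }
    stop("sigmoid fit failed to converge from every start", call. = FALSE)
  }
  co <- as.list(stats::coef(best$fit))
  if (co$upper < co$lower) {  # canonical orientation: report lower <= upper
    co <- list(lower = co$upper, upper = co$lower, t50 = co$t50,
               slope = -co$slope)
  }
  degenerate <- abs(co$upper - co$lower) < max(1e-8, 0.02 * max(rng, 1e-12))
  structure(list(lower = co$lower, upper = co$upper, t50 = co$t50,
                 slope = co$slope, rss = best$rss, degenerate = degenerate,
                 fit = best$fit),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "<sigmoid_fit> lower %.3f upper %.3f t50 %.3f h slope %.3f /h rss %.3g%s\n",
    x$lower, x$upper, x$t50, x$slope, x$rss,
    if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Binned CDK4/6 x CDK2 activity map
#'
#' 2D histogram of per-cell CDK4/6 (x) and CDK2 (y) activities; each bin
#' carries its count and a summary of `marker`: `100 * mean` for a logical
#' or 0/1 marker (a percentage), the mean for a numeric marker. Bins with
#' fewer than `min_n` cells are masked (`NA` statistic).
#'
#' @param x,y Per-cell activities.
#' @param marker Per-cell logical/numeric marker.
#' @param bins Number of bins per axis.
#' @param limits Length-2 range applied to both axes; points outside are
#'   dropped.
#' @param min_n Minimum cells per reported bin.
#' @return A tibble of class `activity_map`: `x_lo`, `x_hi`, `y_lo`,
#'   `y_hi`, `n`, `stat`, with attributes `breaks_x`, `breaks_y`,
#'   `stat_type`, `n_dropped`.
#' @export
activity_map <- function(x, y, marker, bins = 30, limits = c(0, 2.5),
                         min_n = 5) {
  stopifnot(length(x) == length(y), length(x) == length(marker))
  binary <- is.logical(marker) || all(marker %in% c(0, 1, NA))
  keep <- is.finite(x) & is.finite(y) &
    x >= limits[1] & x <= limits[2] & y >= limits[1] & y <= limits[2]
  n_dropped <- sum(!keep)
  br <- seq(limits[1], limits[2], length.out = bins + 1)
  if (!any(keep)) {
    out <- tibble::tibble(x_lo = numeric(), x_hi = numeric(),
                          y_lo = numeric(), y_hi = numeric(),
                          n = integer(), stat = numeric())
  } else {
    bx <- pmin(findInterval(x[keep], br, rightmost.closed = TRUE), bins)
    by <- pmin(findInterval(y[keep], br, rightmost.closed = TRUE), bins)
    mk <- as.numeric(marker[keep])
    out <- tibble::tibble(bx = bx, by = by, mk = mk) |>
      dplyr::group_by(.data$bx, .data$by) |>
      dplyr::summarise(n = dplyr::n(),
                       stat = mean(.data$mk, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(
        stat = ifelse(.data$n < min_n, NA_real_,
                      if (binary) 100 * .data$stat else .data$stat),
        x_lo = br[.data$bx], x_hi = br[.data$bx + 1],
        y_lo = br[.data$by], y_hi = br[.data$by + 1]) |>
      dplyr::select("x_lo", "x_hi", "y_lo", "y_hi", "n", "stat")
  }
  attr(out, "breaks_x") <- br
  attr(out, "breaks_y") <- br
  attr(out, "stat_type") <- if (binary) "percent" else "mean"
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("activity_map", class(out))
  out
}

#' Gate cell-cycle phases from Hoechst and EdU
#'
#' S-phase cells are EdU-positive (above the EdU threshold). Among
#' EdU-negative cells, the Hoechst (DNA content) distribution is split into
#' 2N and 4N bands by a two-component Gaussian mixture (or a manual
#' boundary): G0/G1 below the crossing, G2/M above.
#'
#' @param hoechst Per-cell total Hoechst intensity.
#' @param edu Per-cell mean EdU intensity.
#' @param edu_threshold Threshold for EdU positivity; `NULL` fits a
#'   two-component mixture to `edu` ([fit_threshold()] with `gmm2`).
#' @param hoechst_boundary Manual 2N/4N boundary; `NULL` fits a mixture to
#'   EdU-negative Hoechst values.
#' @return Tibble `hoechst`, `edu`, `phase` (`"G0/G1"`, `"S"`, `"G2/M"`);
#'   thresholds attached as attributes.
#' @export
gate_phases <- function(hoechst, edu, edu_threshold = NULL,
                        hoechst_boundary = NULL) {
  stopifnot(length(hoechst) == length(edu))
  if (length(hoechst) == 0) {
    return(tibble::tibble(hoechst = numeric(), edu = numeric(),
                          phase = character()))
  }
  if (is.null(edu_threshold))
    edu_threshold <- fit_threshold(edu, "gmm2")$threshold
  s_pos <- edu >= edu_threshold
  if (is.null(hoechst_boundary)) {
    hneg <- hoechst[!s_pos]
    hoechst_boundary <- Inf
    if (length(unique(hneg)) >= 10 && stats::sd(hneg) > 1e-12) {
      tm <- fit_threshold(hneg, "gmm2")
      # keep the split only for genuinely bimodal DNA content: the 2N and
      # 4N modes must be separated beyond their widths
      if (!tm$fallback && !is.null(tm$components)) {
        cmp <- tm$components
        if (diff(cmp$mean) > 2 * max(cmp$sd) && all(cmp$weight > 0.02))
          hoechst_boundary <- tm$threshold
      }
    }
  }
  phase <- ifelse(s_pos, "S",
                  ifelse(hoechst < hoechst_boundary, "G0/G1", "G2/M"))
  out <- tibble::tibble(hoechst = hoechst, edu = edu, phase = phase)
  attr(out, "edu_threshold") <- edu_threshold
  attr(out, "hoechst_boundary") <- hoechst_boundary
  out
}

#' Welch two-sample t-test
#'
#' Unequal-variance two-sided t-test with Satterthwaite degrees of freedom.
#' When both samples have zero variance and equal means the conventional
#' `p = 1` is returned, flagged.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return Tibble `t`, `df`, `p`, `mean_a`, `mean_b`, `flag_degenerate`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1,
                            mean_a = mean(a), mean_b = mean(b),
                            flag_degenerate = TRUE))
    }
    return(tibble::tibble(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_,
                          p = 0, mean_a = mean(a), mean_b = mean(b),
                          flag_degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b),
                 flag_degenerate = FALSE)
}
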