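#' Event-calling configuration
#'
#' Thresholds and windows used to call per-cell activation events and
#' proliferative fates from activity traces.
#'
#' @param theta46_on Corrected CDK4/6 activity onset threshold.
#' @param theta2_on CDK2 activity onset threshold (the cohort-selection gate
#'   of 0.6 reporter units).
#' @param theta_degron_on Degron intensity marking APC/C inactivation.
#' @param persistence_w Consecutive frames required above (or below, for
#'   inactivation) threshold. Default 3 frames (36 min at 12-min sampling).
#' @param theta_off Corrected CDK4/6 activity below which the kinase is
#'   called inactivated.
#' @param select_gate CDK2 activity required at treatment time for inclusion
#'   in fate classification. Default 0.6.
#' @param window1,window2 Length-2 offsets from treatment (h) of the two
#'   fate-classification windows.
#' @param inc_cutoff,low_cutoff Mean CDK2 levels in `window2` defining the
#'   continuing (`inc`) and reverting (`low`) fates.
#' @param smooth_k Running-median window (frames, odd) applied to each
#'   series before onset detection in [call_events()]; 1 disables.
#' @param tail_frames Frames required for an above-threshold run truncated
#'   by the end of the series to count as an onset (right-censoring-aware
#'   calling; set to `persistence_w` to disable).
#' @return An object of class `event_config`.
#' @export
event_config <- function(theta46_on = 0.3,
                         theta2_on = 0.6,
                         theta_degron_on = 0.5,
                         persistence_w = 3L,
                         theta_off = 0.3,
                         select_gate = 0.6,
                         window1 = c(0, 2),
                         window2 = c(6, 10),
                         inc_cutoff = 0.8,
                         low_cutoff = 0.5,
                         smooth_k = 3L,
                         tail_frames = 2L) {
  stopifnot(theta46_on >= 0, theta2_on >= 0, theta_off >= 0,
            persistence_w >= 1,
            length(window1) == 2, length(window2) == 2,
            window1[1] <= window1[2], window2[1] <= window2[2])
  if (window1[2] > window2[1])
    stop("event_config: window1 must precede window2", call. = FALSE)
  stopifnot(smooth_k >= 1, smooth_k %% 2 == 1)
  structure(list(theta46_on = theta46_on, theta2_on = theta2_on,
                 theta_degron_on = theta_degron_on,
                 persistence_w = as.integer(persistence_w),
                 theta_off = theta_off, select_gate = select_gate,
                 window1 = window1, window2 = window2,
                 inc_cutoff = inc_cutoff, low_cutoff = low_cutoff,
                 smooth_k = as.integer(smooth_k),
                 tail_frames = as.integer(tail_frames)),
            class = "event_config")
}

#' Detect an activation onset in an activity trace
#'
#' The onset is the first time at which the activity is at or above `theta`
#' for `w` consecutive frames (the onset is the time of the first frame of
#' that run). Returns `NA` if no such run exists.
#'
#' Traces end at fixation, so a crossing in the final frames can never
#' complete a full persistence run; with `tail_w < w`, a terminal run of at
#' least `tail_w` above-threshold frames reaching the end of the series also
#' counts as an onset (right-censoring-aware calling, used by
#' [call_events()]). The default `tail_w = w` is the plain persistence rule.
#'
#' @param activity Numeric activity series, equally spaced in time.
#' @param t Frame times (h), same length as `activity`.
#' @param theta Onset threshold.
#' @param w Persistence, in frames.
#' @param tail_w Frames required when the run is truncated by the series
#'   end.
#' @return Onset time in hours, or `NA_real_`.
#' @export
detect_onset <- function(activity, t, theta, w = 3L, tail_w = w) {
  n <- length(activity)
  stopifnot(length(t) == n)
  w <- as.integer(w)
  tail_w <- max(1L, min(as.integer(tail_w), w))
  if (w > n) stop("persistence window exceeds series length", call. = FALSE)
  above <- !is.na(activity) & activity >= theta
  idx <- first_run_start(above, w)
  if (is.na(idx) && tail_w < w) {
    # terminal run cut short by fixation
    r <- 0L
    while (r < n && above[n - r]) r <- r + 1L
    if (r >= tail_w && r < w) idx <- n - r + 1L
  }
  if (is.na(idx)) NA_real_ else t[idx]
}

# index of the first start of a run of >= w TRUEs, or NA
first_run_start <- function(flag, w) {
  n <- length(flag)
  if (w == 1L) {
    i <- which(flag)[1]
    return(if (is.na(i)) NA_integer_ else i)
  }
  runs <- rle(flag)
  ends <- cumsum(runs$lengths)
  ok <- which(runs$values & runs$lengths >= w)
  if (!length(ok)) return(NA_integer_)
  as.integer(ends[ok[1]] - runs$lengths[ok[1]] + 1L)
}

#' Call per-cell activation events and CDK4/6 classes
#'
#' Applies [detect_onset()] per cell to the corrected CDK4/6 activity, the
#' CDK2 activity, and the degron series, and labels each cell
#' `CDK4/6-high` (onset detected) or `CDK4/6-low`.
#'
#' For a simulated `trace_set` the corrected CDK4/6 activity is computed as
#' `r46_obs - rho * r2_obs` with the generative cross-talk coefficient
#' unless a fitted [estimate_crosstalk()] model is supplied via `crosstalk`.
#'
#' @param traces A `trace_set` or a data frame with columns `cell_id`,
#'   `t`, `cdk46_corrected` (or `r46_obs`/`r2_obs`), `cdk2` (or `r2_obs`),
#'   and optionally `degron` (or `degron_obs`).
#' @param cfg An [event_config()].
#' @param crosstalk Optional `crosstalk_model` used for the correction.
#' @return A tibble with one row per cell: `onset46`, `onset2`, `apc_off`
#'   (hours or `NA`) and `class46` (`"high"`/`"low"`).
#' @export
call_events <- function(traces, cfg = event_config(), crosstalk = NULL) {
  df <- as_event_frame(traces, crosstalk)
  w <- cfg$persistence_w
  sm <- function(x) {
    if (cfg$smooth_k == 1L || length(x) < cfg$smooth_k || anyNA(x)) x
    else stats::runmed(x, cfg$smooth_k)
  }
  out <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      onset46 = detect_onset(sm(.data$cdk46_corrected), .data$t,
                             cfg$theta46_on, w, cfg$tail_frames),
      onset2 = detect_onset(sm(.data$cdk2), .data$t, cfg$theta2_on, w,
                            cfg$tail_frames),
      apc_off = detect_onset(sm(.data$degron), .data$t,
                             cfg$theta_degron_on, w, cfg$tail_frames),
      .groups = "drop"
    ) |>
    dplyr::mutate(class46 = ifelse(is.na(.data$onset46), "low", "high"))
  out
}

# Normalize trace input to cell_id/t/cdk46_corrected/cdk2/degron columns.
as_event_frame <- function(traces, crosstalk = NULL) {
  df <- tibble::as_tibble(traces)
  if (!all(c("cell_id", "t") %in% names(df)))
    stop("traces need cell_id and t columns", call. = FALSE)
  rho <- if (!is.null(crosstalk)) crosstalk$rho
         else attr(traces, "params")$crosstalk_rho
  if (!"cdk2" %in% names(df)) {
    if (!"r2_obs" %in% names(df)) stop("no CDK2 series found", call. = FALSE)
    df$cdk2 <- df$r2_obs
  }
  if (!"cdk46_corrected" %in% names(df)) {
    if (!"r46_obs" %in% names(df))
      stop("no CDK4/6 series found", call. = FALSE)
    if (is.null(rho))
      stop("supply a crosstalk model to correct the CDK4/6 reporter",
           call. = FALSE)
    df$cdk46_corrected <- df$r46_obs - rho * df$cdk2
  }
  if (!"degron" %in% names(df))
    df$degron <- if ("degron_obs" %in% names(df)) df$degron_obs else NA_real_
  df[c("cell_id", "t", "cdk46_corrected", "cdk2", "degron")]
}

#' Classify proliferative fate after a perturbation
#'
#' Implements the two-window fate call: among cells whose CDK2 activity at
#' the treatment time is at least `select_gate`, a cell is `inc`
#' (continuing) if its mean CDK2 over `window2` is at least `inc_cutoff`
#' and not below its mean over `window1`; `low` (reverting to quiescence)
#' if the `window2` mean is at most `low_cutoff`; otherwise `unclassified`.
#' Cells failing the gate are marked `not_selected`.
#'
#' @inheritParams call_events
#' @param t_treat Treatment time, hours.
#' @return A tibble with one row per cell: `cdk2_at_treatment`, `selected`,
#'   `mean_w1`, `mean_w2`, `fate`.
#' @export
classify_fate <- function(traces, t_treat, cfg = event_config(),
                          crosstalk = NULL) {
  df <- as_event_frame(traces, crosstalk)
  if (max(df$t) < t_treat + cfg$window2[2])
    stop("traces end before window2; extend the horizon or move the windows",
         call. = FALSE)
  dtg <- min(diff(sort(unique(df$t))))
  out <- df |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::summarise(
      cdk2_at_treatment = .data$cdk2[which.min(abs(.data$t - t_treat))],
      mean_w1 = mean(.data$cdk2[.data$t >= t_treat + cfg$window1[1] - dtg / 2 &
                                  .data$t <= t_treat + cfg$window1[2] + dtg / 2]),
      mean_w2 = mean(.data$cdk2[.data$t >= t_treat + cfg$window2[1] - dtg / 2 &
                                  .data$t <= t_treat + cfg$window2[2] + dtg / 2]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      selected = .data$cdk2_at_treatment >= cfg$select_gate,
      fate = dplyr::case_when(
        !selected ~ "not_selected",
        mean_w2 >= cfg$inc_cutoff & mean_w2 >= mean_w1 ~ "inc",
        mean_w2 <= cfg$low_cutoff ~ "low",
        TRUE ~ "unclassified"
      )
    )
  out
}

#' Align traces to per-cell event times and summarize
#'
#' Shifts each cell's trace by its event time (offset 0 = the event), then
#' averages the chosen channel per offset across cells, with a t-based 95%
#' confidence interval of the mean.
#'
#' @inheritParams call_events
#' @param event_times Data frame with `cell_id` and `event_time` (h); cells
#'   with `NA` are dropped.
#' @param channel Column of the trace frame to summarize
#'   (`"cdk46_corrected"`, `"cdk2"`, or `"degron"`).
#' @return A tibble of class `aligned_summary`: `offset` (h), `mean`,
#'   `ci_half`, `n`.
#' @export
align_and_summarize <- function(traces, event_times, channel = "cdk2",
                                crosstalk = NULL) {
  df <- as_event_frame(traces, crosstalk)
  ev <- tibble::as_tibble(event_times)
  stopifnot(all(c("cell_id", "event_time") %in% names(ev)))
  ev <- ev[!is.na(ev$event_time), c("cell_id", "event_time")]
  if (nrow(ev) == 0) {
    out <- tibble::tibble(offset = numeric(), mean = numeric(),
                          ci_half = numeric(), n = integer())
    class(out) <- c("aligned_summary", class(out))
    return(out)
  }
  dtg <- min(diff(sort(unique(df$t))))
  out <- df |>
    dplyr::inner_join(ev, by = "cell_id") |>
    dplyr::mutate(offset = round((.data$t - .data$event_time) / dtg) * dtg) |>
    dplyr::group_by(.data$offset) |>
    dplyr::summarise(
      mean = mean(.data[[channel]]),
      ci_half = ci_half_width(.data[[channel]]),
      n = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::arrange(.data$offset)
  class(out) <- c("aligned_summary", class(out))
  out
}

# half-width of the t-based 95% CI of the mean (0 for degenerate samples)
ci_half_width <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2) return(0)
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(0)
  stats::qt(0.975, df = n - 1) * s / sqrt(n)
}

#' Estimate the CDK2 commitment boundary
#'
#' Logistic regression of the continuing fate (`inc`) on CDK2 activity at
#' the time of CDK4/6 inhibition; the boundary is the activity at fitted
#' probability 0.5, with a seeded bootstrap confidence interval. Under
#' complete separation the midpoint between the class extremes is reported
#' and flagged.
#'
#' @param cdk2_at_treatment Per-cell CDK2 activity at the treatment time.
#' @param fate Per-cell fate labels; `"inc"` is the positive class, `"low"`
#'   the negative; other labels are dropped.
#' @param n_boot Bootstrap resamples for the CI. Default 1000.
#' @param seed Bootstrap seed.
#' @return An object of class `commitment_boundary`: a list with `boundary`,
#'   `ci` (2.5/97.5% bootstrap percentiles), `n`, `separation`, and the
#'   fitted `glm` (when not separated). Has [tidy()]/[glance()] methods.
#' @export
estimate_commitment_boundary <- function(cdk2_at_treatment, fate,
                                         n_boot = 1000, seed = 1) {
  keep <- fate %in% c("inc", "low")
  x <- cdk2_at_treatment[keep]
  y <- as.integer(fate[keep] == "inc")
  if (length(unique(y)) < 2)
    stop("both fates must be represented to estimate a boundary",
         call. = FALSE)
  sep <- max(x[y == 0]) < min(x[y == 1])
  if (sep) {
    b <- (max(x[y == 0]) + min(x[y == 1])) / 2
    out <- list(boundary = b, ci = c(NA_real_, NA_real_), n = length(x),
                separation = TRUE, fit = NULL)
    class(out) <- "commitment_boundary"
    return(out)
  }
  fit_b <- function(x, y) {
    f <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
    co <- stats::coef(f)
    if (!is.finite(co[2]) || co[2] == 0) return(NA_real_)
    unname(-co[1] / co[2])
  }
  f <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial()))
  b <- -stats::coef(f)[1] / stats::coef(f)[2]
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    bs <- vapply(seq_len(n_boot), function(k) {
      i <- sample.int(length(x), replace = TRUE)
      if (length(unique(y[i])) < 2) NA_real_ else fit_b(x[i], y[i])
    }, numeric(1))
    ci <- stats::quantile(bs, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  out <- list(boundary = unname(b), ci = ci, n = length(x),
              separation = FALSE, fit = f)
  class(out) <- "commitment_boundary"
  out
}

#' @export
print.commitment_boundary <- function(x, ...) {
  cat("<commitment_boundary> boundary =", round(x$boundary, 4),
      if (x$separation) "(complete separation; midpoint)" else
        sprintf("[95%% CI %.3f, %.3f]", x$ci[1], x$ci[2]),
      " n =", x$n, "\n")
  invisible(x)
}

#' Time from treatment to CDK4/6 inactivation
#'
#' First time at or after `t_treat` at which the corrected CDK4/6 activity
#' is below `theta_off` for `w` consecutive frames, minus `t_treat`.
#'
#' @param activity Corrected CDK4/6 activity series.
#' @param t Frame times (h).
#' @param t_treat Treatment time (h).
#' @param theta_off Inactivation threshold.
#' @param w Persistence, frames.
#' @return Delay in hours, or `NA_real_` if the trace never inactivates.
#' @export
inactivation_delay <- function(activity, t, t_treat, theta_off = 0.3, w = 3L) {
  keep <- t >= t_treat
  below <- !is.na(activity[keep]) & activity[keep] < theta_off
  idx <- first_run_start(below, as.integer(w))
  if (is.na(idx)) NA_real_ else t[keep][idx] - t_treat
}
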