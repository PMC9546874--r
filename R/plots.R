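#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a binned activity map
#'
#' Tile plot of the per-bin statistic (percentage positive or mean marker
#' value) over CDK4/6 (x) and CDK2 (y) activity; masked bins are blank.
#'
#' @param object An `activity_map`.
#' @param ... Unused.
#' @export
autoplot.activity_map <- function(object, ...) {
  lab <- if (attr(object, "stat_type") == "percent") "% positive" else "mean"
  ggplot2::ggplot(tibble::as_tibble(object)) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$x_lo, xmax = .data$x_hi,
      ymin = .data$y_lo, ymax = .data$y_hi, fill = .data$stat)) +
    ggplot2::scale_fill_viridis_c(name = lab, na.value = "grey92") +
    ggplot2::labs(x = "CDK4/6 activity", y = "CDK2 activity") +
    ggplot2::theme_minimal()
}

#' Plot an event-aligned trace summary
#'
#' Mean activity against offset from the aligning event, with the 95%
#' confidence band of the mean.
#'
#' @param object An `aligned_summary` from [align_and_summarize()].
#' @param ... Unused.
#' @export
autoplot.aligned_summary <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$offset, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$ci_half,
                                      ymax = .data$mean + .data$ci_half),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "time from event (h)", y = "mean activity") +
    ggplot2::theme_minimal()
}

#' Plot single-cell reporter traces
#'
#' @param traces A `trace_set` (or compatible tibble).
#' @param channel Column to plot (default the observed CDK2 reporter).
#' @param n_cells Cap on the number of cells drawn.
#' @export
plot_traces <- function(traces, channel = "r2_obs", n_cells = 50) {
  df <- tibble::as_tibble(traces)
  ids <- utils::head(sort(unique(df$cell_id)), n_cells)
  ggplot2::ggplot(df[df$cell_id %in% ids, ],
                  ggplot2::aes(.data$t, .data[[channel]],
                               group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.3) +
    ggplot2::labs(x = "time (h)", y = channel) +
    ggplot2::theme_minimal()
}
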