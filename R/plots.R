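#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bland-Altman plot
#'
#' Scatter of per-pair differences against per-pair means with the bias and
#' limits of agreement as horizontal lines.
#'
#' @param object A [bland_altman] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$mean_deg, y = .data$difference_deg)) +
    ggplot2::geom_hline(yintercept = object$bias_deg, linetype = "solid",
                        colour = "steelblue") +
    ggplot2::geom_hline(yintercept = c(object$lower_loa_deg,
                                       object$upper_loa_deg),
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(
      x = "Mean of device and reference tilt change (deg)",
      y = "Device - reference (deg)",
      title = sprintf("Bland-Altman: bias %.2f deg, LOA [%.2f, %.2f]",
                      object$bias_deg, object$lower_loa_deg,
                      object$upper_loa_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Absolute-error histogram with Poisson overlay
#'
#' Integer-binned histogram of absolute device-reference errors with the
#' fitted Poisson probability mass function (scaled to counts) overlaid.
#'
#' @param object An [error_distribution] object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.error_distribution <- function(object, ...) {
  h <- object$histogram
  h$poisson_count <- object$n *
    stats::dpois(h$error_deg, object$poisson_lambda)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$error_deg, y = .data$count)) +
    ggplot2::geom_col(fill = "grey70", colour = "grey30", width = 0.9) +
    ggplot2::geom_line(ggplot2::aes(y = .data$poisson_count),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$poisson_count),
                        colour = "firebrick", size = 1.5) +
    ggplot2::labs(
      x = "Absolute error (deg)", y = "Count",
      title = sprintf("Absolute errors: median %.1f deg, Q3 %.1f deg",
                      object$median_deg, object$q3_deg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a trace's tilt series with its selected stable window
#'
#' Diagnostic view of the per-sample pitch (raw and smoothed) with the
#' selected most-stable 300 ms window shaded.
#'
#' @param trace An [accel_trace].
#' @inheritParams select_stable_window
#' @return A ggplot.
#' @export
plot_stable_window <- function(trace, window_s = 0.3, hop_s = 0.1,
                               filter_len_s = 0.05) {
  est <- select_stable_window(trace, window_s, hop_s, filter_len_s)
  raw <- tilt_series(trace, smooth = FALSE)
  sm <- tilt_series(trace, filter_len_s = filter_len_s, smooth = TRUE)
  df <- dplyr::bind_rows(
    dplyr::mutate(raw, series = "raw"),
    dplyr::mutate(sm, series = "smoothed")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$pitch_deg,
                                   colour = .data$series)) +
    ggplot2::annotate("rect", xmin = est$window_start_s,
                      xmax = est$window_end_s, ymin = -Inf, ymax = Inf,
                      alpha = 0.2, fill = "seagreen") +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = est$pitch_deg, linetype = "dotted") +
    ggplot2::labs(x = "Time (s)", y = "Pitch (deg)", colour = NULL,
                  title = sprintf("Selected window %.1f-%.1f s, pitch %.2f deg",
                                  est$window_start_s, est$window_end_s,
                                  est$pitch_deg)) +
    ggplot2::theme_minimal()
}
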