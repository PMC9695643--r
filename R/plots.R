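#' Plot monitored-point temperature traces
#'
#' Temperature over treatment time at the monitored points, with the
#' apoptosis band shaded.
#'
#' @param object a `temperature_series`.
#' @param band an [apoptosis_band()] to shade.
#' @param ... unused.
#' @return a ggplot.
#' @importFrom ggplot2 autoplot
#' @export
autoplot.temperature_series <- function(object, band = apoptosis_band(),
                                        ...) {
  df <- tidy.temperature_series(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s,
                                   y = .data$temperature_C,
                                   color = .data$point)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = band$lower, ymax = band$upper,
                      alpha = 0.15, fill = "forestgreen") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "temperature (°C)",
                  color = "monitor") +
    ggplot2::theme_minimal()
}

#' Plot a dose-metric trace
#'
#' Instantaneous apoptosis ratio and thermal hazard over treatment time.
#'
#' @param object a [treatment_metrics()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.metric_series <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object), -"time_s",
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot sweep results over laser power
#'
#' One panel per cooling-time ratio, one line per nanoparticle volume
#' fraction — the layout used to compare retention metrics across the
#' sweep.
#'
#' @param object a [run_sweep()] result.
#' @param metric which scalar to plot.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.sweep_result <- function(object,
                                  metric = c("theta_A_star", "theta_H_star",
                                             "theta_eff_star"), ...) {
  metric <- match.arg(metric)
  df <- dplyr::mutate(tibble::as_tibble(object),
                      f_v = factor(format(.data$f_v, scientific = TRUE)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_mw, y = .data[[metric]],
                                   color = .data$f_v)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phi_c, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "laser power (mW)", y = metric,
                  color = "volume fraction") +
    ggplot2::theme_minimal()
}
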