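#' Spike raster plot
#'
#' @param spikes Spike tibble from the simulation functions.
#' @param populations Populations to show (default: all present).
#' @return A ggplot object.
#' @export
plot_raster <- function(spikes, populations = NULL) {
  if (!is.null(populations)) {
    spikes <- spikes[spikes$population %in% populations, ]
  }
  ggplot2::ggplot(spikes,
                  ggplot2::aes(x = .data$t_ms / 1000, y = .data$neuron)) +
    ggplot2::geom_point(size = 0.1, shape = ".") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$population),
                        scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' @method autoplot learning_curve
#' @export
autoplot.learning_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample, y = .data$l1_error)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "sample presentation", y = "L1 error") +
    ggplot2::theme_minimal()
}

#' @method autoplot psychometric_curve
#' @export
autoplot.psychometric_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$input, y = .data$r_mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r_mean - .data$r_sd,
                                      ymax = .data$r_mean + .data$r_sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "input i", y = "output r") +
    ggplot2::theme_minimal()
}

#' @method autoplot history_fit
#' @export
autoplot.history_fit <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$last5_mean, y = .data$output)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "mean of last five samples",
                  y = "normalized output r") +
    ggplot2::theme_minimal()
}

#' @method autoplot recall_result
#' @export
autoplot.recall_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$probability,
                                       y = .data$rate_hz)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$rate_hz - .data$rate_sd,
      ymax = .data$rate_hz + .data$rate_sd)) +
    ggplot2::labs(x = "stored probability", y = "read-out E rate (Hz)") +
    ggplot2::theme_minimal()
}

#' @method autoplot switch_series
#' @export
autoplot.switch_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sample, y = .data$slope)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "samples after distribution switch",
                  y = "psychometric slope") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
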