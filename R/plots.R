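#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a temporal generalisation matrix
#'
#' @param object A `tgm` object.
#' @param ... Unused.
#' @return A ggplot: training time against testing time, filled by
#'   cross-validated accuracy, with a diverging scale centred on chance.
#' @method autoplot tgm
#' @export
autoplot.tgm <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$test_time, .data$train_time,
                                   fill = .data$accuracy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(midpoint = 0.5, low = "#2166ac",
                                  mid = "white", high = "#b2182b") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(x = "testing time (s)", y = "training time (s)",
                  fill = "accuracy") +
    ggplot2::theme_minimal()
}

#' Condition-average (ERP/F-style) traces of an epoched dataset
#'
#' Averages the signal across trials within each condition for the selected
#' channels.
#'
#' @param object An `epoched_data` object.
#' @param channels Channel indices to show (default: first channel).
#' @param ... Unused.
#' @return A ggplot of the per-condition trial-average traces.
#' @method autoplot epoched_data
#' @export
autoplot.epoched_data <- function(object, channels = 1, ...) {
  df <- tidy(object)
  df <- dplyr::filter(df, .data$channel %in% channels)
  df <- dplyr::summarise(
    dplyr::group_by(df, .data$condition, .data$channel, .data$time),
    value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$value,
                                   colour = factor(.data$condition))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "trial-average signal",
                  colour = "condition") +
    ggplot2::theme_minimal()
}

#' Heatmap of a response-shape sweep
#'
#' @param object A `tgm_sweep` tibble ([sweep_response_shape()]).
#' @param ... Unused.
#' @return A ggplot tile map of correlation over the (delta2, delta3) grid,
#'   with the best cell outlined.
#' @method autoplot tgm_sweep
#' @export
autoplot.tgm_sweep <- function(object, ...) {
  am <- attr(object, "argmax")
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$delta2, .data$delta3,
                                            fill = .data$correlation)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "rise duration delta2 (samples)",
                  y = "fall duration delta3 (samples)",
                  fill = "r") +
    ggplot2::theme_minimal()
  if (!is.null(am)) {
    p <- p + ggplot2::geom_tile(data = am, fill = NA, colour = "black",
                                linewidth = 0.8)
  }
  p
}

#' Plot the response function
#'
#' @param shape A [response_shape()].
#' @param tau Stimulus onset (samples).
#' @param n_times Number of samples to draw.
#' @return A ggplot of the gate over time.
#' @export
plot_response_shape <- function(shape, tau = 0, n_times = NULL) {
  if (is.null(n_times)) {
    n_times <- ceiling(tau + shape$delta1 + shape$delta2 + shape$delta3 + 10)
  }
  tt <- 0:(n_times - 1)
  df <- tibble::tibble(t = tt, gate = response_gate(shape, tt, tau))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$gate)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = shape$delta1 + shape$delta2 + tau,
                        linetype = "dashed") +
    ggplot2::labs(x = "time (samples)", y = "G(t; tau)") +
    ggplot2::theme_minimal()
}
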