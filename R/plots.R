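#' Plot per-class normalized decay curves
#'
#' @param decay_curves The `decay_curves` component of a
#'   [run_grid_analysis()] result (columns `class`, `dose_mode`, `trial`,
#'   `norm_response`).
#' @return A ggplot.
#' @export
plot_decay_curves <- function(decay_curves) {
  ggplot2::ggplot(decay_curves,
                  ggplot2::aes(x = .data$trial, y = .data$norm_response,
                               colour = .data$class,
                               linetype = .data$dose_mode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::scale_x_continuous(breaks = unique(decay_curves$trial)) +
    ggplot2::labs(x = "Trial", y = "Normalized response",
                  colour = "Cell class", linetype = "Imaging dose") +
    ggplot2::theme_minimal()
}

#' Plot delta response against ISI
#'
#' @param deltas The `deltas` component of a [run_grid_analysis()] result
#'   (columns `class`, `animal`, `isi`, `dose_mode`, `delta_response`).
#' @return A ggplot with per-ISI means and a linear fit per dose.
#' @export
plot_delta_response <- function(deltas) {
  means <- dplyr::summarize(
    dplyr::group_by(deltas, .data$class, .data$dose_mode, .data$isi),
    delta_response = mean(.data$delta_response), .groups = "drop")
  ggplot2::ggplot(means,
                  ggplot2::aes(x = .data$isi, y = .data$delta_response,
                               colour = .data$dose_mode)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::facet_wrap(~class) +
    ggplot2::labs(x = "ISI (s)", y = expression(Delta * "Response"),
                  colour = "Imaging dose") +
    ggplot2::theme_minimal()
}

#' Plot a decay fit with its data
#'
#' @param object A `decay_fit`.
#' @param ... Unused.
#' @return A ggplot of the data points and the fitted curve.
#' @export
autoplot.decay_fit <- function(object, ...) {
  grid <- tibble(x = seq(min(object$data$x), max(object$data$x),
                         length.out = 200))
  grid$y <- predict(object, grid$x)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::labs(x = "x", y = "y",
                  title = sprintf("%s fit (RSS %.3g)", object$model,
                                  object$rss)) +
    ggplot2::theme_minimal()
}
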