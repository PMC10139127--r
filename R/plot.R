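#' Prediction-probability plot with per-sample confidence intervals
#'
#' One point per held-out sample at its mean jackknife prediction
#' probability, a vertical error bar spanning its nonparametric confidence
#' interval, a horizontal reference line at the classification threshold,
#' and samples grouped by true class along the x axis.  A zero-width
#' interval degenerates to the marker.
#'
#' @param records Records tibble carrying `jk_mean`, `ci_low`, `ci_high`
#'   (from [conservative_intervals()]).
#' @param threshold Classification cut-point drawn as a reference line.
#' @return A ggplot object.
#' @export
plot_prediction_probabilities <- function(records, threshold = 0.5) {
  if (!all(c("jk_mean", "ci_low", "ci_high") %in% names(records)) ||
      anyNA(records$ci_low)) {
    abort(paste0("Records lack jackknife summaries; run ",
                 "conservative_intervals() first."),
          class = "stavarsel_jackknife")
  }
  dat <- records |>
    arrange(.data$y, desc(.data$jk_mean)) |>
    mutate(position = row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$position, y = .data$jk_mean,
                                    colour = .data$true_label)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high),
                           width = 0.3) +
    ggplot2::geom_point(shape = 21, fill = "white", size = 2) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "sample", y = "prediction probability",
                  colour = "true class") +
    ggplot2::theme_minimal()
}

#' Render the prediction-probability plot to an image file
#'
#' @inheritParams plot_prediction_probabilities
#' @param path Output image path (`.png` or `.svg` by extension).
#' @param width,height Device size in inches.
#' @return The path, invisibly.
#' @export
render_prediction_probability_plot <- function(records, path,
                                               threshold = 0.5,
                                               width = 7, height = 4) {
  p <- plot_prediction_probabilities(records, threshold)
  ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
  invisible(path)
}

#' Step-forward error-curve plot
#'
#' @param object A `stavarsel_fit` or `step_forward_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot step_forward_curve
#' @export
autoplot.step_forward_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$k, y = .data$error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dotted") +
    ggplot2::labs(x = "model size (number of ratios)",
                  y = "mean cross-validated prediction error") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.step_forward_curve
#' @method autoplot stavarsel_fit
#' @export
autoplot.stavarsel_fit <- function(object, ...) {
  if (is.null(object$curve)) {
    abort("Fit has no step-forward curve (empty stable list).",
          class = "stavarsel_frequency")
  }
  autoplot.step_forward_curve(object$curve, ...)
}
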