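#' @method autoplot simple_fit
#' @export
autoplot.simple_fit <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[object$x]], y = .data[[object$y]])) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(
      title = sprintf("%s = %.3f %s %+.3f  (r² = %.3f, p = %.4f)",
                      object$y, object$slope, object$x, object$intercept,
                      object$r2, object$slope_p),
      x = object$x, y = object$y
    ) +
    ggplot2::theme_minimal()
}

#' Threshold-classification scatter plot
#'
#' Scatter of per-interval records in the (DI change, layer change) plane
#' with the fitted regression line and both threshold lines; points are
#' coloured by diagnostic cell. This is the plane in which the contingency
#' table lives: the vertical line is the CI threshold, the horizontal line
#' the interpolated biomarker threshold.
#'
#' @param classified Output of [classify_changes()].
#' @param spec The `threshold_spec` used for classification.
#' @return A ggplot object.
#' @export
plot_threshold_classification <- function(classified, spec) {
  dcol <- paste0("d_", spec$layer %||% "inl")
  d <- dplyr::mutate(
    classified,
    cell = factor(
      paste(.data$ncd_status, .data$test_result, sep = " / "),
      levels = c("no_CI / positive", "no_CI / negative",
                 "CI / positive", "CI / negative")
    )
  )
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$d_di, y = .data[[dcol]],
                                       colour = .data$cell)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(xintercept = spec$ci_threshold, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = spec$biomarker_threshold,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "monthly change in discrimination index (DI/month)",
      y = sprintf("monthly change in %s thickness (px/month)",
                  toupper(spec$layer %||% "layer")),
      colour = "condition / test"
    ) +
    ggplot2::theme_minimal()
  if (is.finite(spec$slope) && is.finite(spec$intercept)) {
    p <- p + ggplot2::geom_abline(slope = spec$slope,
                                  intercept = spec$intercept,
                                  colour = "grey40")
  }
  p
}

#' @method autoplot contingency_2x2
#' @export
autoplot.contingency_2x2 <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$test, y = .data$condition)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "diagnostic test result", y = "condition",
                  title = "2x2 contingency (condition = no CI)") +
    ggplot2::theme_minimal()
}

#' @method autoplot pipeline_result
#' @export
autoplot.pipeline_result <- function(object, ...) {
  plot_threshold_classification(object$classified, object$thresholds)
}
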