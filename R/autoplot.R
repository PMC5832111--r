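#' Plot a CCA score curve
#'
#' @param object A [cca_score_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cca_curve
#' @export
autoplot.cca_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = frequency, y = score)) +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::labs(x = "Frequency (Hz)", y = "Max canonical correlation",
                  title = "CCA score curve") +
    ggplot2::theme_minimal()
}

#' Plot per-channel PSD curves
#'
#' @param object A [psd_curve()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot psd_curve
#' @export
autoplot.psd_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = frequency, y = power,
                               colour = factor(channel))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Frequency (Hz)", y = expression(PSD ~ (mu * V^2 / Hz)),
                  colour = "Channel", title = "Welch PSD per channel") +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation confusion matrix
#'
#' @param object An [cross_validate()] result.
#' @param ... Unused.
#' @return A ggplot heatmap of the pooled confusion matrix.
#' @method autoplot ssvep_cv
#' @export
autoplot.ssvep_cv <- function(object, ...) {
  df <- as.data.frame(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = predicted, y = truth,
                                   fill = .data$Freq)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$Freq), colour = "white") +
    ggplot2::scale_fill_gradient(low = "#3b528b", high = "#5ec962") +
    ggplot2::labs(x = "Predicted frequency (Hz)", y = "True frequency (Hz)",
                  fill = "Trials",
                  title = sprintf("Confusion matrix (mean accuracy %.1f%%)",
                                  object$mean_accuracy)) +
    ggplot2::theme_minimal()
}
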