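#' Scatter plot of out-of-fold predictive values
#'
#' One point per patient, grouped by true class, with the threshold-0
#' decision boundary drawn; the figure mirrors the usual way individual
#' predictive values of an e-nose classifier are reported.
#'
#' @param object an `enose_cv` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enose_cv <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$true_label, y = .data$predictive_value,
                 colour = .data$true_label)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed") +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.8) +
    ggplot2::scale_y_continuous(limits = c(-1, 1)) +
    ggplot2::labs(
      x = NULL, y = "predictive value",
      colour = NULL,
      title = sprintf("Out-of-fold predictive values (positive: %s)",
                      attr(object, "positive"))
    ) +
    ggplot2::theme_minimal()
}

#' ROC curve plot
#'
#' @param object an `enose_roc` object from [roc_curve()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.enose_roc <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "false-positive rate", y = "true-positive rate",
      title = sprintf("ROC (AUC = %.3f)", as.numeric(attr(object, "auc")))
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.enose_cv
#' @param x an `enose_cv` object.
#' @export
plot_predictions <- function(x, ...) autoplot.enose_cv(x, ...)

#' @rdname autoplot.enose_roc
#' @param x an `enose_roc` object.
#' @export
plot_roc <- function(x, ...) autoplot.enose_roc(x, ...)
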