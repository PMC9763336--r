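## ggplot2 visualizations for result objects.

#' Plot a ROC curve
#'
#' @param object An `acp_roc` tibble from [roc_curve()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot acp_roc
#' @export
autoplot.acp_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - Spc)",
      y = "True positive rate (Sen)",
      title = "ROC curve"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a 2-D PCA projection
#'
#' @param object An `acp_projection` from [pca_project()].
#' @param labels Optional vector (aligned with the projected rows) used to
#'   colour points, e.g. class labels.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot acp_projection
#' @export
autoplot.acp_projection <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  evr <- object$explained_variance_ratio
  if (!is.null(labels)) df$label <- factor(labels)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * evr[1L]),
      y = sprintf("PC2 (%.1f%%)", 100 * evr[2L]),
      title = "PCA of penultimate-layer features"
    ) +
    ggplot2::theme_minimal()
  if (is.null(labels)) {
    p + ggplot2::geom_point(alpha = 0.7)
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$label), alpha = 0.7)
  }
}

#' Plot channel importance from an attribution report
#'
#' Bar chart of the mean absolute Shapley value per feature channel.
#'
#' @param object An `acp_attribution`.
#' @param top_n Number of channels shown (default 10).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot acp_attribution
#' @export
autoplot.acp_attribution <- function(object, top_n = 10L, ...) {
  imp <- head(object$importance, top_n)
  imp$channel <- factor(imp$channel, levels = rev(imp$channel))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$channel)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "mean |Shapley value|",
      y = NULL,
      title = "Channel importance"
    ) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `acp_cv`.
#' @param ... Unused.
#' @return A ggplot with one panel per metric.
#' @method autoplot acp_cv
#' @export
autoplot.acp_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$folds[c("fold", "acc", "sen", "spc", "mcc", "auc")],
    cols = -"fold", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$fold), y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fold", y = NULL, title = "Cross-validation metrics") +
    ggplot2::theme_minimal()
}
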