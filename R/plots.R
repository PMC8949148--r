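# ggplot2 autoplot methods for the main result types.

#' @importFrom ggplot2 ggplot aes geom_line geom_point geom_ribbon geom_col
#'   geom_boxplot geom_step geom_abline labs theme_minimal
NULL

#' Plot a depth validation curve
#'
#' Training and validation label-based accuracy (percent) against tree
#' depth, with +/- 1 SD ribbons; the vertical line marks the recommended
#' depth.
#'
#' @param object An `amen_validation_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amen_validation_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    cols = c("train_mean", "val_mean"),
    names_to = "set", values_to = "mean"
  )
  long$sd <- ifelse(long$set == "train_mean", long$train_sd, long$val_sd)
  long$set <- ifelse(long$set == "train_mean", "training", "validation")
  ggplot(long, aes(x = .data$depth, y = .data$mean, colour = .data$set, fill = .data$set)) +
    geom_ribbon(aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.15, colour = NA
    ) +
    geom_line() +
    geom_point(size = 1) +
    ggplot2::geom_vline(
      xintercept = attr(object, "recommended_depth"),
      linetype = "dashed", colour = "grey40"
    ) +
    labs(
      x = "max depth", y = "label-based accuracy (%)",
      colour = NULL, fill = NULL,
      title = "Decision-tree validation curve"
    ) +
    theme_minimal()
}

#' Plot a selection trace
#'
#' Retained feature counts per pipeline stage (log scale), the compact
#' view of the staged selection.
#'
#' @param object An `amen_selection_trace`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amen_selection_trace <- function(object, ...) {
  d <- tidy(object)
  d$stage <- factor(d$stage, levels = d$stage)
  ggplot(d, aes(x = .data$stage, y = .data$n_retained)) +
    geom_col(fill = "steelblue") +
    ggplot2::geom_text(aes(label = .data$n_retained), vjust = -0.4, size = 3) +
    ggplot2::scale_y_log10() +
    labs(
      x = NULL, y = "features retained (log scale)",
      title = "Staged feature selection"
    ) +
    theme_minimal()
}

#' Plot the recursive-elimination score curve
#'
#' Cross-validated label-based accuracy against the number of retained
#' features, the plateau diagnostic of the RFE stage.
#'
#' @param trace An `amen_selection_trace` (or an `amen_rfe`).
#' @return A ggplot object.
#' @export
plot_rfe_curve <- function(trace) {
  curve <- if (inherits(trace, "amen_rfe")) trace$score_curve else trace$rfe_curve
  ggplot(curve, aes(x = .data$n_features, y = 100 * .data$accuracy)) +
    geom_line() +
    geom_point() +
    labs(
      x = "number of features", y = "CV label-based accuracy (%)",
      title = "Recursive feature elimination"
    ) +
    theme_minimal()
}

#' Plot repeated-CV accuracies per method
#'
#' @param object An `amen_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amen_cv <- function(object, ...) {
  ggplot(object$scores, aes(x = .data$method, y = 100 * .data$accuracy)) +
    geom_boxplot(fill = "grey90") +
    labs(
      x = NULL, y = "label-based accuracy (%)",
      title = sprintf("%d x %d-fold cross-validation", object$repetitions, object$folds)
    ) +
    theme_minimal()
}

#' Plot a ROC curve
#'
#' @param object An `amen_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.amen_roc <- function(object, ...) {
  ggplot(object, aes(x = .data$fpr, y = .data$tpr)) +
    geom_step() +
    geom_abline(slope = 1, intercept = 0, linetype = "dotted", colour = "grey50") +
    labs(x = "false positive rate", y = "true positive rate", title = "ROC curve") +
    theme_minimal()
}
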