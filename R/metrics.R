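#' Label-based (Hamming) accuracy for multi-label predictions
#'
#' The score of one compound is the Jaccard overlap between its true and
#' predicted label sets: |y ∩ ŷ| / |y ∪ ŷ|, where each set is a subset of
#' \{GC, LC\}. The overall accuracy is the mean over compounds. A compound
#' with both sets empty scores 1 (nothing to get wrong); this situation is
#' reported through the `n_empty` attribute so it can be flagged.
#'
#' @param truth Data frame or matrix with binary columns `GC` and `LC`
#'   holding the true labels.
#' @param pred Same shape, holding predicted labels.
#' @return A single number in \[0, 1\]. Attribute `n_empty` counts rows where
#'   both label sets were empty.
#' @seealso [exact_match_ratio()], [classification_report()]
#' @examples
#' truth <- data.frame(GC = c(1, 1, 0), LC = c(0, 1, 1))
#' pred  <- data.frame(GC = c(0, 1, 1), LC = c(1, 1, 1))
#' label_accuracy(truth, pred) # (0 + 1 + 1/2) / 3
#' @export
label_accuracy <- function(truth, pred) {
  yt <- as_label_matrix(truth, "truth")
  yp <- as_label_matrix(pred, "pred")
  if (nrow(yt) != nrow(yp)) abort("'truth' and 'pred' must have the same number of rows")
  if (nrow(yt) == 0) abort("'truth' is empty")
  inter <- rowSums(yt & yp)
  union <- rowSums(yt | yp)
  score <- ifelse(union == 0, 1, inter / union)
  out <- mean(score)
  attr(out, "n_empty") <- sum(union == 0)
  out
}

#' Exact match ratio
#'
#' Fraction of compounds whose predicted label set equals the true label set
#' exactly. Always less than or equal to [label_accuracy()], which gives
#' partial credit for half-right rows.
#'
#' @inheritParams label_accuracy
#' @return A single number in \[0, 1\].
#' @export
exact_match_ratio <- function(truth, pred) {
  yt <- as_label_matrix(truth, "truth")
  yp <- as_label_matrix(pred, "pred")
  if (nrow(yt) != nrow(yp)) abort("'truth' and 'pred' must have the same number of rows")
  if (nrow(yt) == 0) abort("'truth' is empty")
  mean(rowSums(yt == yp) == ncol(yt))
}

#' Multi-label classification report
#'
#' Per-class precision, recall, F1 and accuracy for the GC and LC labels,
#' plus micro (pooled confusion counts), macro (unweighted class mean),
#' weighted (support-weighted class mean) and samples (per-row, then
#' averaged) averages, the label-based accuracy and the exact match ratio.
#' Rates are kept as proportions internally; [tidy()] renders the
#' conventional percent table rounded to two decimals.
#'
#' A class with no predicted positives gets precision 0 (flagged in
#' `$flags`), and analogously for recall with no true positives; the samples
#' average treats a row with an empty predicted (or true) set as precision
#' (or recall) 0 for that row.
#'
#' @inheritParams label_accuracy
#' @return An object of class `amen_report` with elements `per_class`
#'   (tibble: class, tp, fp, fn, tn, support, precision, recall, f1,
#'   accuracy), `averages` (tibble: average, precision, recall, f1),
#'   `label_accuracy`, `exact_match_ratio`, `n`, and `flags`.
#' @export
classification_report <- function(truth, pred) {
  yt <- as_label_matrix(truth, "truth")
  yp <- as_label_matrix(pred, "pred")
  if (nrow(yt) != nrow(yp)) abort("'truth' and 'pred' must have the same number of rows")
  n <- nrow(yt)
  if (n == 0) abort("'truth' is empty")

  flags <- character(0)
  per_class <- purrr::map_dfr(seq_along(LABEL_COLS), function(j) {
    t <- yt[, j]
    p <- yp[, j]
    tp <- sum(t == 1 & p == 1)
    fp <- sum(t == 0 & p == 1)
    fn <- sum(t == 1 & p == 0)
    tn <- sum(t == 0 & p == 0)
    if (tp + fp == 0) flags <<- c(flags, sprintf("%s: no predicted positives, precision set to 0", LABEL_COLS[j]))
    if (tp + fn == 0) flags <<- c(flags, sprintf("%s: no true positives, recall set to 0", LABEL_COLS[j]))
    prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    tibble(
      class = LABEL_COLS[j], tp = tp, fp = fp, fn = fn, tn = tn,
      support = tp + fn, precision = prec, recall = rec, f1 = f1,
      accuracy = (tp + tn) / n
    )
  })

  # micro: pool counts over classes
  tp <- sum(per_class$tp); fp <- sum(per_class$fp); fn <- sum(per_class$fn)
  micro_p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  micro_r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  micro_f <- if (micro_p + micro_r == 0) 0 else 2 * micro_p * micro_r / (micro_p + micro_r)

  macro <- colMeans(per_class[, c("precision", "recall", "f1")])
  w <- per_class$support / sum(per_class$support)
  weighted <- colSums(per_class[, c("precision", "recall", "f1")] * w)

  # samples: per-row precision/recall/F1 on the label sets, then averaged
  inter <- rowSums(yt & yp)
  n_pred <- rowSums(yp)
  n_true <- rowSums(yt)
  sp <- ifelse(n_pred == 0, 0, inter / pmax(n_pred, 1))
  sr <- ifelse(n_true == 0, 0, inter / pmax(n_true, 1))
  sf <- ifelse(sp + sr == 0, 0, 2 * sp * sr / (sp + sr))
  if (any(n_pred == 0)) flags <- c(flags, "samples average: rows with empty predicted set scored precision 0")
  if (any(n_true == 0)) flags <- c(flags, "samples average: rows with empty true set scored recall 0")

  averages <- tibble(
    average = c("micro", "macro", "weighted", "samples"),
    precision = c(micro_p, macro[["precision"]], weighted[["precision"]], mean(sp)),
    recall = c(micro_r, macro[["recall"]], weighted[["recall"]], mean(sr)),
    f1 = c(micro_f, macro[["f1"]], weighted[["f1"]], mean(sf))
  )

  structure(
    list(
      per_class = per_class,
      averages = averages,
      label_accuracy = as.numeric(label_accuracy(yt, yp)),
      exact_match_ratio = exact_match_ratio(yt, yp),
      n = n,
      flags = unique(flags)
    ),
    class = "amen_report"
  )
}

#' @export
print.amen_report <- function(x, ...) {
  cat(sprintf("Multi-label classification report (n = %d)\n", x$n))
  print(tidy(x), n = Inf)
  cat(sprintf(
    "Label-based accuracy: %.2f%%   Exact match ratio: %.2f%%\n",
    100 * x$label_accuracy, 100 * x$exact_match_ratio
  ))
  if (length(x$flags) > 0) cat("Flags:", paste(x$flags, collapse = "; "), "\n")
  invisible(x)
}

#' @describeIn classification_report Percent-scale report table (two
#'   decimals), one row per class and per averaging scheme.
#' @param x An `amen_report` object.
#' @param ... Unused.
#' @export
tidy.amen_report <- function(x, ...) {
  pc <- dplyr::transmute(
    x$per_class,
    row = paste0(.data$class, " class"),
    precision = round(100 * .data$precision, 2),
    recall = round(100 * .data$recall, 2),
    f1 = round(100 * .data$f1, 2),
    accuracy = round(100 * .data$accuracy, 2)
  )
  av <- dplyr::transmute(
    x$averages,
    row = paste(.data$average, "average"),
    precision = round(100 * .data$precision, 2),
    recall = round(100 * .data$recall, 2),
    f1 = round(100 * .data$f1, 2),
    accuracy = NA_real_
  )
  dplyr::bind_rows(pc, av)
}

#' @describeIn classification_report One-row summary with the two global
#'   multi-label scores (percent).
#' @export
glance.amen_report <- function(x, ...) {
  tibble(
    n = x$n,
    label_accuracy = round(100 * x$label_accuracy, 2),
    exact_match_ratio = round(100 * x$exact_match_ratio, 2)
  )
}

#' ROC curve and AUC by the rank statistic
#'
#' `roc_auc()` computes the area under the ROC curve as the probability that
#' a randomly chosen positive outscores a randomly chosen negative, with
#' ties counted 1/2 (the Mann-Whitney statistic). This equals the
#' trapezoidal area under the empirical ROC step curve. `roc_points()`
#' returns the curve itself. Binary 0/1 scores give the one-point ROC whose
#' AUC is the balanced accuracy.
#'
#' @param truth Binary 0/1 vector for a single label.
#' @param scores Numeric score vector; larger means more positive.
#' @return `roc_auc()`: a single number in \[0, 1\]. `roc_points()`: a tibble
#'   with columns `threshold`, `fpr`, `tpr` (class `amen_roc`).
#' @examples
#' roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)) # 0.75
#' @export
roc_auc <- function(truth, scores) {
  if (length(truth) != length(scores)) abort("'truth' and 'scores' must have equal length")
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) abort("'truth' must be binary 0/1")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) abort("ROC needs at least one positive and one negative instance")
  r <- rank(scores) # average ranks handle ties as 1/2 wins
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname roc_auc
#' @export
roc_points <- function(truth, scores) {
  if (length(truth) != length(scores)) abort("'truth' and 'scores' must have equal length")
  truth <- as.integer(truth)
  if (!all(truth %in% c(0L, 1L))) abort("'truth' must be binary 0/1")
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) abort("ROC needs at least one positive and one negative instance")
  thr <- sort(unique(scores), decreasing = TRUE)
  pts <- purrr::map_dfr(thr, function(t) {
    tibble(
      threshold = t,
      fpr = sum(truth == 0 & scores >= t) / n0,
      tpr = sum(truth == 1 & scores >= t) / n1
    )
  })
  out <- dplyr::bind_rows(tibble(threshold = Inf, fpr = 0, tpr = 0), pts)
  class(out) <- c("amen_roc", class(out))
  out
}
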