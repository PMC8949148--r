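# Small fixture builders used across the test files; everything is
# generated in code at test time.

# single separable feature: both labels are x > 0
make_separable <- function(n = 100) {
  x <- c(seq(-1, -0.01, length.out = n / 2), seq(0.01, 1, length.out = n / 2))
  list(
    data = tibble::tibble(.id = as.character(seq_along(x)), x = x),
    labels = tibble::tibble(GC = as.integer(x > 0), LC = as.integer(x > 0))
  )
}

# compact synthetic dataset for fast model-based tests
tiny_sim <- function(seed = 1, n = 400, noise = 0.05, red = 2, qc = 2, nnoise = 8) {
  generate_descriptors(synthetic_config(
    n_compounds = n, label_noise = noise, n_redundant = red,
    n_quasi_constant = qc, n_noise = nnoise, seed = seed
  ))
}

# fast selection configuration for unit tests
tiny_selection_config <- function(seed = 1, ...) {
  selection_config(
    cv_folds = 3L, sfs_repetitions = 2L, n_trees = 15L, seed = seed, ...
  )
}

write_tiny_csv <- function(path, gc = c("1", "0", "1"), lc = c("0", "1", "1")) {
  writeLines(c(
    "SMILES,logP,GC,LC",
    paste("CCO", "1.2", gc[1], lc[1], sep = ","),
    paste("CCN", "0.5", gc[2], lc[2], sep = ","),
    paste("CCC", "2.1", gc[3], lc[3], sep = ",")
  ), path)
  path
}

# independent brute-force oracle for the per-row Jaccard accuracy:
# explicit label-set arithmetic, no vectorized shortcuts
oracle_label_accuracy <- function(truth, pred) {
  truth <- as.matrix(truth)
  pred <- as.matrix(pred)
  labels <- c("GC", "LC")
  scores <- vapply(seq_len(nrow(truth)), function(i) {
    yt <- labels[truth[i, ] == 1]
    yp <- labels[pred[i, ] == 1]
    u <- union(yt, yp)
    if (length(u) == 0) 1 else length(intersect(yt, yp)) / length(u)
  }, numeric(1))
  mean(scores)
}

# independent trapezoidal AUC oracle over the empirical ROC step curve
oracle_trapezoid_auc <- function(truth, scores) {
  thr <- sort(unique(scores), decreasing = TRUE)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  fpr <- c(0, vapply(thr, function(t) sum(truth == 0 & scores >= t) / n0, numeric(1)))
  tpr <- c(0, vapply(thr, function(t) sum(truth == 1 & scores >= t) / n1, numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
}
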