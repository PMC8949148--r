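#' Friedman rank test with Kendall's W
#'
#' Compares k methods over n paired blocks (here: the (repetition, fold)
#' cells of a repeated-CV protocol). Scores are ranked within each block
#' (ties get average ranks) and the chi-squared statistic
#' Q = 12n/(k(k+1)) * sum_j (Rbar_j - (k+1)/2)^2, divided by the standard
#' tie-correction factor, is referred to the chi-squared distribution with
#' k - 1 degrees of freedom. Kendall's coefficient of concordance is
#' derived as W = Q / (n (k - 1)).
#'
#' @param scores Numeric matrix, one row per block, one column per method.
#' @return An `amen_friedman`: list with `statistic` (Q), `p_value`, `df`,
#'   `kendall_w`, `n_blocks`, `k`, `mean_ranks`.
#' @examples
#' m <- rbind(c(1, 2, 3), c(1.1, 2.2, 3.1), c(0.5, 1.5, 2.5))
#' friedman_rank_test(m) # perfect concordance: Q = 6, W = 1
#' @export
friedman_rank_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (n < 2 || k < 2) abort("Need at least 2 blocks and 2 methods")
  r <- t(apply(scores, 1, rank))
  ties <- apply(scores, 1, function(row) {
    t <- table(row)
    sum(t^3 - t)
  })
  correction <- 1 - sum(ties) / (n * k * (k^2 - 1))
  if (correction <= 0) {
    abort("Every block is completely tied; the Friedman statistic is undefined")
  }
  rj <- colSums(r)
  q0 <- 12 / (n * k * (k + 1)) * sum(rj^2) - 3 * n * (k + 1)
  q <- q0 / correction
  structure(
    list(
      statistic = q,
      p_value = pchisq(q, df = k - 1, lower.tail = FALSE),
      df = k - 1,
      kendall_w = q / (n * (k - 1)),
      n_blocks = n, k = k,
      mean_ranks = colMeans(r)
    ),
    class = "amen_friedman"
  )
}

#' @export
print.amen_friedman <- function(x, ...) {
  cat(sprintf(
    "Friedman rank test: Q = %.4g, df = %d, p = %.4g; Kendall's W = %.3f (n = %d blocks, k = %d)\n",
    x$statistic, x$df, x$p_value, x$kendall_w, x$n_blocks, x$k
  ))
  invisible(x)
}

#' @describeIn friedman_rank_test One-row tibble of the test summary.
#' @param x An `amen_friedman` object.
#' @param ... Unused.
#' @export
tidy.amen_friedman <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value, df = x$df,
    kendall_w = x$kendall_w, n_blocks = x$n_blocks, k = x$k
  )
}

#' Nemenyi post hoc test
#'
#' All-pairs comparison of mean ranks after a significant Friedman test:
#' the standardized mean-rank difference |Rbar_i - Rbar_j| /
#' sqrt(k(k+1)/(12n)) is referred to the studentized range distribution
#' with k groups and infinite degrees of freedom. The p-value matrix is
#' symmetric with unit diagonal; values are reported uncapped (printing
#' may apply the conventional 0.900 display cap).
#'
#' @param scores Numeric matrix, one row per block, one column per method
#'   (at least 3 methods).
#' @return An `amen_nemenyi`: list with `p_values` (k x k matrix),
#'   `mean_ranks`, `n_blocks`, `k`.
#' @export
nemenyi_test <- function(scores) {
  scores <- as.matrix(scores)
  n <- nrow(scores)
  k <- ncol(scores)
  if (k < 3) abort("The Nemenyi test needs at least 3 methods")
  r <- t(apply(scores, 1, rank))
  rbar <- colMeans(r)
  se <- sqrt(k * (k + 1) / (12 * n))
  p <- matrix(1, k, k, dimnames = list(colnames(scores), colnames(scores)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      stat <- abs(rbar[i] - rbar[j]) / se
      pv <- ptukey(stat, nmeans = k, df = Inf, lower.tail = FALSE)
      p[i, j] <- p[j, i] <- min(max(pv, 0), 1)
    }
  }
  structure(
    list(p_values = p, mean_ranks = rbar, n_blocks = n, k = k),
    class = "amen_nemenyi"
  )
}

#' @export
#' @param display_cap Cap p-values at this value for display (use 0.9 for
#'   the conventional capped table); `NULL` = uncapped.
#' @rdname nemenyi_test
print.amen_nemenyi <- function(x, display_cap = NULL, ...) {
  cat(sprintf("Nemenyi post hoc test (k = %d, n = %d blocks)\n", x$k, x$n_blocks))
  p <- x$p_values
  if (!is.null(display_cap)) p <- pmin(p, display_cap)
  print(round(p, 3))
  invisible(x)
}

#' @describeIn nemenyi_test Long tibble of the pairwise p-values
#'   (upper triangle).
#' @param x An `amen_nemenyi` object.
#' @param ... Unused.
#' @export
tidy.amen_nemenyi <- function(x, ...) {
  nm <- colnames(x$p_values) %||% paste0("method", seq_len(x$k))
  pairs <- which(upper.tri(x$p_values), arr.ind = TRUE)
  tibble(
    method_a = nm[pairs[, 1]], method_b = nm[pairs[, 2]],
    p_value = x$p_values[pairs]
  )
}

#' Wilcoxon signed-rank test for paired scores
#'
#' Zero differences are dropped; the absolute differences are ranked with
#' average ranks for ties; the statistic W is the sum of the ranks of the
#' positive differences. For up to `exact_limit` nonzero pairs the p-value
#' is exact, by enumeration of the 2^n sign patterns (implemented as a
#' convolution over the doubled ranks, so ties are handled exactly);
#' beyond that, the normal approximation with continuity correction and
#' the tie-adjusted variance is used.
#'
#' @param a,b Paired numeric vectors (`b` defaults to zeros, i.e. `a` are
#'   differences).
#' @param alternative `"greater"` (a tends to exceed b), `"less"`, or
#'   `"two_sided"`.
#' @param exact_limit Largest number of nonzero pairs for which the exact
#'   null distribution is enumerated.
#' @return An `amen_wilcoxon`: list with `statistic` (W), `p_value`,
#'   `n` (nonzero pairs), `alternative`, `method`.
#' @examples
#' wilcoxon_signed_rank(c(1, 2, 3, 4, 5), rep(0, 5), "greater") # W = 15, p = 1/32
#' @export
wilcoxon_signed_rank <- function(a, b = NULL,
                                 alternative = c("greater", "less", "two_sided"),
                                 exact_limit = 20L) {
  alternative <- match.arg(alternative)
  b <- b %||% numeric(length(a))
  if (length(a) != length(b)) abort("'a' and 'b' must have equal length")
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) abort("All paired differences are zero; the test is undefined")
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_limit) {
    method <- "exact enumeration"
    # doubled ranks are integers even with average ranks
    w2 <- as.integer(round(2 * r))
    total <- sum(w2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (wi in w2) {
      idx <- (total + 1):(wi + 1)
      f[idx] <- f[idx] + f[idx - wi]
    }
    sums <- 0:total
    wobs <- round(2 * w)
    p_ge <- sum(f[sums >= wobs - 1e-9]) / 2^n
    p_le <- sum(f[sums <= wobs + 1e-9]) / 2^n
  } else {
    method <- "normal approximation"
    mu <- n * (n + 1) / 4
    tie_term <- {
      t <- table(r)
      sum(t^3 - t) / 48
    }
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tie_term)
    p_ge <- pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- pnorm((w - mu + 0.5) / sigma)
  }
  p <- switch(alternative,
    greater = p_ge,
    less = p_le,
    two_sided = min(1, 2 * min(p_ge, p_le))
  )
  structure(
    list(statistic = w, p_value = p, n = n, alternative = alternative, method = method),
    class = "amen_wilcoxon"
  )
}

#' @export
print.amen_wilcoxon <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank (%s, %s): W = %g, p = %.5g (n = %d nonzero pairs)\n",
    x$alternative, x$method, x$statistic, x$p_value, x$n
  ))
  invisible(x)
}

#' @describeIn wilcoxon_signed_rank One-row tibble of the test summary.
#' @param x An `amen_wilcoxon` object.
#' @param ... Unused.
#' @export
tidy.amen_wilcoxon <- function(x, ...) {
  tibble(
    statistic = x$statistic, p_value = x$p_value, n = x$n,
    alternative = x$alternative, method = x$method
  )
}

#' Matched-pairs rank-biserial correlation
#'
#' Effect size companion of the Wilcoxon signed-rank test: the difference
#' between the proportions of favorable and unfavorable evidence,
#' (W+ - W-) / (W+ + W-), computed on the nonzero paired differences.
#' Ranges over \[-1, 1\].
#'
#' @param a,b Paired numeric vectors.
#' @return A single number in \[-1, 1\].
#' @export
effect_rank_biserial <- function(a, b) {
  if (length(a) != length(b)) abort("'a' and 'b' must have equal length")
  d <- a - b
  d <- d[d != 0]
  if (length(d) == 0) abort("All paired differences are zero; the effect size is undefined")
  r <- rank(abs(d))
  (sum(r[d > 0]) - sum(r[d < 0])) / sum(r)
}

#' Common-language effect size
#'
#' Probability that a score sampled at random from `a` exceeds one sampled
#' at random from `b`, with ties counted half: an all-pairs comparison,
#' not a paired one.
#'
#' @param a,b Nonempty numeric vectors.
#' @return A single number in \[0, 1\].
#' @export
effect_cles <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("'a' and 'b' must be nonempty")
  mean(outer(a, b, ">") + 0.5 * outer(a, b, "=="))
}

#' McNemar test on the discordant predictions of two classifiers
#'
#' For one binary label, each instance is marked correct or wrong under
#' each classifier; the discordant counts are b (A correct, B wrong) and
#' c (A wrong, B correct). The statistic is (|b - c| - 1)^2 / (b + c)
#' with the continuity correction (default) or (b - c)^2 / (b + c)
#' without, referred to chi-squared with 1 df. The odds ratio b/c serves
#' as the effect size; when either count is zero both get the Haldane
#' +0.5 correction.
#'
#' @param truth Binary 0/1 vector of true labels for one class.
#' @param pred_a,pred_b Binary predictions of the two classifiers.
#' @param continuity Apply the continuity correction (default `TRUE`).
#' @return An `amen_mcnemar`: list with `statistic`, `p_value`,
#'   `odds_ratio`, `b_count`, `c_count`, `continuity`.
#' @examples
#' # b = 10, c = 2: chi2 = 49/12 corrected, 64/12 uncorrected, OR = 5
#' @export
mcnemar_paired <- function(truth, pred_a, pred_b, continuity = TRUE) {
  if (length(truth) != length(pred_a) || length(truth) != length(pred_b)) {
    abort("'truth', 'pred_a' and 'pred_b' must have equal length")
  }
  correct_a <- as.integer(pred_a) == as.integer(truth)
  correct_b <- as.integer(pred_b) == as.integer(truth)
  b <- sum(correct_a & !correct_b)
  c <- sum(!correct_a & correct_b)
  if (b + c == 0) abort("No discordant pairs; the McNemar test is undefined")
  stat <- if (continuity) (abs(b - c) - 1)^2 / (b + c) else (b - c)^2 / (b + c)
  or <- if (b == 0 || c == 0) (b + 0.5) / (c + 0.5) else b / c
  structure(
    list(
      statistic = stat,
      p_value = pchisq(stat, df = 1, lower.tail = FALSE),
      odds_ratio = or, b_count = b, c_count = c,
      continuity = continuity
    ),
    class = "amen_mcnemar"
  )
}

#' @export
print.amen_mcnemar <- function(x, ...) {
  cat(sprintf(
    "McNemar test (%s continuity correction): chi2 = %.4g, p = %.4g; OR = %.3g (b = %d, c = %d)\n",
    if (x$continuity) "with" else "without",
    x$statistic, x$p_value, x$odds_ratio, x$b_count, x$c_count
  ))
  invisible(x)
}

#' @describeIn mcnemar_paired Per-class McNemar comparison for the two
#'   amenability labels; returns a tibble with one row per class. A class
#'   with no discordant predictions gets `NA` statistics (with its zero
#'   discordant counts) instead of an error, so a batch comparison never
#'   aborts on one degenerate class.
#' @param labels Truth matrix/data frame with binary `GC`, `LC` columns.
#' @param pred_a,pred_b Label matrices/data frames of the two classifiers.
#' @export
mcnemar_labels <- function(labels, pred_a, pred_b, continuity = TRUE) {
  yt <- as_label_matrix(labels, "labels")
  pa <- as_label_matrix(pred_a, "pred_a")
  pb <- as_label_matrix(pred_b, "pred_b")
  purrr::map_dfr(seq_along(LABEL_COLS), function(j) {
    m <- tryCatch(
      mcnemar_paired(yt[, j], pa[, j], pb[, j], continuity = continuity),
      error = function(e) {
        warn(sprintf("%s class: %s", LABEL_COLS[j], conditionMessage(e)))
        list(statistic = NA_real_, p_value = NA_real_, odds_ratio = NA_real_, b_count = 0L, c_count = 0L)
      }
    )
    tibble(
      class = LABEL_COLS[j], statistic = m$statistic, p_value = m$p_value,
      odds_ratio = m$odds_ratio, b_count = m$b_count, c_count = m$c_count,
      continuity = continuity
    )
  })
}
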