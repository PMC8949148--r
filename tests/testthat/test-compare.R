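test_that("Friedman statistic matches the closed form under perfect concordance", {
  m <- rbind(c(1, 2, 3), c(0.1, 0.2, 0.3), c(5, 6, 7))
  fr <- friedman_rank_test(m)
  expect_equal(fr$statistic, 6)
  expect_equal(fr$kendall_w, 1)
  expect_equal(fr$df, 2)
  expect_equal(fr$p_value, pchisq(6, 2, lower.tail = FALSE))
})

test_that("Friedman agrees with the base-R implementation including ties", {
  withr::with_seed(8, {
    for (i in 1:10) {
      m <- matrix(round(rnorm(12 * 4), sample(1:3, 1)), nrow = 12)
      ref <- stats::friedman.test(m)
      fr <- friedman_rank_test(m)
      expect_equal(fr$statistic, unname(ref$statistic))
      expect_equal(fr$p_value, unname(ref$p.value))
    }
  })
  # rank invariance: permuting columns leaves Q unchanged
  m <- matrix(runif(40), nrow = 10)
  expect_equal(friedman_rank_test(m)$statistic, friedman_rank_test(m[, c(3, 1, 4, 2)])$statistic)
  expect_error(friedman_rank_test(matrix(1, 4, 3)), "tied")
})

test_that("two-method Friedman reduces to the sign-test relationship", {
  withr::with_seed(4, {
    for (i in 1:10) {
      n <- sample(4:12, 1)
      a <- rnorm(n)
      b <- a + sample(c(-1, 1), n, replace = TRUE) * runif(n, 0.1, 1)
      fr <- friedman_rank_test(cbind(a, b))
      n_plus <- sum(b > a)
      expect_equal(fr$statistic, (n_plus - (n - n_plus))^2 / n)
    }
  })
})

test_that("Nemenyi p-values are symmetric and monotone in the mean-rank gap", {
  withr::with_seed(15, {
    m <- matrix(rnorm(20 * 4), nrow = 20) + rep(c(0, 0.3, 0.8, 1.5), each = 20)
  })
  nm <- nemenyi_test(m)
  expect_equal(nm$p_values, t(nm$p_values))
  expect_equal(diag(nm$p_values), rep(1, 4))
  # identical columns give the maximum p-value
  m2 <- cbind(m[, 1], m[, 1], m[, 3])
  expect_equal(nemenyi_test(m2)$p_values[1, 2], 1)
  # smaller mean-rank gap never yields a smaller p
  gaps <- abs(outer(nm$mean_ranks, nm$mean_ranks, "-"))
  idx <- which(upper.tri(gaps), arr.ind = TRUE)
  o <- order(gaps[idx])
  expect_true(all(diff(nm$p_values[idx][o]) <= 1e-12))
  # direct evaluation of the studentized-range construction
  k <- 4
  n <- 20
  se <- sqrt(k * (k + 1) / (12 * n))
  expect_equal(
    nm$p_values[1, 4],
    ptukey(gaps[1, 4] / se, nmeans = k, df = Inf, lower.tail = FALSE)
  )
  expect_error(nemenyi_test(m[, 1:2]), "at least 3")
  # relabeling methods permutes the matrix consistently
  perm <- c(2, 4, 1, 3)
  expect_equal(unname(nemenyi_test(m[, perm])$p_values), unname(nm$p_values[perm, perm]))
})

test_that("Wilcoxon signed-rank matches exact enumeration on small samples", {
  wx <- wilcoxon_signed_rank(1:5, rep(0, 5), alternative = "greater")
  expect_equal(wx$statistic, 15)
  expect_equal(wx$p_value, 1 / 32)
  expect_equal(wx$n, 5)
  # swapping the members maps W to n(n+1)/2 - W and greater <-> less
  withr::with_seed(6, {
    a <- rnorm(8)
    b <- rnorm(8)
  })
  g <- wilcoxon_signed_rank(a, b, "greater")
  l <- wilcoxon_signed_rank(b, a, "less")
  expect_equal(g$statistic + wilcoxon_signed_rank(b, a, "greater")$statistic, 8 * 9 / 2)
  expect_equal(g$p_value, l$p_value)
  expect_error(wilcoxon_signed_rank(a, a), "zero")
})

test_that("Wilcoxon agrees with base R on tie-free data", {
  withr::with_seed(9, {
    for (i in 1:10) {
      n <- sample(6:15, 1)
      a <- rnorm(n)
      b <- rnorm(n)
      mine <- wilcoxon_signed_rank(a, b, "greater")
      ref <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE, alternative = "greater", exact = TRUE))
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, unname(ref$p.value))
    }
  })
})

test_that("exact and approximate Wilcoxon p-values agree within 0.01 at n = 20", {
  withr::with_seed(13, {
    for (i in 1:20) {
      d <- rnorm(20, mean = runif(1, -0.5, 0.5))
      exact <- wilcoxon_signed_rank(d, alternative = "two_sided", exact_limit = 20)
      approx <- wilcoxon_signed_rank(d, alternative = "two_sided", exact_limit = 5)
      expect_equal(exact$method, "exact enumeration")
      expect_equal(approx$method, "normal approximation")
      expect_lt(abs(exact$p_value - approx$p_value), 0.01)
    }
  })
})

test_that("rank-biserial and common-language effect sizes match hand calculations", {
  expect_equal(effect_rank_biserial(1:4, rep(0, 4)), 1)
  expect_equal(effect_rank_biserial(c(1, -1), c(0, 0)), 0)
  # differences (+1, +2, +3, -4): rank sums 6 vs 4 -> 0.2
  expect_equal(effect_rank_biserial(c(1, 2, 3, -4), rep(0, 4)), 0.2)

  expect_equal(effect_cles(c(2, 3), c(0, 1)), 1)
  expect_equal(effect_cles(c(1, 2), c(1, 2)), 0.5)
  expect_equal(effect_cles(c(1, 2), c(2, 3)), 0.125)
  # complement identity for tie-free inputs
  withr::with_seed(21, {
    a <- rnorm(15)
    b <- rnorm(12)
  })
  expect_equal(effect_cles(a, b) + effect_cles(b, a), 1)
})

test_that("McNemar arithmetic, invariances and odds-ratio corrections hold", {
  truth <- rep(1, 20)
  pred_a <- c(rep(1, 18), 0, 0) # wrong on 2
  pred_b <- c(rep(0, 10), rep(1, 8), 1, 1) # wrong on the first 10
  # b = |A right, B wrong| = 10, c = |A wrong, B right| = 2
  un <- mcnemar_paired(truth, pred_a, pred_b, continuity = FALSE)
  expect_equal(un$b_count, 10)
  expect_equal(un$c_count, 2)
  expect_equal(un$statistic, 64 / 12)
  expect_equal(un$odds_ratio, 5)
  co <- mcnemar_paired(truth, pred_a, pred_b, continuity = TRUE)
  expect_equal(co$statistic, 49 / 12)
  expect_equal(co$p_value, pchisq(49 / 12, 1, lower.tail = FALSE))
  # agreement with the base-R continuity-corrected test
  ref <- stats::mcnemar.test(matrix(c(5, 10, 2, 3), 2), correct = TRUE)
  expect_equal(co$statistic, unname(ref$statistic))

  # swapping classifiers preserves chi2 and inverts the odds ratio
  sw <- mcnemar_paired(truth, pred_b, pred_a, continuity = FALSE)
  expect_equal(sw$statistic, un$statistic)
  expect_equal(sw$odds_ratio, 1 / un$odds_ratio)

  # b = c: zero statistic, unit odds ratio
  even <- mcnemar_paired(c(1, 1, 0, 0), c(1, 0, 1, 0), c(0, 1, 0, 1), continuity = FALSE)
  expect_equal(even$statistic, 0)
  expect_equal(even$odds_ratio, 1)
  # Haldane correction when a discordant count is zero
  h <- mcnemar_paired(rep(1, 5), rep(1, 5), c(0, 0, 1, 1, 1))
  expect_equal(h$odds_ratio, 2.5 / 0.5)
  expect_error(mcnemar_paired(c(1, 0), c(1, 0), c(1, 0)), "discordant")

  # per-class wrapper returns one row per label
  yl <- data.frame(GC = truth, LC = truth)
  tab <- mcnemar_labels(yl, data.frame(GC = pred_a, LC = pred_a), data.frame(GC = pred_b, LC = pred_b))
  expect_equal(tab$class, c("GC", "LC"))
  expect_equal(tab$statistic, rep(49 / 12, 2))
})

test_that("repeated CV pairs methods on identical folds and is reproducible", {
  sim <- tiny_sim(seed = 40, n = 200, red = 0, qc = 0, nnoise = 2)
  methods <- list(
    rule = cv_method_rule(),
    tree = cv_method_tree(max_depth = 3)
  )
  cv1 <- repeated_cv(sim$data, sim$labels, methods, folds = 4, repetitions = 2, seed = 5)
  cv2 <- repeated_cv(sim$data, sim$labels, methods, folds = 4, repetitions = 2, seed = 5)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$fold_assignments, cv2$fold_assignments)
  # fold assignments are shared across methods and recorded per repetition
  expect_length(cv1$fold_assignments, 2)
  expect_true(all(vapply(cv1$fold_assignments, function(f) all(sort(unique(f)) == 1:4), logical(1))))
  m <- cv_score_matrix(cv1)
  expect_equal(dim(m), c(8, 2))
  expect_true(all(m >= 0 & m <= 1))
  expect_error(repeated_cv(sim$data, sim$labels, list(cv_method_rule()), folds = 4), "named")
})

test_that("a deterministic constant classifier varies only with fold composition", {
  sim <- tiny_sim(seed = 44, n = 200, red = 0, qc = 0, nnoise = 1)
  const_method <- structure(
    list(
      kind = "const", features = NULL,
      fit = function(data, labels, seed) NULL,
      predict = function(model, data) {
        tibble::tibble(GC = rep(1L, nrow(data)), LC = rep(1L, nrow(data)))
      }
    ),
    class = "amen_cv_method"
  )
  cv <- repeated_cv(sim$data, sim$labels, list(const = const_method),
    folds = 5, repetitions = 4, seed = 2
  )
  rep_means <- dplyr::summarise(
    dplyr::group_by(cv$scores, repetition),
    m = mean(accuracy), .groups = "drop"
  )$m
  # the mean over folds is the full-sample score in every repetition
  expect_lt(stats::var(rep_means), stats::var(cv$scores$accuracy) + 1e-12)
  expect_equal(max(rep_means) - min(rep_means), 0, tolerance = 1e-12)
})
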