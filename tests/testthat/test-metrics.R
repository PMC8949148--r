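test_that("label-based accuracy matches hand-computed Jaccard examples", {
  # single row: truth {GC, LC}, pred {GC} -> 1/2
  expect_equal(
    as.numeric(label_accuracy(data.frame(GC = 1, LC = 1), data.frame(GC = 1, LC = 0))),
    0.5
  )
  # identity
  truth <- data.frame(GC = c(1, 0, 1, 0), LC = c(1, 1, 0, 0))
  expect_equal(as.numeric(label_accuracy(truth, truth)), 1)
  # three rows: ({GC},{LC}), ({GC,LC},{GC,LC}), ({LC},{GC,LC}) -> (0 + 1 + 1/2)/3
  truth3 <- data.frame(GC = c(1, 1, 0), LC = c(0, 1, 1))
  pred3 <- data.frame(GC = c(0, 1, 1), LC = c(1, 1, 1))
  expect_equal(as.numeric(label_accuracy(truth3, pred3)), 0.5)
  expect_equal(exact_match_ratio(truth3, pred3), 1 / 3)
  # both sets empty scores 1 and is flagged
  both_empty <- data.frame(GC = 0, LC = 0)
  res <- label_accuracy(both_empty, both_empty)
  expect_equal(as.numeric(res), 1)
  expect_equal(attr(res, "n_empty"), 1)
  expect_error(label_accuracy(truth3, truth3[1:2, ]), "same number of rows")
})

test_that("accuracy equals the brute-force set-arithmetic oracle on random matrices", {
  withr::with_seed(42, {
    for (i in 1:200) {
      n <- sample(1:25, 1)
      truth <- matrix(rbinom(2 * n, 1, 0.5), ncol = 2, dimnames = list(NULL, c("GC", "LC")))
      pred <- matrix(rbinom(2 * n, 1, 0.5), ncol = 2, dimnames = list(NULL, c("GC", "LC")))
      expect_equal(as.numeric(label_accuracy(truth, pred)), oracle_label_accuracy(truth, pred))
      # exact match never exceeds the Jaccard accuracy
      expect_lte(exact_match_ratio(truth, pred), as.numeric(label_accuracy(truth, pred)))
    }
  })
})

test_that("accuracy collapses to exact match when every row has exactly one label", {
  withr::with_seed(7, {
    for (i in 1:20) {
      n <- 30
      gc_t <- rbinom(n, 1, 0.5)
      gc_p <- rbinom(n, 1, 0.5)
      truth <- data.frame(GC = gc_t, LC = 1 - gc_t) # exactly one true label
      pred <- data.frame(GC = gc_p, LC = 1 - gc_p) # exactly one predicted label
      expect_equal(as.numeric(label_accuracy(truth, pred)), exact_match_ratio(truth, pred))
    }
  })
})

test_that("classification report reproduces confusion-table arithmetic", {
  # perfect predictions (every row has at least one label) -> all rates 100
  truth <- data.frame(GC = c(1, 0, 1, 1), LC = c(1, 1, 0, 1))
  rep_perfect <- classification_report(truth, truth)
  td <- tidy(rep_perfect)
  expect_true(all(td$precision == 100))
  expect_true(all(td$recall == 100))

  # single class with TP=2 FP=1 FN=1 TN=6: precision = recall = F1 = 66.67, accuracy 80
  gc_t <- c(1, 1, 1, rep(0, 7))
  gc_p <- c(1, 1, 0, 1, rep(0, 6))
  rep1 <- classification_report(
    data.frame(GC = gc_t, LC = gc_t), data.frame(GC = gc_p, LC = gc_p)
  )
  gc_row <- tidy(rep1)[tidy(rep1)$row == "GC class", ]
  expect_equal(gc_row$precision, 66.67)
  expect_equal(gc_row$recall, 66.67)
  expect_equal(gc_row$f1, 66.67)
  expect_equal(gc_row$accuracy, 80.00)
  # confusion counts partition n per class
  expect_true(all(rowSums(rep1$per_class[, c("tp", "fp", "fn", "tn")]) == rep1$n))

  # micro pools counts; macro averages defined-as-0 precision
  # GC: TP=2, FP=0; LC: TP=0, FP=2 (and FN=0 for LC so recall flagged too)
  truth2 <- data.frame(GC = c(1, 1, 0, 0), LC = c(0, 0, 0, 0))
  pred2 <- data.frame(GC = c(1, 1, 0, 0), LC = c(0, 0, 1, 1))
  rep2 <- classification_report(truth2, pred2)
  av <- rep2$averages
  expect_equal(av$precision[av$average == "micro"], 0.5) # pooled 2/(2+2)
  expect_equal(av$precision[av$average == "macro"], 0.5) # (1 + 0)/2
  expect_true(length(rep2$flags) > 0)
  # macro precision is the unweighted mean of class precisions
  expect_equal(
    av$precision[av$average == "macro"],
    mean(rep2$per_class$precision)
  )
})

test_that("rank-statistic AUC matches enumeration and the trapezoidal oracle", {
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(2, 3, 0, 1)), 1) # perfect separation
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5) # all tied
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "positive and one negative")

  withr::with_seed(11, {
    for (i in 1:100) {
      n <- sample(5:40, 1)
      truth <- c(0, 1, rbinom(n, 1, 0.5))
      scores <- round(rnorm(n + 2), sample(0:2, 1)) # rounding induces ties
      expect_equal(roc_auc(truth, scores), oracle_trapezoid_auc(truth, scores),
        tolerance = 1e-12
      )
    }
    # complement identity in the absence of ties
    truth <- c(rep(1, 10), rep(0, 10))
    scores <- sample(seq(0.01, 1, length.out = 20))
    expect_equal(roc_auc(truth, scores) + roc_auc(truth, -scores), 1)
  })
})

test_that("ROC points trace a valid monotone step curve", {
  withr::with_seed(3, {
    pts <- roc_points(rbinom(50, 1, 0.4) + c(1, 0, rep(0, 48)) * 0, runif(50))
  })
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_equal(pts$fpr[1], 0)
  expect_equal(pts$tpr[nrow(pts)], 1)
})
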