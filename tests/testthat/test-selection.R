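test_that("quasi-constant filter removes by modal frequency, NA counting as a value", {
  n <- 1000
  d <- tibble::tibble(
    mostly995 = c(rep(1, 995), 2:6),
    mostly980 = c(rep(1, 980), seq_len(20) + 1),
    constant = rep(3.3, n),
    mostlyNA = c(rep(NA_real_, 995), 1:5),
    spread = seq_len(n)
  )
  kept <- filter_quasi_constant(d, threshold = 0.99)
  expect_equal(kept, c("mostly980", "spread"))
})

test_that("correlation filter drops monotone copies and keeps a pairwise-clean set", {
  withr::with_seed(2, {
    x1 <- runif(300)
    d <- tibble::tibble(
      X1 = x1,
      X2 = 2 * x1 + 7, # affine copy, r_s = 1
      X3 = exp(x1), # monotone nonlinear copy, r_s = 1
      X4 = runif(300)
    )
  })
  expect_equal(filter_correlation(d, 0.9), c("X1", "X4"))

  # three mutually correlated columns: only the first survives column order
  withr::with_seed(3, {
    a <- runif(500)
    d2 <- tibble::tibble(A = a, B = a + rnorm(500, 0, 0.01), C = a^3, D = rnorm(500))
  })
  kept <- filter_correlation(d2, 0.9)
  expect_equal(kept, c("A", "D"))
  # brute-force postcondition: no retained pair at or above the threshold
  R <- abs(cor(as.matrix(d2[kept]), method = "spearman"))
  diag(R) <- 0
  expect_lt(max(R), 0.9)
})

test_that("correlation filter postcondition holds on random correlated tables", {
  withr::with_seed(19, {
    for (i in 1:10) {
      p <- sample(4:10, 1)
      base <- matrix(rnorm(120 * 3), ncol = 3)
      X <- sapply(seq_len(p), function(j) {
        base[, sample(3, 1)] + rnorm(120, 0, runif(1, 0.01, 2))
      })
      colnames(X) <- paste0("V", seq_len(p))
      kept <- filter_correlation(as.data.frame(X), 0.9)
      R <- abs(cor(X[, kept, drop = FALSE], method = "spearman"))
      diag(R) <- 0
      expect_lt(max(R, 0), 0.9)
    }
  })
})

test_that("label-relevance keep rule retains the member closer to the labels", {
  withr::with_seed(5, {
    b <- runif(400)
    d <- tibble::tibble(A = b + rnorm(400, 0, 0.02), B = b)
    labels <- tibble::tibble(GC = as.integer(b > 0.5), LC = as.integer(b > 0.25))
  })
  # B drives the labels; under label_relevance it must survive although later
  expect_equal(filter_correlation(d, 0.9, keep_rule = "label_relevance", labels = labels), "B")
  expect_equal(filter_correlation(d, 0.9), "A") # column order keeps the earlier
  expect_error(filter_correlation(d, 0.9, keep_rule = "label_relevance"), "labels")
})

test_that("importance cutoff arithmetic is inclusive with an empty-set guard", {
  expect_equal(importance_keep(c(a = 0.5, b = 0.3, c = 0.2), 1.5), "a")
  expect_warning(
    kept <- importance_keep(c(a = 0.25, b = 0.25, c = 0.25, d = 0.25), 1.5),
    "single most important"
  )
  expect_equal(kept, "a")
  expect_equal(importance_keep(c(a = 0.25, b = 0.25), 1), c("a", "b"))
})

test_that("importance filter keeps planted informative features and rejects degenerate labels", {
  sim <- tiny_sim(seed = 6, n = 800, nnoise = 40)
  # the importance filter runs after the correlation filter, i.e. without
  # redundant copies that would split a parent's importance credit
  candidates <- setdiff(setdiff(names(sim$data), ".id"), sim$truth$redundant)
  kept <- filter_importance(sim$data, sim$labels[, c("GC", "LC")],
    features = candidates, n_trees = 40, seed = 7
  )
  expect_true(all(sim$truth$informative %in% kept))
  expect_length(intersect(kept, sim$truth$noise), 0)
  expect_named(attr(kept, "importances"))
  degenerate <- tibble::tibble(GC = rep(1L, 800), LC = rep(0L, 800))
  expect_error(
    filter_importance(sim$data, degenerate, n_trees = 25, seed = 7),
    "Degenerate"
  )
})

test_that("recursive elimination returns a full curve and is deterministic", {
  sim <- tiny_sim(seed = 9, n = 300, red = 0, qc = 0, nnoise = 4)
  feats <- c(sim$truth$informative, sim$truth$noise)
  r1 <- select_rfe(sim$data, sim$labels[, c("GC", "LC")],
    features = feats,
    folds = 3, n_trees = 15, seed = 5
  )
  expect_equal(r1$score_curve$n_features, seq_along(feats))
  expect_true(all(r1$retained %in% feats))
  r2 <- select_rfe(sim$data, sim$labels[, c("GC", "LC")],
    features = feats,
    folds = 3, n_trees = 15, seed = 5
  )
  expect_identical(r1$score_curve$accuracy, r2$score_curve$accuracy)
  expect_identical(r1$retained, r2$retained)

  # degenerate single-feature input
  r3 <- select_rfe(sim$data, sim$labels[, c("GC", "LC")],
    features = "logP",
    folds = 3, n_trees = 10, seed = 1
  )
  expect_equal(nrow(r3$score_curve), 1)
  expect_equal(r3$retained, "logP")
  expect_error(
    select_rfe(sim$data, sim$labels[, c("GC", "LC")], folds = 301, n_trees = 5),
    "cannot exceed"
  )
})

test_that("sequential forward selection finds a dominant feature and is deterministic", {
  withr::with_seed(12, {
    x <- rnorm(200)
    d <- tibble::tibble(signal = x, junk1 = rnorm(200), junk2 = rnorm(200))
    labels <- tibble::tibble(GC = as.integer(x > 0), LC = as.integer(x > 1))
  })
  lists <- select_sequential_forward(d, labels,
    k = 1, folds = 3, repetitions = 3,
    n_trees = 15, seed = 3
  )
  expect_true(all(vapply(lists, function(l) l == "signal", logical(1))))
  again <- select_sequential_forward(d, labels,
    k = 1, folds = 3, repetitions = 3,
    n_trees = 15, seed = 3
  )
  expect_identical(lists, again)
  expect_error(
    select_sequential_forward(d, labels, k = 10, folds = 3),
    "cannot exceed"
  )
})

test_that("overlap consensus counts, filters and caps deterministically", {
  lists5 <- replicate(5, letters[1:8], simplify = FALSE)
  expect_equal(sort(select_overlap(lists5, min_count = 3)), letters[1:8])

  # a feature present in only 2 of 5 lists is excluded at min_count 3
  lists <- list(c("a", "b"), c("a", "b"), c("a", "z"), c("a", "z"), c("a", "q"))
  out <- select_overlap(lists, min_count = 3)
  expect_equal(as.character(out), "a")
  ov <- attr(out, "overlap")
  expect_equal(ov$count[ov$feature == "z"], 2L)

  # cap: higher count wins, then earlier mean selection position
  lists2 <- list(
    c("a", "b", "c"), c("a", "b", "c"), c("a", "b", "c"),
    c("c", "b", "a"), c("b", "a", "c")
  )
  capped <- select_overlap(lists2, min_count = 1, cap = 2, feature_order = c("a", "b", "c"))
  expect_length(capped, 2)
  expect_true(all(c("a", "b") %in% capped)) # c has the latest mean position
  expect_error(select_overlap(list()), "at least one")
})

test_that("the staged pipeline nests its retained sets and is reproducible", {
  sim <- tiny_sim(seed = 14, n = 400, red = 2, qc = 2, nnoise = 8)
  cfg <- tiny_selection_config(seed = 14)
  trace <- suppressMessages(run_selection_pipeline(sim$data, sim$labels, cfg))
  counts <- trace$stages$n_retained
  expect_equal(trace$stages$stage[1], "initial")
  expect_equal(counts[1], 3 + 2 + 2 + 8)
  expect_true(all(diff(counts[1:4]) < 0)) # filters strictly shrink here
  # nestedness with respect to each stage's input set
  st <- trace$stages$features
  expect_true(all(st[[2]] %in% st[[1]]))
  expect_true(all(st[[3]] %in% st[[2]]))
  expect_true(all(st[[4]] %in% st[[3]]))
  expect_true(all(st[[5]] %in% st[[4]])) # rfecv within the importance set
  expect_true(all(st[[6]] %in% st[[4]])) # final from the SFS input (importance set)
  expect_length(trace$sfs_lists, cfg$sfs_repetitions)

  # configuration JSON round-trip gives the identical trace
  path <- withr::local_tempfile(fileext = ".json")
  write_selection_config(cfg, path)
  trace2 <- suppressMessages(run_selection_pipeline(sim$data, sim$labels, read_selection_config(path)))
  expect_identical(trace$stages, trace2$stages)
  expect_identical(trace$final, trace2$final)

  expect_error(
    suppressMessages(run_selection_pipeline(sim$data[, ".id", drop = FALSE], sim$labels, cfg)),
    "Empty"
  )
})
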