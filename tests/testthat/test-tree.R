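test_that("a depth-1 tree separates an axis-aligned binary concept exactly", {
  sep <- make_separable(100)
  fit <- fit_amen_tree(sep$data, sep$labels, max_depth = 1)
  expect_equal(as.numeric(label_accuracy(sep$labels, predict(fit, sep$data))), 1)
  root <- fit$nodes[1, ]
  expect_equal(root$feature, "x")
  expect_gt(root$threshold, -0.01)
  expect_lt(root$threshold, 0.01)
  # same data, same seed -> identical node array
  fit2 <- fit_amen_tree(sep$data, sep$labels, max_depth = 1)
  expect_identical(fit$nodes, fit2$nodes)
})

test_that("scores are leaf proportions and classification thresholds at 0.5", {
  sep <- make_separable(80)
  fit <- fit_amen_tree(sep$data, sep$labels, max_depth = 2)
  sc <- predict(fit, sep$data, type = "score")
  expect_true(all(sc$GC >= 0 & sc$GC <= 1))
  expect_true(all(sc$LC >= 0 & sc$LC <= 1))
  # pure leaves: scores are 0/1 and equal the class predictions
  expect_true(all(sc$GC %in% c(0, 1)))
  cls <- predict(fit, sep$data)
  expect_equal(cls$GC, as.integer(sc$GC))
  # duplicated row duplicates its prediction
  two <- sep$data[c(5, 5), ]
  expect_equal(predict(fit, two)[1, ], predict(fit, two)[2, ])
  # unused columns are ignored
  extra <- dplyr::mutate(sep$data, other = seq_len(nrow(sep$data)))
  expect_equal(predict(fit, extra), cls)
})

test_that("ties at a score of exactly 0.5 classify as positive", {
  # force a mixed leaf: depth 0 with half-positive labels
  d <- tibble::tibble(x = 1:4)
  labels <- tibble::tibble(GC = c(1L, 1L, 0L, 0L), LC = c(0L, 0L, 0L, 0L))
  fit <- fit_amen_tree(d, labels, max_depth = 0)
  sc <- predict(fit, d, type = "score")
  expect_equal(sc$GC, rep(0.5, 4))
  expect_equal(predict(fit, d)$GC, rep(1L, 4))
})

test_that("training accuracy is monotone non-decreasing in depth", {
  sim <- tiny_sim(seed = 23, n = 500, red = 0, qc = 0, nnoise = 2)
  accs <- vapply(1:6, function(d) {
    fit <- fit_amen_tree(sim$data, sim$labels, max_depth = d)
    as.numeric(label_accuracy(sim$labels, predict(fit, sim$data)))
  }, numeric(1))
  expect_true(all(diff(accs) >= -1e-12))
})

test_that("non-finite feature values are diagnosed with the offending column", {
  d <- tibble::tibble(x = c(1, NA, 3), y = c(1, 2, 3))
  labels <- tibble::tibble(GC = c(1L, 0L, 1L), LC = c(0L, 1L, 0L))
  expect_error(fit_amen_tree(d, labels), "Non-finite.*x")
  fit <- fit_amen_tree(d["y"], labels)
  expect_error(predict(fit, tibble::tibble(z = 1)), "not found")
})

test_that("grid search evaluates exhaustively with deterministic tie-breaks", {
  sep <- make_separable(60)
  g1 <- tree_grid(
    criterion = "gini", max_features = "none",
    min_samples_split = 2, max_depth = 3, min_samples_leaf = 1
  )
  gs1 <- grid_search_tree(sep$data, sep$labels, grid = g1, folds = 3)
  expect_equal(nrow(gs1$results), 1)
  expect_equal(gs1$best_params$max_depth, 3L)
  expect_gte(gs1$best_score, 0.95) # boundary rows may fall on the wrong fold

  # two depths scoring equally: the smaller depth wins
  g2 <- tree_grid(
    criterion = "gini", max_features = "none",
    min_samples_split = 2, max_depth = c(3, 5), min_samples_leaf = 1
  )
  gs2 <- grid_search_tree(sep$data, sep$labels, grid = g2, folds = 3)
  expect_equal(gs2$best_params$max_depth, 3L)

  # adding a dominated grid point never changes the winner
  g3 <- tree_grid(
    criterion = "gini", max_features = "none",
    min_samples_split = 2, max_depth = c(3, 5), min_samples_leaf = c(1, 40)
  )
  gs3 <- grid_search_tree(sep$data, sep$labels, grid = g3, folds = 3)
  expect_equal(gs3$best_params, gs2$best_params)
  expect_error(grid_search_tree(sep$data, sep$labels, grid = g1, folds = 300), "cannot exceed")
})

test_that("the default grid mirrors the conventional CART search space", {
  g <- tree_grid()
  expect_setequal(g$criterion, c("gini", "entropy"))
  expect_equal(g$max_depth, 3:29)
  expect_equal(g$min_samples_split, c(2L, 3L, 5L, 8L, 10L, 20L, 40L))
  expect_equal(g$min_samples_leaf, c(1:5, 10L, 20L, 40L))
  expect_equal(nrow(grid_points(g)), 2 * 3 * 7 * 27 * 8)
  expect_error(tree_grid(min_samples_split = integer(0)), "nonempty")
})

test_that("depth recommendation picks the smallest depth within tolerance", {
  expect_equal(recommend_depth(1:4, c(70, 80, 80.5, 80.6), tolerance = 1), 2)
  expect_equal(recommend_depth(1:4, c(70, 80, 80.5, 80.6), tolerance = 0), 4)
  expect_equal(recommend_depth(5:7, c(90, 90, 90), tolerance = 0), 5)
  expect_error(recommend_depth(1:2, 1), "aligned")
})

test_that("the validation curve reports train/validation scores per depth", {
  sim <- tiny_sim(seed = 27, n = 400, red = 0, qc = 0, nnoise = 2)
  curve <- depth_validation_curve(sim$data, sim$labels,
    depths = c(2, 4, 6),
    folds = 3, seed = 2
  )
  expect_equal(curve$depth, c(2, 4, 6))
  expect_true(all(curve$train_mean >= curve$val_mean - 5)) # training tracks above validation
  rec <- attr(curve, "recommended_depth")
  expect_true(rec %in% c(2, 4, 6))
})

test_that("DOT export mirrors the node array", {
  sep <- make_separable(40)
  fit <- fit_amen_tree(sep$data, sep$labels, max_depth = 2)
  dot <- export_dot(fit)
  expect_match(dot, "^digraph")
  dot_lines <- strsplit(dot, "\n")[[1]]
  expect_equal(sum(grepl("^  node\\d+ \\[label", dot_lines)), nrow(fit$nodes))
  n_edges <- length(gregexpr("->", dot)[[1]])
  expect_equal(n_edges, 2 * sum(!is.na(fit$nodes$feature)))

  # a depth-0 tree is a single node with no edges
  stub <- fit_amen_tree(sep$data, sep$labels, max_depth = 0)
  dot0 <- export_dot(stub)
  expect_equal(nrow(stub$nodes), 1)
  expect_false(grepl("->", dot0))
})

test_that("random feature subsampling is reproducible under the seed", {
  sim <- tiny_sim(seed = 33, n = 300, red = 0, qc = 0, nnoise = 6)
  f1 <- fit_amen_tree(sim$data, sim$labels, max_features = "sqrt", max_depth = 4, seed = 5)
  f2 <- fit_amen_tree(sim$data, sim$labels, max_features = "sqrt", max_depth = 4, seed = 5)
  expect_identical(f1$nodes, f2$nodes)
})
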