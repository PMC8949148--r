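#' Hyperparameter grid for the amenability tree
#'
#' The default grid spans the standard CART controls: split criterion,
#' per-node feature subsampling, minimum node sizes and tree depth
#' (3 to 29). `grid_points()` expands it to one tibble row per
#' combination, in the documented order (criterion, max_features,
#' min_samples_split, max_depth, min_samples_leaf; later fields vary
#' fastest), which also defines the deterministic tie-break order of
#' [grid_search_tree()].
#'
#' @param criterion,max_features,min_samples_split,max_depth,min_samples_leaf
#'   Candidate values; all must be nonempty.
#' @return An `amen_grid_spec` (named list of candidate vectors).
#' @export
tree_grid <- function(criterion = c("gini", "entropy"),
                      max_features = c("auto", "sqrt", "none"),
                      min_samples_split = c(2L, 3L, 5L, 8L, 10L, 20L, 40L),
                      max_depth = 3:29,
                      min_samples_leaf = c(1:5, 10L, 20L, 40L)) {
  spec <- list(
    criterion = match.arg(criterion, c("gini", "entropy"), several.ok = TRUE),
    max_features = match.arg(max_features, c("auto", "sqrt", "none"), several.ok = TRUE),
    min_samples_split = as.integer(min_samples_split),
    max_depth = as.integer(max_depth),
    min_samples_leaf = as.integer(min_samples_leaf)
  )
  if (any(lengths(spec) == 0)) abort("Every grid dimension must be nonempty")
  structure(spec, class = "amen_grid_spec")
}

#' @rdname tree_grid
#' @param grid An `amen_grid_spec`.
#' @export
grid_points <- function(grid = tree_grid()) {
  stopifnot(inherits(grid, "amen_grid_spec"))
  tidyr::expand_grid(
    criterion = grid$criterion,
    max_features = grid$max_features,
    min_samples_split = grid$min_samples_split,
    max_depth = grid$max_depth,
    min_samples_leaf = grid$min_samples_leaf
  )
}

#' Grid search over tree hyperparameters by cross-validated label accuracy
#'
#' Exhaustive evaluation of every grid point under a shared k-fold
#' assignment, scored by mean label-based accuracy on the validation
#' folds. Ties are broken by higher mean score, then smaller `max_depth`,
#' then grid order; the whole search is deterministic for a fixed seed.
#'
#' @inheritParams fit_amen_tree
#' @param grid An [tree_grid()] specification.
#' @param folds Number of CV folds.
#' @return An `amen_grid_search`: list with `best_params` (one-row tibble),
#'   `best_score`, and `results` (the full grid with `mean_accuracy`).
#' @export
grid_search_tree <- function(data, labels, features = NULL, grid = tree_grid(),
                             folds = 10L, seed = 1L) {
  features <- features %||% feature_names_of(data)
  Y <- as_label_matrix(labels)
  n <- nrow(data)
  fa <- make_folds(n, folds, seed)
  pts <- grid_points(grid)
  mean_acc <- vapply(seq_len(nrow(pts)), function(i) {
    par <- pts[i, ]
    acc <- vapply(seq_len(folds), function(k) {
      tr <- fa != k
      fit <- fit_amen_tree(
        data[tr, , drop = FALSE], Y[tr, , drop = FALSE],
        features = features,
        criterion = par$criterion, max_features = par$max_features,
        min_samples_split = par$min_samples_split,
        max_depth = par$max_depth, min_samples_leaf = par$min_samples_leaf,
        seed = seed + k
      )
      as.numeric(label_accuracy(Y[!tr, , drop = FALSE], predict(fit, data[!tr, , drop = FALSE])))
    }, numeric(1))
    mean(acc)
  }, numeric(1))
  results <- dplyr::mutate(pts, mean_accuracy = mean_acc, grid_index = dplyr::row_number())
  ord <- order(-results$mean_accuracy, results$max_depth, results$grid_index)
  best <- results[ord[1], ]
  structure(
    list(
      best_params = best[, setdiff(names(best), c("mean_accuracy", "grid_index"))],
      best_score = best$mean_accuracy,
      results = results,
      folds = folds, seed = seed
    ),
    class = "amen_grid_search"
  )
}

#' @export
print.amen_grid_search <- function(x, ...) {
  cat(sprintf(
    "<amen_grid_search> %d grid points, %d-fold CV; best mean label accuracy %.4f\n",
    nrow(x$results), x$folds, x$best_score
  ))
  print(x$best_params)
  invisible(x)
}

#' @describeIn grid_search_tree Full results table, one row per grid point.
#' @param x An `amen_grid_search` object.
#' @param ... Unused.
#' @export
tidy.amen_grid_search <- function(x, ...) {
  x$results
}

#' @describeIn grid_search_tree Winning grid point with its CV score.
#' @export
glance.amen_grid_search <- function(x, ...) {
  dplyr::bind_cols(x$best_params, tibble(mean_accuracy = x$best_score))
}

#' Depth validation curve and parsimonious depth recommendation
#'
#' Scores trees of increasing depth by k-fold cross-validation (mean and
#' SD of both training and validation label-based accuracy, in percent)
#' with all other hyperparameters fixed. The recommended depth is the
#' smallest whose mean validation score is within `tolerance` percentage
#' points of the maximum - the classic interpretability trade-off read off
#' a validation curve.
#'
#' @inheritParams fit_amen_tree
#' @param depths Integer vector of depths to evaluate.
#' @param folds Number of CV folds.
#' @param tolerance Percentage points of validation accuracy the
#'   recommended depth may concede to the best depth.
#' @param ... Further fixed hyperparameters for [fit_amen_tree()].
#' @return An `amen_validation_curve`: tibble with columns `depth`,
#'   `train_mean`, `train_sd`, `val_mean`, `val_sd` (percent) and
#'   attribute `recommended_depth`.
#' @export
depth_validation_curve <- function(data, labels, features = NULL, depths = 3:29,
                                   folds = 10L, seed = 1L, tolerance = 1, ...) {
  if (length(depths) == 0) abort("'depths' must be nonempty")
  features <- features %||% feature_names_of(data)
  Y <- as_label_matrix(labels)
  fa <- make_folds(nrow(data), folds, seed)
  rows <- purrr::map_dfr(depths, function(d) {
    tr_acc <- numeric(folds)
    va_acc <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fa != k
      fit <- fit_amen_tree(
        data[tr, , drop = FALSE], Y[tr, , drop = FALSE],
        features = features, max_depth = d, seed = seed + k, ...
      )
      tr_acc[k] <- as.numeric(label_accuracy(Y[tr, , drop = FALSE], predict(fit, data[tr, , drop = FALSE])))
      va_acc[k] <- as.numeric(label_accuracy(Y[!tr, , drop = FALSE], predict(fit, data[!tr, , drop = FALSE])))
    }
    tibble(
      depth = d,
      train_mean = 100 * mean(tr_acc), train_sd = 100 * sd(tr_acc),
      val_mean = 100 * mean(va_acc), val_sd = 100 * sd(va_acc)
    )
  })
  out <- rows
  class(out) <- c("amen_validation_curve", class(out))
  attr(out, "recommended_depth") <- recommend_depth(rows$depth, rows$val_mean, tolerance)
  attr(out, "tolerance") <- tolerance
  out
}

#' @rdname depth_validation_curve
#' @param scores Validation scores aligned with `depths` (any fixed scale;
#'   `tolerance` is in the same units).
#' @export
recommend_depth <- function(depths, scores, tolerance = 1) {
  if (length(depths) != length(scores) || length(depths) == 0) {
    abort("'depths' and 'scores' must be nonempty and aligned")
  }
  if (tolerance < 0) abort("'tolerance' must be >= 0")
  ok <- scores >= max(scores) - tolerance
  min(depths[ok])
}
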