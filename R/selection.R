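#' Configuration of the staged feature-selection pipeline
#'
#' Bundles every tunable of [run_selection_pipeline()]: the quasi-constant
#' modal-frequency threshold, the Spearman redundancy threshold, the
#' importance cutoff scale, the CV protocol of the model-based stages, the
#' sequential-forward-selection schedule and the overlap consensus rule.
#'
#' @param quasi_constant_threshold Remove a feature when its modal value
#'   covers more than this fraction of rows (default 0.99).
#' @param correlation_threshold Absolute Spearman correlation at or above
#'   which a pair is redundant (default 0.9).
#' @param importance_scale Keep features with ensemble importance at least
#'   `importance_scale` times the mean importance (default 1.5).
#' @param cv_folds Folds for the cross-validated stages (default 10).
#' @param sfs_keep Features kept per sequential-forward repetition
#'   (default 10).
#' @param sfs_repetitions Number of SFS repetitions (default 5).
#' @param overlap_min_count Minimum number of repetition lists a feature
#'   must appear in to survive the consensus stage (default 3, a majority
#'   of 5).
#' @param overlap_cap Maximum size of the final set (default 10).
#' @param n_trees Ensemble size of the random forests used inside the
#'   importance, RFE and SFS stages (default 50).
#' @param importance_type Importance measure of the importance filter:
#'   `"permutation"` (default) or `"impurity"` (see
#'   [filter_importance()]).
#' @param keep_rule How the correlation filter chooses which member of a
#'   redundant pair to drop: `"column_order"` (drop the later column) or
#'   `"label_relevance"` (drop the one less rank-correlated with the
#'   labels).
#' @param absolute_correlation Use |r_s| (default) or signed r_s in the
#'   correlation filter.
#' @param sfs_input Which retained set feeds the SFS stage:
#'   `"importance"` (default) or `"rfecv"`.
#' @param seed Master seed of the pipeline; stage seeds are derived from
#'   it by fixed offsets.
#' @return An `amen_selection_config` (named list).
#' @export
selection_config <- function(quasi_constant_threshold = 0.99,
                             correlation_threshold = 0.9,
                             importance_scale = 1.5,
                             cv_folds = 10L, sfs_keep = 10L,
                             sfs_repetitions = 5L,
                             overlap_min_count = 3L, overlap_cap = 10L,
                             n_trees = 50L,
                             importance_type = c("permutation", "impurity"),
                             keep_rule = c("column_order", "label_relevance"),
                             absolute_correlation = TRUE,
                             sfs_input = c("importance", "rfecv"),
                             seed = 1L) {
  check_fraction(quasi_constant_threshold, "quasi_constant_threshold", open = FALSE)
  if (quasi_constant_threshold <= 0 || quasi_constant_threshold > 1) {
    abort("'quasi_constant_threshold' must lie in (0, 1]")
  }
  if (correlation_threshold <= 0 || correlation_threshold > 1) {
    abort("'correlation_threshold' must lie in (0, 1]")
  }
  if (importance_scale <= 0) abort("'importance_scale' must be positive")
  structure(
    list(
      quasi_constant_threshold = quasi_constant_threshold,
      correlation_threshold = correlation_threshold,
      importance_scale = importance_scale,
      cv_folds = check_count(cv_folds, "cv_folds", 2L),
      sfs_keep = check_count(sfs_keep, "sfs_keep", 1L),
      sfs_repetitions = check_count(sfs_repetitions, "sfs_repetitions", 1L),
      overlap_min_count = check_count(overlap_min_count, "overlap_min_count", 1L),
      overlap_cap = check_count(overlap_cap, "overlap_cap", 1L),
      n_trees = check_count(n_trees, "n_trees", 1L),
      importance_type = match.arg(importance_type),
      keep_rule = match.arg(keep_rule),
      absolute_correlation = isTRUE(absolute_correlation),
      sfs_input = match.arg(sfs_input),
      seed = check_count(seed, "seed")
    ),
    class = "amen_selection_config"
  )
}

#' Serialize / restore a selection configuration
#'
#' @param config An `amen_selection_config`.
#' @param path File path.
#' @return `write_selection_config()` returns `path` invisibly;
#'   `read_selection_config()` the configuration.
#' @export
write_selection_config <- function(config, path) {
  stopifnot(inherits(config, "amen_selection_config"))
  payload <- c(list(schema = "amenability/selection_config/v1"), unclass(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_selection_config
#' @export
read_selection_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "amenability/selection_config/v1")) {
    abort("Unsupported selection-config schema")
  }
  payload$schema <- NULL
  do.call(selection_config, payload)
}

#' Quasi-constant feature filter
#'
#' Removes a feature when the frequency of its modal value exceeds
#' `threshold` (as a fraction of rows). Missing values count as a value of
#' their own, so a column that is mostly `NA` is also quasi-constant.
#'
#' @param data Descriptor table (data frame).
#' @param threshold Modal-frequency threshold in (0, 1].
#' @param features Columns to consider; default all except `.id`/labels.
#' @return Character vector of retained feature names, in column order.
#' @export
filter_quasi_constant <- function(data, threshold = 0.99, features = NULL) {
  features <- features %||% feature_names_of(data)
  n <- nrow(data)
  if (n < 2) abort("Need at least 2 rows")
  modal <- vapply(features, function(f) {
    max(table(data[[f]], useNA = "ifany"))
  }, numeric(1))
  features[modal / n <= threshold]
}

#' Spearman correlation redundancy filter
#'
#' Computes all pairwise Spearman rank correlations (on pairwise-complete
#' observations) and scans the pairs in column order; whenever a still-
#' retained pair reaches the threshold, one member is dropped. With
#' `keep_rule = "column_order"` the later column goes; with
#' `"label_relevance"` the member whose mean absolute rank correlation
#' with the two label columns is smaller goes (ties keep the earlier
#' column). Already-removed features never trigger further removals, so
#' the retained set has every pairwise correlation below the threshold.
#'
#' @inheritParams filter_quasi_constant
#' @param threshold Redundancy threshold in (0, 1].
#' @param keep_rule `"column_order"` or `"label_relevance"`.
#' @param labels Binary `GC`/`LC` labels; required for
#'   `"label_relevance"`.
#' @param absolute Compare |r_s| (default) rather than signed r_s, so
#'   anti-correlated duplicates are also caught.
#' @return Character vector of retained feature names, in column order.
#' @export
filter_correlation <- function(data, threshold = 0.9,
                               keep_rule = c("column_order", "label_relevance"),
                               labels = NULL, features = NULL, absolute = TRUE) {
  keep_rule <- match.arg(keep_rule)
  features <- features %||% feature_names_of(data)
  if (keep_rule == "label_relevance" && is.null(labels)) {
    abort("keep_rule = \"label_relevance\" requires 'labels'")
  }
  p <- length(features)
  if (p < 2) return(features)
  X <- descriptor_matrix(data, features)
  R <- suppressWarnings(cor(X, method = "spearman", use = "pairwise.complete.obs"))
  V <- if (absolute) abs(R) else R
  V[is.na(V)] <- 0
  rel <- NULL
  if (keep_rule == "label_relevance") {
    Y <- as_label_matrix(labels)
    rel <- vapply(seq_len(p), function(j) {
      r <- suppressWarnings(c(
        cor(X[, j], Y[, 1], method = "spearman", use = "pairwise.complete.obs"),
        cor(X[, j], Y[, 2], method = "spearman", use = "pairwise.complete.obs")
      ))
      mean(abs(ifelse(is.na(r), 0, r)))
    }, numeric(1))
  }
  removed <- rep(FALSE, p)
  for (i in seq_len(p - 1)) {
    if (removed[i]) next
    js <- which(!removed & V[i, ] >= threshold & seq_len(p) > i)
    if (length(js) == 0) next
    if (keep_rule == "column_order") {
      removed[js] <- TRUE
    } else {
      for (j in js) {
        if (removed[i]) break
        if (rel[j] > rel[i]) removed[i] <- TRUE else removed[j] <- TRUE
      }
    }
  }
  features[!removed]
}

#' Importance cutoff rule
#'
#' Keeps the features whose importance is at least `scale` times the mean
#' importance (the comparison is inclusive). If the rule would empty the
#' set - e.g. all importances equal with `scale > 1` - the single most
#' important feature is kept and a warning raised.
#'
#' @param importances Named numeric vector of importances.
#' @param scale Multiplier of the mean importance.
#' @return Names of the retained features, in input order.
#' @export
importance_keep <- function(importances, scale = 1.5) {
  if (is.null(names(importances))) abort("'importances' must be named")
  keep <- importances >= scale * mean(importances)
  if (!any(keep)) {
    warn("Importance cutoff removed every feature; keeping the single most important one")
    keep <- seq_along(importances) == which.max(importances)
  }
  names(importances)[keep]
}

#' Random-forest importance filter
#'
#' Fits a random forest jointly on the two labels (4-class product
#' encoding) and keeps the features whose importance reaches `scale`
#' times the mean importance. The default importance measure is
#' out-of-bag permutation importance: with many irrelevant columns and
#' noisy labels, impurity importance credits spurious deep splits to
#' noise features and can push a genuinely predictive but weak descriptor
#' below the cutoff, whereas permuting a noise column leaves out-of-bag
#' accuracy unchanged. Impurity importance remains available via
#' `importance_type`. Deterministic for a fixed seed. Model-based stages
#' require complete columns: missing values in the candidate features are
#' a diagnostic error.
#'
#' @inheritParams filter_quasi_constant
#' @param labels Binary `GC`/`LC` labels aligned with `data`.
#' @param scale Importance cutoff multiplier.
#' @param n_trees Ensemble size.
#' @param importance_type `"permutation"` (default) or `"impurity"`.
#' @param seed Integer seed.
#' @return Character vector of retained names (column order), with the
#'   full importance vector in attribute `importances`.
#' @export
filter_importance <- function(data, labels, features = NULL, scale = 1.5,
                              n_trees = 50L,
                              importance_type = c("permutation", "impurity"),
                              seed = 1L) {
  importance_type <- match.arg(importance_type)
  features <- features %||% feature_names_of(data)
  if (length(features) < 2) abort("Need at least 2 candidate features")
  X <- descriptor_matrix(data, features, require_finite = TRUE)
  Y <- as_label_matrix(labels)
  if (length(unique(Y[, 1])) == 1 && length(unique(Y[, 2])) == 1) {
    abort("Degenerate labels: both outputs are single-class; importances are undefined")
  }
  fit <- fit_joint_forest(X, Y, n_trees = n_trees, seed = seed, importance = importance_type)
  imp <- fit$variable.importance[features]
  kept <- importance_keep(imp, scale)
  out <- features[features %in% kept]
  attr(out, "importances") <- imp
  out
}

#' Recursive feature elimination with cross-validated scoring
#'
#' Starting from the full candidate set, repeatedly drops the least
#' important feature (importance refitted at each step on the current
#' set) and scores every intermediate set by k-fold cross-validated
#' label-based accuracy of the joint random forest, under one shared fold
#' assignment. Returns the whole score curve - the plateau diagnostic -
#' and the best-scoring set (ties prefer fewer features).
#'
#' @inheritParams filter_importance
#' @param folds CV folds.
#' @return An `amen_rfe`: list with `score_curve` (tibble `n_features`,
#'   `accuracy`, `features` list-column) and `retained` (character).
#' @export
select_rfe <- function(data, labels, features = NULL, folds = 10L,
                       n_trees = 50L, seed = 1L) {
  features <- features %||% feature_names_of(data)
  Y <- as_label_matrix(labels)
  n <- nrow(data)
  folds <- check_count(folds, "folds", 2L)
  if (folds > n) abort(sprintf("'folds' (%d) cannot exceed n (%d)", folds, n))
  X <- descriptor_matrix(data, features, require_finite = TRUE)
  fa <- make_folds(n, folds, seed)
  current <- features
  rows <- list()
  while (length(current) >= 1) {
    acc <- cv_forest_accuracy(X[, current, drop = FALSE], Y, fa,
      n_trees = n_trees, seed = seed + length(current)
    )
    rows[[length(rows) + 1L]] <- tibble(
      n_features = length(current), accuracy = acc, features = list(current)
    )
    if (length(current) == 1) break
    fit <- fit_joint_forest(X[, current, drop = FALSE], Y,
      n_trees = n_trees, seed = seed + 10000L + length(current), importance = "impurity"
    )
    imp <- fit$variable.importance[current]
    current <- current[-which.min(imp)]
  }
  curve <- dplyr::arrange(dplyr::bind_rows(rows), .data$n_features)
  best <- which(curve$accuracy == max(curve$accuracy))
  best <- best[which.min(curve$n_features[best])]
  structure(
    list(score_curve = curve, retained = curve$features[[best]]),
    class = "amen_rfe"
  )
}

#' @export
print.amen_rfe <- function(x, ...) {
  cat(sprintf(
    "<amen_rfe> best CV label accuracy %.4f at %d feature(s)\n",
    max(x$score_curve$accuracy), length(x$retained)
  ))
  invisible(x)
}

#' Repeated sequential forward selection
#'
#' Greedy forward selection scored by k-fold cross-validated label-based
#' accuracy of the joint random forest: at each step the candidate whose
#' addition maximizes the mean CV score joins the set, until `k` features
#' are selected. The whole procedure is repeated `repetitions` times,
#' repetition `r` re-shuffling folds and re-seeding the ensembles with
#' `seed + r`, so the repetition lists differ only through that
#' resampling.
#'
#' @inheritParams select_rfe
#' @param k Features to keep per repetition (`k <= p`).
#' @param repetitions Number of repetitions.
#' @return List of `repetitions` character vectors, each in selection
#'   order.
#' @export
select_sequential_forward <- function(data, labels, features = NULL, k = 10L,
                                      folds = 10L, repetitions = 5L,
                                      n_trees = 50L, seed = 1L) {
  features <- features %||% feature_names_of(data)
  k <- check_count(k, "k", 1L)
  if (k > length(features)) {
    abort(sprintf("'k' (%d) cannot exceed the number of features (%d)", k, length(features)))
  }
  Y <- as_label_matrix(labels)
  n <- nrow(data)
  folds <- check_count(folds, "folds", 2L)
  if (folds > n) abort(sprintf("'folds' (%d) cannot exceed n (%d)", folds, n))
  X <- descriptor_matrix(data, features, require_finite = TRUE)
  lapply(seq_len(check_count(repetitions, "repetitions", 1L)), function(r) {
    seed_r <- seed + r
    fa <- make_folds(n, folds, seed_r)
    selected <- character(0)
    for (step in seq_len(k)) {
      candidates <- setdiff(features, selected)
      scores <- vapply(candidates, function(f) {
        cv_forest_accuracy(X[, c(selected, f), drop = FALSE], Y, fa,
          n_trees = n_trees, seed = seed_r
        )
      }, numeric(1))
      selected <- c(selected, candidates[which.max(scores)])
    }
    selected
  })
}

#' Overlap consensus over repetition lists
#'
#' Counts how often each feature appears across the repetition lists and
#' keeps those appearing at least `min_count` times. If more than `cap`
#' survive, the `cap` best by (higher count, earlier mean selection
#' position, then column order) are kept. Deterministic.
#'
#' @param lists List of character vectors (selection order preserved).
#' @param min_count Minimum number of lists a feature must appear in.
#' @param cap Maximum size of the returned set.
#' @param feature_order Optional character vector fixing the final
#'   tie-break order (e.g. the table's column order); defaults to order of
#'   first appearance.
#' @return Character vector of consensus features; attribute `overlap`
#'   holds the full count table (tibble `feature`, `count`,
#'   `mean_position`).
#' @export
select_overlap <- function(lists, min_count = 3L, cap = 10L, feature_order = NULL) {
  if (length(lists) == 0) abort("'lists' must contain at least one list")
  all_feats <- unique(unlist(lists))
  feature_order <- feature_order %||% all_feats
  ord <- match(all_feats, feature_order)
  ord[is.na(ord)] <- length(feature_order) + seq_len(sum(is.na(ord)))
  counts <- unname(vapply(all_feats, function(f) {
    sum(vapply(lists, function(l) f %in% l, logical(1)))
  }, integer(1)))
  mean_pos <- unname(vapply(all_feats, function(f) {
    mean(unlist(lapply(lists, function(l) which(l == f))))
  }, numeric(1)))
  overlap <- tibble(feature = all_feats, count = counts, mean_position = mean_pos)
  keep <- which(counts >= min_count)
  if (length(keep) > cap) {
    keep <- keep[order(-counts[keep], mean_pos[keep], ord[keep])][seq_len(cap)]
  }
  keep <- keep[order(ord[keep])]
  out <- all_feats[keep]
  attr(out, "overlap") <- dplyr::arrange(overlap, dplyr::desc(.data$count), .data$mean_position)
  out
}

#' Run the full staged feature-selection pipeline
#'
#' Executes the six stages in order - initial set, quasi-constant filter,
#' Spearman correlation filter, random-forest importance filter, recursive
#' feature elimination with CV, repeated sequential forward selection -
#' and condenses the repetition lists into the final consensus set. Every
#' stage's retained set is recorded, so the trace prints as the familiar
#' per-stage count table. The pipeline is a pure function of (data,
#' labels, config), including all ensemble seeds.
#'
#' @param data Descriptor table (data frame; `.id` column ignored).
#' @param labels Binary `GC`/`LC` labels aligned with `data`.
#' @param config An [selection_config()].
#' @return An `amen_selection_trace`: `stages` (tibble `stage`,
#'   `n_retained`, `features` list-column), `sfs_lists`, `overlap` (count
#'   table), `final` (character), `rfe_curve`, `config`.
#' @export
run_selection_pipeline <- function(data, labels, config = selection_config()) {
  stopifnot(inherits(config, "amen_selection_config"))
  features <- feature_names_of(data)
  if (length(features) == 0 || nrow(data) == 0) abort("Empty descriptor table")
  Y <- as_label_matrix(labels)
  seed <- config$seed

  variance_set <- filter_quasi_constant(data, config$quasi_constant_threshold, features)
  correlation_set <- filter_correlation(
    data, config$correlation_threshold,
    keep_rule = config$keep_rule, labels = Y,
    features = variance_set, absolute = config$absolute_correlation
  )
  importance_set <- filter_importance(
    data, Y, features = correlation_set,
    scale = config$importance_scale, n_trees = config$n_trees,
    importance_type = config$importance_type, seed = seed + 1L
  )
  rfe <- select_rfe(
    data, Y, features = as.character(importance_set),
    folds = config$cv_folds, n_trees = config$n_trees, seed = seed + 2L
  )
  sfs_input <- if (config$sfs_input == "importance") as.character(importance_set) else rfe$retained
  sfs_lists <- select_sequential_forward(
    data, Y, features = sfs_input,
    k = min(config$sfs_keep, length(sfs_input)),
    folds = config$cv_folds, repetitions = config$sfs_repetitions,
    n_trees = config$n_trees, seed = seed + 10L
  )
  final <- select_overlap(
    sfs_lists,
    # a majority of the available lists, in case fewer repetitions than the
    # configured overlap count were run
    min_count = min(config$overlap_min_count, length(sfs_lists)),
    cap = config$overlap_cap,
    feature_order = features
  )

  stages <- tibble(
    stage = c("initial", "variance", "correlation", "rf_importance", "rfecv", "final"),
    features = list(
      features, variance_set, correlation_set,
      as.character(importance_set), rfe$retained, as.character(final)
    )
  )
  stages$n_retained <- lengths(stages$features)
  trace <- structure(
    list(
      stages = stages[, c("stage", "n_retained", "features")],
      sfs_lists = sfs_lists,
      overlap = attr(final, "overlap"),
      final = as.character(final),
      rfe_curve = rfe$score_curve[, c("n_features", "accuracy")],
      config = unclass(config)
    ),
    class = "amen_selection_trace"
  )
  inform(paste("Selection trace:", format_trace_counts(trace)))
  trace
}

format_trace_counts <- function(trace) {
  paste(sprintf("%s (%d)", trace$stages$stage, trace$stages$n_retained), collapse = " ")
}

#' @export
print.amen_selection_trace <- function(x, ...) {
  cat("<amen_selection_trace>\n  ", format_trace_counts(x), "\n", sep = "")
  cat("  final:", paste(x$final, collapse = ", "), "\n")
  invisible(x)
}

#' @describeIn run_selection_pipeline Stage count table (Table-1 layout).
#' @param x An `amen_selection_trace` object.
#' @param ... Unused.
#' @export
tidy.amen_selection_trace <- function(x, ...) {
  x$stages[, c("stage", "n_retained")]
}

#' @describeIn run_selection_pipeline One-row summary of the trace.
#' @export
glance.amen_selection_trace <- function(x, ...) {
  tibble(
    n_initial = x$stages$n_retained[1],
    n_final = length(x$final),
    sfs_repetitions = length(x$sfs_lists)
  )
}
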