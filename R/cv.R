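# Fold construction and cross-validated label-accuracy scoring shared by
# the selection pipeline, the tree tuning and the comparison protocol.

#' Cross-validation fold assignment
#'
#' Shuffled, near-equal-size fold labels for `n` rows, deterministic for a
#' fixed seed.
#'
#' @param n Number of rows.
#' @param folds Number of folds (2 <= folds <= n).
#' @param seed Integer seed.
#' @return Integer vector of length `n` with values in `1:folds`.
#' @export
make_folds <- function(n, folds, seed = 1L) {
  n <- check_count(n, "n", 1L)
  folds <- check_count(folds, "folds", 2L)
  if (folds > n) abort(sprintf("'folds' (%d) cannot exceed n (%d)", folds, n))
  withr::with_seed(seed, sample(rep(seq_len(folds), length.out = n)))
}

# Joint two-output random forest used inside feature selection: the two
# binary labels are encoded as the 4-class product label so one ensemble
# models both outputs.
fit_joint_forest <- function(X, Y, n_trees = 50L, seed = 1L, importance = "none") {
  y <- joint_label_factor(Y)
  withCallingHandlers(
    ranger::ranger(
      x = X, y = y, num.trees = n_trees, seed = seed,
      num.threads = 1L, importance = importance,
      respect.unordered.factors = "ignore", verbose = FALSE
    ),
    # absent label combinations are expected (e.g. GC-only compounds may not
    # occur in a small fold); ranger drops the unused level and warns
    warning = function(w) {
      if (grepl("Dropped unused factor level", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

predict_joint_forest <- function(fit, X) {
  # ranger breaks classification vote ties at random from the global RNG;
  # pin it so repeated evaluations of the same model are identical
  pr <- withr::with_seed(
    1L,
    stats::predict(fit, data = X, num.threads = 1L, verbose = FALSE)
  )
  joint_label_decode(pr$predictions)
}

# k-fold CV label-based accuracy of the joint forest on a feature subset.
cv_forest_accuracy <- function(X, Y, fold_assign, n_trees = 50L, seed = 1L) {
  ks <- sort(unique(fold_assign))
  scores <- vapply(ks, function(k) {
    tr <- fold_assign != k
    fit <- fit_joint_forest(X[tr, , drop = FALSE], Y[tr, , drop = FALSE],
      n_trees = n_trees, seed = seed + k
    )
    pred <- predict_joint_forest(fit, X[!tr, , drop = FALSE])
    as.numeric(label_accuracy(Y[!tr, , drop = FALSE], pred))
  }, numeric(1))
  mean(scores)
}

#' Classifier specifications for the repeated-CV protocol
#'
#' A method bundles a fit function and a predict function so that several
#' classifiers (or the same classifier on different feature sets) can be
#' scored on identical folds. `cv_method_tree()` wraps [fit_amen_tree()],
#' `cv_method_forest()` the joint random forest used inside feature
#' selection, and `cv_method_rule()` the (training-free) rule baseline.
#'
#' @param features Feature columns the method may use (`NULL` = all).
#' @param ... Hyperparameters forwarded to [fit_amen_tree()].
#' @param n_trees Ensemble size for `cv_method_forest()`.
#' @param column_map,thresholds Arguments of [predict_rule()].
#' @return An `amen_cv_method` object.
#' @export
cv_method_tree <- function(features = NULL, ...) {
  args <- list(...)
  structure(
    list(
      kind = "tree", features = features,
      fit = function(data, labels, seed) {
        do.call(fit_amen_tree, c(list(data = data, labels = labels, features = features, seed = seed), args))
      },
      predict = function(model, data) predict(model, data)
    ),
    class = "amen_cv_method"
  )
}

#' @rdname cv_method_tree
#' @export
cv_method_forest <- function(features = NULL, n_trees = 50L) {
  structure(
    list(
      kind = "forest", features = features,
      fit = function(data, labels, seed) {
        feats <- features %||% feature_names_of(data)
        fit <- fit_joint_forest(
          descriptor_matrix(data, feats, require_finite = TRUE),
          as_label_matrix(labels),
          n_trees = n_trees, seed = seed
        )
        list(fit = fit, features = feats)
      },
      predict = function(model, data) {
        label_tibble(predict_joint_forest(
          model$fit, descriptor_matrix(data, model$features, require_finite = TRUE)
        ))
      }
    ),
    class = "amen_cv_method"
  )
}

#' @rdname cv_method_tree
#' @export
cv_method_rule <- function(column_map = c(bp = "BoilingPoint", mw = "MW", logp = "logP"),
                           thresholds = rule_thresholds()) {
  structure(
    list(
      kind = "rule", features = unname(column_map),
      fit = function(data, labels, seed) NULL,
      predict = function(model, data) {
        suppressWarnings(predict_rule(data, column_map = column_map, thresholds = thresholds))
      }
    ),
    class = "amen_cv_method"
  )
}

#' Repeated k-fold cross-validation with paired folds
#'
#' The comparison protocol: `repetitions` repetitions of `folds`-fold CV.
#' Repetition `r` shuffles folds with `seed + r`; within a repetition every
#' method sees exactly the same fold assignment, so the resulting
#' label-based accuracies are paired block by block - the layout required
#' by the Friedman, Nemenyi and Wilcoxon machinery.
#'
#' @param data Descriptor table (data frame).
#' @param labels Binary `GC`/`LC` labels aligned with `data`.
#' @param methods Named list of [cv_method_tree()]-style specifications.
#' @param folds Folds per repetition.
#' @param repetitions Number of repetitions.
#' @param seed Master seed.
#' @return An `amen_cv` object: tibble `scores` (method, repetition, fold,
#'   accuracy) plus protocol metadata and the recorded fold assignments.
#' @export
repeated_cv <- function(data, labels, methods, folds = 10L, repetitions = 10L, seed = 1L) {
  if (is.null(names(methods)) || any(names(methods) == "")) {
    abort("'methods' must be a named list")
  }
  n <- nrow(data)
  folds <- check_count(folds, "folds", 2L)
  repetitions <- check_count(repetitions, "repetitions", 1L)
  seed <- check_count(seed, "seed")
  if (folds > n) abort(sprintf("'folds' (%d) cannot exceed n (%d)", folds, n))
  Y <- as_label_matrix(labels)
  assignments <- lapply(seq_len(repetitions), function(r) make_folds(n, folds, seed + r))
  scores <- purrr::map_dfr(seq_len(repetitions), function(r) {
    fa <- assignments[[r]]
    purrr::map_dfr(names(methods), function(m) {
      meth <- methods[[m]]
      acc <- vapply(seq_len(folds), function(k) {
        tr <- fa != k
        model <- meth$fit(data[tr, , drop = FALSE], Y[tr, , drop = FALSE], seed = seed + 1000L * r + k)
        pred <- meth$predict(model, data[!tr, , drop = FALSE])
        as.numeric(label_accuracy(Y[!tr, , drop = FALSE], pred))
      }, numeric(1))
      tibble(method = m, repetition = r, fold = seq_len(folds), accuracy = acc)
    })
  })
  structure(
    list(
      scores = scores, methods = names(methods),
      folds = folds, repetitions = repetitions, seed = seed,
      fold_assignments = assignments
    ),
    class = "amen_cv"
  )
}

#' @export
print.amen_cv <- function(x, ...) {
  cat(sprintf(
    "<amen_cv> %d x %d-fold CV, %d method(s): %s\n",
    x$repetitions, x$folds, length(x$methods), paste(x$methods, collapse = ", ")
  ))
  print(glance(x))
  invisible(x)
}

#' @describeIn repeated_cv Long tibble of per-fold accuracies.
#' @param x An `amen_cv` object.
#' @param ... Unused.
#' @export
tidy.amen_cv <- function(x, ...) {
  x$scores
}

#' @describeIn repeated_cv Per-method mean and SD of the fold accuracies.
#' @export
glance.amen_cv <- function(x, ...) {
  dplyr::summarise(
    dplyr::group_by(x$scores, .data$method),
    mean_accuracy = mean(.data$accuracy), sd_accuracy = sd(.data$accuracy),
    .groups = "drop"
  )
}

#' Block-by-method score matrix from repeated CV
#'
#' Rearranges an [repeated_cv()] result into the (repetition x fold) blocks
#' by methods matrix consumed by [friedman_rank_test()] and
#' [nemenyi_test()].
#'
#' @param cv An `amen_cv` object.
#' @return Numeric matrix, one row per (repetition, fold) block, one named
#'   column per method.
#' @export
cv_score_matrix <- function(cv) {
  stopifnot(inherits(cv, "amen_cv"))
  wide <- tidyr::pivot_wider(
    cv$scores,
    id_cols = c("repetition", "fold"),
    names_from = "method", values_from = "accuracy"
  )
  m <- as.matrix(wide[, cv$methods, drop = FALSE])
  rownames(m) <- paste0("r", wide$repetition, "f", wide$fold)
  m
}
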