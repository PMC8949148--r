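#' Configuration of the end-to-end workflow
#'
#' A run is fully determined by this object (bit-reproducible given the
#' seed): input data (a labeled CSV or a synthetic configuration), split
#' fraction, selection configuration, final-model hyperparameters or
#' tuning grid, and the repeated-CV comparison protocol. The master seed
#' fans out to per-stage seeds by fixed offsets, so one number reproduces
#' everything.
#'
#' @param synthetic An [synthetic_config()], or `NULL` when reading a CSV.
#' @param input_csv Path to a labeled descriptor CSV, or `NULL`.
#' @param gc_col,lc_col,id_col Column names for [read_labeled_table()].
#' @param test_fraction Holdout fraction for [split_train_test()].
#' @param selection An [selection_config()].
#' @param tree Named list of fixed hyperparameters for [fit_amen_tree()]
#'   (default a depth-4 tree), ignored when `grid` is given.
#' @param grid Optional [tree_grid()] to tune the final tree by
#'   [grid_search_tree()].
#' @param folds,repetitions Comparison protocol for [repeated_cv()].
#' @param column_map,thresholds Rule-baseline settings.
#' @param out_dir Output directory for the run artifacts.
#' @param seed Master seed.
#' @return An `amen_run_config` (named list).
#' @export
run_config <- function(synthetic = NULL, input_csv = NULL,
                       gc_col = "GC", lc_col = "LC", id_col = NULL,
                       test_fraction = 0.2,
                       selection = selection_config(),
                       tree = list(max_depth = 4), grid = NULL,
                       folds = 10L, repetitions = 10L,
                       column_map = c(bp = "BoilingPoint", mw = "MW", logp = "logP"),
                       thresholds = rule_thresholds(),
                       out_dir = tempfile("amen_run_"), seed = 1L) {
  if (is.null(synthetic) && is.null(input_csv)) {
    abort("Provide either a synthetic configuration or an input CSV path")
  }
  if (!is.null(synthetic) && !is.null(input_csv)) {
    abort("Provide only one of 'synthetic' and 'input_csv'")
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "amen_sim_config"))
  stopifnot(inherits(selection, "amen_selection_config"))
  if (!is.null(grid)) stopifnot(inherits(grid, "amen_grid_spec"))
  check_fraction(test_fraction, "test_fraction")
  structure(
    list(
      synthetic = synthetic, input_csv = input_csv,
      gc_col = gc_col, lc_col = lc_col, id_col = id_col,
      test_fraction = test_fraction, selection = selection,
      tree = tree, grid = grid,
      folds = check_count(folds, "folds", 2L),
      repetitions = check_count(repetitions, "repetitions", 1L),
      column_map = column_map, thresholds = thresholds,
      out_dir = out_dir, seed = check_count(seed, "seed")
    ),
    class = "amen_run_config"
  )
}

# fixed seed fan-out so a single master seed reproduces every stage
run_seeds <- function(seed) {
  list(
    synthetic = seed + 53L, split = seed + 101L, selection = seed + 211L,
    model = seed + 307L, cv = seed + 401L
  )
}

#' Run the full amenability analysis end to end
#'
#' Orchestrates simulate/load, split, rule baseline, staged feature
#' selection, model tuning or fitting, holdout evaluation of both
#' classifiers, the repeated-CV statistical comparison, and prediction
#' export. All artifacts are written to `config$out_dir` as JSON/CSV
#' (selection trace, fitted tree, both classification reports, comparison
#' report, predictions and a manifest of every seed consumed); none
#' contain timestamps, so two runs with the same configuration produce
#' byte-identical files.
#'
#' The repeated-CV comparison pits the rule baseline (when the mapped
#' descriptor columns exist) against the tuned tree on the full feature
#' set and on the selected set; the feature-selection effect is tested
#' with the Friedman/Nemenyi machinery and the one-sided Wilcoxon
#' signed-rank (selected > initial) with its effect sizes, and the
#' holdout superiority over the baseline with the per-class McNemar test.
#'
#' @param config An [run_config()].
#' @return Invisibly, a list with every in-memory result (`dataset`,
#'   `split`, `trace`, `model`, `report_rule`, `report_tree`,
#'   `comparison`, `cv`, `out_dir`).
#' @export
run_full <- function(config) {
  stopifnot(inherits(config, "amen_run_config"))
  seeds <- run_seeds(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # ---- data ----
  dataset <- stage("data", {
    if (!is.null(config$synthetic)) {
      sim_cfg <- config$synthetic
      sim_cfg$seed <- seeds$synthetic
      sim <- generate_descriptors(sim_cfg)
      list(descriptors = sim$data, labels = sim$labels, truth = sim$truth)
    } else {
      ds <- read_labeled_table(config$input_csv,
        gc_col = config$gc_col,
        lc_col = config$lc_col, id_col = config$id_col
      )
      list(descriptors = ds$descriptors, labels = ds$labels, truth = NULL)
    }
  })
  X <- dataset$descriptors
  Y <- dataset$labels
  n <- nrow(X)
  inform(sprintf("[data] %d compounds x %d descriptors", n, length(feature_names_of(X))))

  # ---- split ----
  split <- stage("split", split_train_test(n, config$test_fraction, seed = seeds$split))
  tr <- split$train
  te <- split$test
  inform(sprintf("[split] %d train / %d test", length(tr), length(te)))

  # ---- selection ----
  sel_cfg <- config$selection
  sel_cfg$seed <- seeds$selection
  trace <- stage("selection", run_selection_pipeline(X[tr, ], Y[tr, ], sel_cfg))
  final_features <- trace$final

  # ---- model ----
  model <- stage("model", {
    if (!is.null(config$grid)) {
      gs <- grid_search_tree(X[tr, ], Y[tr, ],
        features = final_features,
        grid = config$grid, folds = config$folds, seed = seeds$model
      )
      inform(sprintf("[model] grid best mean CV label accuracy %.4f", gs$best_score))
      do.call(fit_amen_tree, c(
        list(
          data = X[tr, ], labels = Y[tr, ], features = final_features,
          seed = seeds$model
        ),
        as.list(gs$best_params)
      ))
    } else {
      do.call(fit_amen_tree, c(
        list(
          data = X[tr, ], labels = Y[tr, ], features = final_features,
          seed = seeds$model
        ),
        config$tree
      ))
    }
  })

  # ---- holdout evaluation ----
  rule_ok <- all(unname(config$column_map) %in% names(X))
  pred_tree <- predict(model, X[te, ])
  scores_tree <- predict(model, X[te, ], type = "score")
  report_tree <- classification_report(Y[te, ], pred_tree)
  report_rule <- NULL
  mcnemar <- NULL
  if (rule_ok) {
    pred_rule <- suppressWarnings(
      predict_rule(X[te, ], column_map = config$column_map, thresholds = config$thresholds)
    )
    report_rule <- classification_report(Y[te, ], pred_rule)
    mcnemar <- stage("mcnemar", mcnemar_labels(Y[te, ], pred_tree, pred_rule))
  }
  inform(sprintf(
    "[evaluate] holdout label accuracy: tree %.4f%s",
    report_tree$label_accuracy,
    if (rule_ok) sprintf(", rule %.4f", report_rule$label_accuracy) else ""
  ))

  # ---- repeated-CV comparison ----
  # the configured tree hyperparameters apply to both tree methods
  methods <- list(
    tree_initial = do.call(cv_method_tree, c(list(features = feature_names_of(X)), config$tree)),
    tree_final = do.call(cv_method_tree, c(list(features = final_features), config$tree))
  )
  if (rule_ok) {
    methods$rule <- cv_method_rule(config$column_map, config$thresholds)
  }
  cv <- stage("compare", repeated_cv(X[tr, ], Y[tr, ], methods,
    folds = config$folds,
    repetitions = config$repetitions, seed = seeds$cv
  ))
  m <- cv_score_matrix(cv)
  fr <- if (ncol(m) >= 2) friedman_rank_test(m) else NULL
  nem <- if (ncol(m) >= 3) nemenyi_test(m) else NULL
  wx <- wilcoxon_signed_rank(m[, "tree_final"], m[, "tree_initial"], alternative = "greater")
  comparison <- list(
    friedman = if (!is.null(fr)) tidy(fr) else NULL,
    nemenyi = if (!is.null(nem)) list(methods = colnames(m), p_values = nem$p_values) else NULL,
    wilcoxon_final_vs_initial = tidy(wx),
    mprbc = effect_rank_biserial(m[, "tree_final"], m[, "tree_initial"]),
    cles = effect_cles(m[, "tree_final"], m[, "tree_initial"]),
    mcnemar_holdout = mcnemar,
    cv_summary = glance(cv)
  )

  # ---- artifacts ----
  out <- config$out_dir
  write_selection_trace(trace, file.path(out, "selection_trace.json"))
  write_amen_tree(model, file.path(out, "model.json"))
  report_to_json(report_tree, file.path(out, "metrics_tree.json"))
  if (rule_ok) report_to_json(report_rule, file.path(out, "metrics_rule.json"))
  comparison_to_json(comparison, file.path(out, "comparison.json"))
  write_predictions(
    X[te, ][[".id"]] %||% as.character(te), pred_tree,
    file.path(out, "predictions.csv"),
    scores = scores_tree
  )
  manifest <- list(
    package = "amenability",
    version = as.character(utils::packageVersion("amenability")),
    master_seed = config$seed,
    stage_seeds = run_seeds(config$seed),
    n = n, n_train = length(tr), n_test = length(te),
    n_features_initial = length(feature_names_of(X)),
    final_features = as.list(final_features),
    protocol = list(folds = config$folds, repetitions = config$repetitions)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(
    dataset = dataset, split = split, trace = trace, model = model,
    report_rule = report_rule, report_tree = report_tree,
    comparison = comparison, cv = cv, out_dir = out
  ))
}

report_to_json <- function(report, path) {
  payload <- list(
    schema = "amenability/metrics_report/v1",
    per_class = report$per_class,
    averages = report$averages,
    label_accuracy = report$label_accuracy,
    exact_match_ratio = report$exact_match_ratio,
    n = report$n,
    flags = report$flags
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}

comparison_to_json <- function(comparison, path) {
  payload <- comparison
  if (!is.null(payload$nemenyi)) {
    payload$nemenyi$p_values <- as.data.frame(payload$nemenyi$p_values)
  }
  payload <- c(list(schema = "amenability/comparison_report/v1"), payload)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(path)
}
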