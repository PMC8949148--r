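#' Read a labeled descriptor table
#'
#' Reads an RFC-4180 CSV with a header row, one row per compound: an
#' optional ID column (SMILES or arbitrary), numeric molecular-descriptor
#' columns, and two binary label columns for GC and LC amenability. Label
#' cells may be 1/0, Y/N, yes/no or true/false (case-insensitive); anything
#' else is an error, never silently 0. Non-numeric descriptor cells become
#' `NA` and are counted in the load report; no imputation is performed.
#'
#' @param path Path to the CSV file.
#' @param gc_col,lc_col Names of the two label columns.
#' @param id_col Name of the compound-ID column, or `NULL` to use a column
#'   named `SMILES` if present and row numbers otherwise.
#' @return A list of class `amen_dataset`: `descriptors` (tibble with `.id`
#'   plus the descriptor columns), `labels` (tibble `.id`, `GC`, `LC`), and
#'   `report` (list with `n`, `p`, `n_missing`).
#' @export
read_labeled_table <- function(path, gc_col = "GC", lc_col = "LC", id_col = NULL) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE
  )
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    dups <- unique(nm[duplicated(nm)])
    abort(sprintf("Duplicate feature names in '%s': %s", path, paste(dups, collapse = ", ")))
  }
  for (lab in c(gc_col, lc_col)) {
    if (!lab %in% nm) abort(sprintf("Label column '%s' not found in '%s'", lab, path))
  }
  if (is.null(id_col) && "SMILES" %in% nm) id_col <- "SMILES"
  if (!is.null(id_col) && !id_col %in% nm) {
    abort(sprintf("ID column '%s' not found in '%s'", id_col, path))
  }
  ids <- if (is.null(id_col)) as.character(seq_len(nrow(raw))) else as.character(raw[[id_col]])

  gc <- coerce_label_values(raw[[gc_col]], gc_col)
  lc <- coerce_label_values(raw[[lc_col]], lc_col)

  desc_cols <- setdiff(nm, c(id_col, gc_col, lc_col))
  desc <- lapply(raw[desc_cols], function(x) suppressWarnings(as.numeric(x)))
  desc <- tibble::as_tibble(desc, .name_repair = "minimal")
  n_missing <- sum(vapply(desc, function(x) sum(is.na(x)), integer(1)))

  out <- list(
    descriptors = dplyr::bind_cols(tibble(.id = ids), desc),
    labels = tibble(.id = ids, GC = gc, LC = lc),
    report = list(n = nrow(raw), p = length(desc_cols), n_missing = n_missing)
  )
  class(out) <- "amen_dataset"
  inform(sprintf(
    "Loaded %d compounds x %d descriptors (%d missing cells) from %s",
    out$report$n, out$report$p, out$report$n_missing, path
  ))
  out
}

#' @export
print.amen_dataset <- function(x, ...) {
  cat(sprintf(
    "<amen_dataset> %d compounds, %d descriptors, %d missing cells\n",
    x$report$n, x$report$p, x$report$n_missing
  ))
  cat(sprintf(
    "Labels: GC %d/%d positive, LC %d/%d positive\n",
    sum(x$labels$GC), nrow(x$labels), sum(x$labels$LC), nrow(x$labels)
  ))
  invisible(x)
}

#' Train/test split specification
#'
#' Uniform random split without stratification by default; the test set
#' size is `ceiling(fraction * n)`, so 6431 compounds at fraction 0.2 give
#' the conventional 5144 train / 1287 test partition. Deterministic for a
#' fixed seed. Optional stratification allocates test rows per stratum
#' proportionally (largest-remainder rounding to the same total).
#'
#' @param n Number of rows to split (>= 2).
#' @param fraction Test fraction, strictly between 0 and 1.
#' @param seed Integer seed.
#' @param stratify Optional factor of length `n` to stratify on
#'   (e.g. `interaction(GC, LC)`); default `NULL` = plain split.
#' @return An `amen_split` object: list with integer vectors `train`,
#'   `test` (a partition of `1:n`), plus `n`, `fraction`, `seed`.
#' @export
split_train_test <- function(n, fraction = 0.2, seed = 1L, stratify = NULL) {
  n <- check_count(n, "n", min = 2L)
  check_fraction(fraction, "fraction")
  seed <- check_count(seed, "seed")
  n_test <- as.integer(ceiling(fraction * n))
  test <- withr::with_seed(seed, {
    if (is.null(stratify)) {
      sort(sample.int(n, n_test))
    } else {
      if (length(stratify) != n) abort("'stratify' must have length n")
      g <- as.factor(stratify)
      counts <- table(g)
      exact <- as.numeric(counts) * n_test / n
      base <- floor(exact)
      rem <- n_test - sum(base)
      if (rem > 0) {
        extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
        base[extra] <- base[extra] + 1
      }
      idx <- unlist(lapply(seq_along(levels(g)), function(i) {
        rows <- which(g == levels(g)[i])
        if (base[i] > 0) sample(rows, base[i]) else integer(0)
      }))
      sort(idx)
    }
  })
  structure(
    list(
      train = setdiff(seq_len(n), test), test = test,
      n = n, fraction = fraction, seed = seed,
      stratified = !is.null(stratify)
    ),
    class = "amen_split"
  )
}

#' @export
print.amen_split <- function(x, ...) {
  cat(sprintf(
    "<amen_split> n = %d: %d train / %d test (fraction %.3g, seed %d%s)\n",
    x$n, length(x$train), length(x$test), x$fraction, x$seed,
    if (x$stratified) ", stratified" else ""
  ))
  invisible(x)
}

SCHEMA_TRACE <- "amenability/selection_trace/v1"
SCHEMA_TREE <- "amenability/tree/v1"

#' Write / read a selection trace as JSON
#'
#' The JSON round-trip is lossless: reading a written trace yields an
#' object equal in content. Files carry a schema tag; reading a file with a
#' different tag is an error.
#'
#' @param trace An `amen_selection_trace` from [run_selection_pipeline()].
#' @param path Output path.
#' @return `write_selection_trace()` returns `path` invisibly;
#'   `read_selection_trace()` returns the trace.
#' @export
write_selection_trace <- function(trace, path) {
  stopifnot(inherits(trace, "amen_selection_trace"))
  payload <- list(
    schema = SCHEMA_TRACE,
    stages = purrr::map2(
      trace$stages$stage, trace$stages$features,
      function(s, f) list(stage = s, n_retained = length(f), features = as.list(f))
    ),
    sfs_lists = purrr::map(trace$sfs_lists, as.list),
    overlap = list(
      feature = as.list(trace$overlap$feature),
      count = as.list(trace$overlap$count),
      mean_position = as.list(trace$overlap$mean_position)
    ),
    final = as.list(trace$final),
    config = trace$config
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_selection_trace
#' @export
read_selection_trace <- function(path) {
  payload <- jsonlite::read_json(path)
  if (!identical(payload$schema, SCHEMA_TRACE)) {
    abort(sprintf(
      "Unsupported selection-trace schema '%s' (expected '%s')",
      payload$schema %||% "<none>", SCHEMA_TRACE
    ))
  }
  stages <- tibble(
    stage = purrr::map_chr(payload$stages, "stage"),
    n_retained = purrr::map_int(payload$stages, ~ as.integer(.x$n_retained)),
    features = purrr::map(payload$stages, ~ as.character(unlist(.x$features)))
  )
  structure(
    list(
      stages = stages,
      sfs_lists = purrr::map(payload$sfs_lists, ~ as.character(unlist(.x))),
      overlap = tibble(
        feature = as.character(unlist(payload$overlap$feature)),
        count = as.integer(unlist(payload$overlap$count)),
        mean_position = as.numeric(unlist(payload$overlap$mean_position))
      ),
      final = as.character(unlist(payload$final)),
      config = payload$config
    ),
    class = "amen_selection_trace"
  )
}

#' Write / read a fitted amenability tree as JSON
#'
#' Lossless round-trip of the node array, hyperparameters and training
#' metadata; a reread model reproduces predictions exactly. Files carry a
#' schema tag checked on read.
#'
#' @param model An `amen_tree` from [fit_amen_tree()].
#' @param path Output path.
#' @return `write_amen_tree()` returns `path` invisibly; `read_amen_tree()`
#'   returns the model.
#' @export
write_amen_tree <- function(model, path) {
  stopifnot(inherits(model, "amen_tree"))
  hp <- model$hyperparameters
  if (is.infinite(hp$max_depth)) hp$max_depth <- "Inf" # JSON has no infinity
  payload <- list(
    schema = SCHEMA_TREE,
    nodes = as.list(as.data.frame(model$nodes)),
    hyperparameters = hp,
    features = as.list(model$features),
    n_train = model$n_train,
    seed = model$seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_amen_tree
#' @export
read_amen_tree <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, SCHEMA_TREE)) {
    abort(sprintf(
      "Unsupported tree schema '%s' (expected '%s')",
      payload$schema %||% "<none>", SCHEMA_TREE
    ))
  }
  nodes <- tibble::as_tibble(payload$nodes)
  nodes$feature <- as.character(nodes$feature)
  for (col in c("id", "depth", "left", "right", "n")) {
    nodes[[col]] <- as.integer(nodes[[col]])
  }
  hp <- as.list(payload$hyperparameters)
  if (!is.null(hp$max_depth)) hp$max_depth <- as.numeric(hp$max_depth)
  structure(
    list(
      nodes = nodes,
      hyperparameters = hp,
      features = as.character(payload$features),
      n_train = as.integer(payload$n_train),
      seed = as.integer(payload$seed)
    ),
    class = "amen_tree"
  )
}

#' Write predictions to CSV
#'
#' Standard prediction export: one row per compound with the binary
#' predictions and, when scores are given, the per-label class-1 scores.
#'
#' @param ids Character vector of compound IDs.
#' @param pred Tibble/matrix with binary `GC`, `LC` predictions.
#' @param path Output path.
#' @param scores Optional tibble/matrix with numeric `GC`, `LC` scores.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(ids, pred, path, scores = NULL) {
  p <- as_label_matrix(pred, "pred")
  out <- tibble(
    ID = as.character(ids),
    GC_pred = p[, 1], LC_pred = p[, 2]
  )
  if (!is.null(scores)) {
    s <- as.matrix(as.data.frame(scores))
    out$GC_score <- as.numeric(s[, 1])
    out$LC_score <- as.numeric(s[, 2])
  }
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
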