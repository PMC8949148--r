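# Shared coercion and validation helpers. The two platform labels are always
# handled in the fixed column order (GC, LC).

LABEL_COLS <- c("GC", "LC")

# Values accepted when coercing label columns to 0/1; anything else errors.
LABEL_COERCION <- c(
  "1" = 1L, "0" = 0L,
  "y" = 1L, "n" = 0L,
  "yes" = 1L, "no" = 0L,
  "true" = 1L, "false" = 0L
)

coerce_label_values <- function(x, column = "label") {
  if (is.logical(x)) {
    return(as.integer(x))
  }
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) {
      bad <- unique(x[!x %in% c(0, 1)])
      abort(sprintf(
        "Label column '%s' contains non-binary values: %s",
        column, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
    return(as.integer(x))
  }
  key <- tolower(trimws(as.character(x)))
  out <- LABEL_COERCION[key]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    abort(sprintf(
      "Label column '%s' contains values outside the coercion table (1/0, Y/N, yes/no, true/false): %s",
      column, paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  unname(out)
}

# Canonical n x 2 integer label matrix with columns GC, LC.
as_label_matrix <- function(labels, arg = "labels") {
  if (is.matrix(labels)) {
    m <- labels
    if (is.null(colnames(m))) {
      if (ncol(m) != 2) abort(sprintf("'%s' must have two columns (GC, LC)", arg))
      colnames(m) <- LABEL_COLS
    }
  } else if (is.data.frame(labels)) {
    missing <- setdiff(LABEL_COLS, names(labels))
    if (length(missing) > 0) {
      abort(sprintf("'%s' lacks label column(s): %s", arg, paste(missing, collapse = ", ")))
    }
    m <- cbind(GC = labels[["GC"]], LC = labels[["LC"]])
  } else {
    abort(sprintf("'%s' must be a data frame or matrix with GC and LC columns", arg))
  }
  m <- m[, LABEL_COLS, drop = FALSE]
  storage.mode(m) <- "integer"
  if (anyNA(m) || !all(m %in% c(0L, 1L))) {
    abort(sprintf("'%s' entries must all be 0 or 1", arg))
  }
  m
}

label_tibble <- function(m) {
  tibble(GC = as.integer(m[, 1]), LC = as.integer(m[, 2]))
}

# Numeric descriptor matrix for a set of feature columns.
descriptor_matrix <- function(data, features, require_finite = FALSE) {
  if (!is.data.frame(data)) abort("'data' must be a data frame of descriptors")
  missing <- setdiff(features, names(data))
  if (length(missing) > 0) {
    abort(sprintf("Feature column(s) not found: %s", paste(missing, collapse = ", ")))
  }
  x <- as.matrix(as.data.frame(lapply(data[features], as.numeric)))
  colnames(x) <- features
  if (require_finite) {
    bad <- features[!vapply(seq_along(features), function(j) all(is.finite(x[, j])), logical(1))]
    if (length(bad) > 0) {
      abort(sprintf(
        "Non-finite values in selected feature column(s): %s",
        paste(bad, collapse = ", ")
      ))
    }
  }
  x
}

# Feature columns of a table = everything except the id column and labels.
feature_names_of <- function(data, id_col = ".id") {
  setdiff(names(data), c(id_col, LABEL_COLS))
}

check_fraction <- function(x, arg, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) abort(sprintf("'%s' must be a number", arg))
  if (open && (x <= 0 || x >= 1)) abort(sprintf("'%s' must lie strictly between 0 and 1", arg))
  invisible(x)
}

check_count <- function(x, arg, min = 0L) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x != round(x) || x < min) {
    abort(sprintf("'%s' must be an integer >= %d", arg, min))
  }
  invisible(as.integer(x))
}

# Joint 4-class product label used when a single-output learner has to model
# the two binary outputs together: levels 0..3 encode (GC, LC) as 2*GC + LC.
joint_label_factor <- function(label_matrix) {
  factor(2L * label_matrix[, 1] + label_matrix[, 2], levels = 0:3)
}

joint_label_decode <- function(f) {
  v <- as.integer(as.character(f))
  cbind(GC = v %/% 2L, LC = v %% 2L)
}
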