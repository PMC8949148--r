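#' Expert rule thresholds for GC/LC amenability
#'
#' The baseline classifier encodes what an analytical chemist would check
#' before choosing a platform: a compound is GC-amenable when it is volatile
#' enough (boiling point between `bp_min` and `bp_max`, both inclusive), not
#' too heavy (molecular weight strictly below `mw_max`) and apolar enough
#' (logP strictly above `gc_logp_min`); it is LC-amenable (reversed phase)
#' when it is polar enough, logP strictly below `lc_logp_max`.
#'
#' @param bp_min,bp_max Boiling point window in degrees Celsius (inclusive).
#' @param mw_max Molecular weight cap in Dalton (strict).
#' @param gc_logp_min Lower logP bound for GC (strict).
#' @param lc_logp_max Upper logP bound for LC (strict).
#' @return A `rule_thresholds` object (named list).
#' @export
rule_thresholds <- function(bp_min = 100, bp_max = 350, mw_max = 700,
                            gc_logp_min = 2, lc_logp_max = 5.91) {
  for (a in c("bp_min", "bp_max", "mw_max", "gc_logp_min", "lc_logp_max")) {
    v <- get(a)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) abort(sprintf("'%s' must be a number", a))
  }
  if (bp_min >= bp_max) abort("'bp_min' must be smaller than 'bp_max'")
  if (mw_max <= 0) abort("'mw_max' must be positive")
  structure(
    list(
      bp_min = bp_min, bp_max = bp_max, mw_max = mw_max,
      gc_logp_min = gc_logp_min, lc_logp_max = lc_logp_max
    ),
    class = "rule_thresholds"
  )
}

#' @export
print.rule_thresholds <- function(x, ...) {
  cat(sprintf(
    "Amenability rule thresholds:\n  GC: %g <= BP <= %g degC, MW < %g Da, logP > %g\n  LC: logP < %g\n",
    x$bp_min, x$bp_max, x$mw_max, x$gc_logp_min, x$lc_logp_max
  ))
  invisible(x)
}

#' Rule-based amenability classification
#'
#' Applies the expert thresholds to vectors of boiling point, molecular
#' weight and logP. The two labels are assigned independently
#' (multi-label): GC = 1 iff `bp_min <= bp <= bp_max` and `mw < mw_max` and
#' `logp > gc_logp_min`; LC = 1 iff `logp < lc_logp_max`. Boundary
#' semantics: the boiling-point window is inclusive at both ends, the MW
#' and logP comparisons are strict. Deterministic and free of randomness.
#'
#' `NA` inputs yield `NA` labels; [predict_rule()] turns those rows into
#' (0, 0) with a warning, the convention for batch screening.
#'
#' @param bp,mw,logp Numeric vectors (degrees Celsius, Dalton,
#'   dimensionless), recycled to a common length.
#' @param thresholds A [rule_thresholds()] object.
#' @return Tibble with integer columns `GC` and `LC`.
#' @examples
#' classify_rule(bp = 200, mw = 300, logp = 3) # GC = 1, LC = 1
#' @export
classify_rule <- function(bp, mw, logp, thresholds = rule_thresholds()) {
  stopifnot(inherits(thresholds, "rule_thresholds"))
  k <- recycle_common(bp, mw, logp)
  bp <- k[[1]]; mw <- k[[2]]; logp <- k[[3]]
  gc <- (bp >= thresholds$bp_min) & (bp <= thresholds$bp_max) &
    (mw < thresholds$mw_max) & (logp > thresholds$gc_logp_min)
  lc <- logp < thresholds$lc_logp_max
  tibble(GC = as.integer(gc), LC = as.integer(lc))
}

# minimal common-length recycling (scalars only)
recycle_common <- function(...) {
  xs <- list(...)
  n <- max(lengths(xs))
  lapply(xs, function(x) {
    if (length(x) == n) x
    else if (length(x) == 1) rep(x, n)
    else abort("inputs must have equal length or length 1")
  })
}

#' Apply the rule-based classifier to a descriptor table
#'
#' Row-wise application of [classify_rule()] to three mapped descriptor
#' columns. Rows with a missing value in any mapped column are classified
#' (0, 0) and counted in a warning; screening a batch never aborts on
#' sparse rows.
#'
#' @param data Data frame holding the descriptor columns.
#' @param column_map Named character vector mapping `bp`, `mw`, `logp` to
#'   column names of `data`.
#' @param thresholds A [rule_thresholds()] object.
#' @return Tibble with integer columns `GC`, `LC`, one row per row of
#'   `data`. Attribute `n_missing` holds the number of rows zeroed for
#'   missing inputs.
#' @export
predict_rule <- function(data,
                         column_map = c(bp = "BoilingPoint", mw = "MW", logp = "logP"),
                         thresholds = rule_thresholds()) {
  if (!is.data.frame(data)) abort("'data' must be a data frame")
  needed <- c("bp", "mw", "logp")
  if (!all(needed %in% names(column_map))) {
    abort("'column_map' must name entries bp, mw and logp")
  }
  missing_cols <- setdiff(unname(column_map[needed]), names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Mapped column(s) absent from data: %s", paste(missing_cols, collapse = ", ")))
  }
  bp <- as.numeric(data[[column_map[["bp"]]]])
  mw <- as.numeric(data[[column_map[["mw"]]]])
  logp <- as.numeric(data[[column_map[["logp"]]]])
  out <- classify_rule(bp, mw, logp, thresholds)
  incomplete <- is.na(bp) | is.na(mw) | is.na(logp)
  if (any(incomplete)) {
    warn(sprintf(
      "%d row(s) with missing boiling point/MW/logP classified as neither GC nor LC",
      sum(incomplete)
    ))
    out$GC[incomplete] <- 0L
    out$LC[incomplete] <- 0L
  }
  attr(out, "n_missing") <- sum(incomplete)
  out
}
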