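#' Configuration for the synthetic descriptor generator
#'
#' Describes a synthetic screening dataset whose labels follow the expert
#' rule on three latent physicochemical descriptors, with controlled
#' nuisance structure around them. Defaults are the study conditions used
#' throughout the package's recovery simulations: 2000 compounds, 5% label
#' noise, 10 redundant, 5 quasi-constant and 50 irrelevant columns.
#'
#' The latent descriptors cover every rule threshold so that all four label
#' combinations occur: boiling point uniform on 0-600 degC, molecular
#' weight log-uniform on 50-1500 Da, logP uniform on -5 to 12. These are
#' documented constants of the generator, not tunable arguments.
#'
#' @param n_compounds Number of rows.
#' @param label_noise Probability in \[0, 0.5) that each label bit is
#'   independently flipped after applying the rule.
#' @param n_redundant Number of rank-correlated monotone copies of randomly
#'   chosen informative columns.
#' @param n_quasi_constant Number of columns with a single value in > 99%
#'   of rows.
#' @param n_noise Number of irrelevant standard-normal columns.
#' @param thresholds [rule_thresholds()] generating the labels.
#' @param seed Integer seed; the generator is a pure function of this
#'   configuration.
#' @return A `amen_sim_config` object (named list).
#' @export
synthetic_config <- function(n_compounds = 2000, label_noise = 0.05,
                             n_redundant = 10, n_quasi_constant = 5,
                             n_noise = 50, thresholds = rule_thresholds(),
                             seed = 1L) {
  n_compounds <- check_count(n_compounds, "n_compounds", min = 4L)
  if (!is.numeric(label_noise) || label_noise < 0 || label_noise >= 0.5) {
    abort("'label_noise' must lie in [0, 0.5)")
  }
  n_redundant <- check_count(n_redundant, "n_redundant")
  n_quasi_constant <- check_count(n_quasi_constant, "n_quasi_constant")
  n_noise <- check_count(n_noise, "n_noise")
  stopifnot(inherits(thresholds, "rule_thresholds"))
  seed <- check_count(seed, "seed")
  structure(
    list(
      n_compounds = n_compounds, label_noise = label_noise,
      n_redundant = n_redundant, n_quasi_constant = n_quasi_constant,
      n_noise = n_noise, thresholds = thresholds, seed = seed
    ),
    class = "amen_sim_config"
  )
}

# latent distributions straddling every rule threshold (fixed constants)
SIM_BP_RANGE <- c(0, 600)
SIM_MW_RANGE <- c(50, 1500)
SIM_LOGP_RANGE <- c(-5, 12)

#' Generate a synthetic descriptor table with planted structure
#'
#' Draws the three informative descriptors (`BoilingPoint`, `MW`, `logP`),
#' derives true labels from the expert rule, flips each label bit with
#' probability `label_noise`, then pads the table with redundant columns
#' (strictly monotone transforms - scale/shift, exponential, cube - of a
#' random informative parent plus small noise, population rank correlation
#' > 0.95), quasi-constant columns (one value in > 99% of rows) and
#' independent noise columns. Bit-identical for identical configurations.
#'
#' @param config An [synthetic_config()] object.
#' @return List of class `amen_sim`: `data` (tibble `.id` + descriptor
#'   columns), `labels` (tibble `.id`, `GC`, `LC`), `truth` (name sets
#'   `informative`, `redundant`, `quasi_constant`, `noise`, plus
#'   `redundant_parent`, the parent of each redundant column).
#' @export
generate_descriptors <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "amen_sim_config"))
  n <- config$n_compounds
  withr::with_seed(config$seed, {
    bp <- runif(n, SIM_BP_RANGE[1], SIM_BP_RANGE[2])
    mw <- exp(runif(n, log(SIM_MW_RANGE[1]), log(SIM_MW_RANGE[2])))
    logp <- runif(n, SIM_LOGP_RANGE[1], SIM_LOGP_RANGE[2])
    labels <- as_label_matrix(classify_rule(bp, mw, logp, config$thresholds))
    if (config$label_noise > 0) {
      flips <- matrix(runif(2L * n) < config$label_noise, nrow = n)
      labels <- 1L * xor(labels == 1L, flips)
    }

    informative <- data.frame(BoilingPoint = bp, MW = mw, logP = logp)
    cols <- informative
    parents <- character(0)
    if (config$n_redundant > 0) {
      red <- lapply(seq_len(config$n_redundant), function(i) {
        parent <- sample(names(informative), 1)
        x <- informative[[parent]]
        # jitter on the parent scale BEFORE the strictly monotone transform,
        # so the rank correlation with the parent stays > 0.95 regardless of
        # how strongly the transform warps the spacing
        xn <- x + rnorm(n, 0, 0.02 * sd(x))
        kind <- sample(c("affine", "exp", "cube"), 1)
        y <- switch(kind,
          affine = runif(1, 0.5, 2) * xn + runif(1, -10, 10),
          # scale into [-3, 3] before exponentiating to keep values finite
          exp = exp((xn - min(xn)) / (max(xn) - min(xn)) * 6 - 3),
          cube = ((xn - mean(xn)) / sd(xn))^3
        )
        list(parent = parent, values = y)
      })
      red_df <- as.data.frame(lapply(red, `[[`, "values"))
      names(red_df) <- sprintf("Redundant%02d", seq_len(config$n_redundant))
      parents <- setNames(
        vapply(red, `[[`, character(1), "parent"),
        names(red_df)
      )
      cols <- cbind(cols, red_df)
    }
    if (config$n_quasi_constant > 0) {
      qc_df <- as.data.frame(lapply(seq_len(config$n_quasi_constant), function(i) {
        # guarantee the modal value covers > 99% of rows
        n_modal <- max(ceiling(0.995 * n), floor(0.99 * n) + 1L)
        v <- runif(n, -1, 1)
        v[sample.int(n, n_modal)] <- 0
        v
      }))
      names(qc_df) <- sprintf("QuasiConst%02d", seq_len(config$n_quasi_constant))
      cols <- cbind(cols, qc_df)
    }
    if (config$n_noise > 0) {
      noise_df <- as.data.frame(matrix(rnorm(n * config$n_noise), nrow = n))
      names(noise_df) <- sprintf("Noise%02d", seq_len(config$n_noise))
      cols <- cbind(cols, noise_df)
    }

    ids <- sprintf("CPD%06d", seq_len(n))
    structure(
      list(
        data = dplyr::bind_cols(tibble(.id = ids), tibble::as_tibble(cols)),
        labels = tibble(.id = ids, GC = labels[, 1], LC = labels[, 2]),
        truth = list(
          informative = names(informative),
          redundant = grep("^Redundant", names(cols), value = TRUE),
          quasi_constant = grep("^QuasiConst", names(cols), value = TRUE),
          noise = grep("^Noise", names(cols), value = TRUE),
          redundant_parent = as.list(parents)
        ),
        config = config
      ),
      class = "amen_sim"
    )
  })
}

#' @export
print.amen_sim <- function(x, ...) {
  cat(sprintf(
    "<amen_sim> %d compounds x %d descriptors (3 informative, %d redundant, %d quasi-constant, %d noise), label noise %.3g, seed %d\n",
    nrow(x$data), length(feature_names_of(x$data)),
    length(x$truth$redundant), length(x$truth$quasi_constant),
    length(x$truth$noise), x$config$label_noise, x$config$seed
  ))
  invisible(x)
}

#' Serialize / restore a synthetic configuration
#'
#' JSON round-trip helper so a simulation can be reproduced from a sidecar
#' file: an identical configuration regenerates bit-identical output.
#'
#' @param config An `amen_sim_config`.
#' @param path File path.
#' @return `write_synthetic_config()` returns `path` invisibly;
#'   `read_synthetic_config()` returns the configuration.
#' @export
write_synthetic_config <- function(config, path) {
  stopifnot(inherits(config, "amen_sim_config"))
  payload <- unclass(config)
  payload$thresholds <- unclass(payload$thresholds)
  payload$schema <- "amenability/sim_config/v1"
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_synthetic_config
#' @export
read_synthetic_config <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(payload$schema, "amenability/sim_config/v1")) {
    abort("Unsupported synthetic-config schema")
  }
  synthetic_config(
    n_compounds = payload$n_compounds, label_noise = payload$label_noise,
    n_redundant = payload$n_redundant, n_quasi_constant = payload$n_quasi_constant,
    n_noise = payload$n_noise,
    thresholds = do.call(rule_thresholds, payload$thresholds),
    seed = payload$seed
  )
}
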