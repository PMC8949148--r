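# Multi-output CART for the two amenability labels. One tree is grown
# jointly on (GC, LC): the impurity of a node is the mean of the two
# per-label binary impurities, so a split must pay off on average across
# the outputs. Leaves store per-label class-1 proportions.

impurity_fun <- function(criterion) {
  if (criterion == "gini") {
    function(p) 2 * p * (1 - p)
  } else {
    function(p) {
      h <- numeric(length(p))
      ok <- p > 0 & p < 1
      q <- p[ok]
      h[ok] <- -(q * log2(q) + (1 - q) * log2(1 - q))
      h
    }
  }
}

#' Fit a multi-output decision tree for GC/LC amenability
#'
#' Grows a single CART on the two binary labels jointly: candidate splits
#' are scored by the weighted mean over children of the node impurity,
#' itself the average of the per-label binary Gini (or entropy) impurities.
#' Growth at a node stops when it is pure on both labels, smaller than
#' `min_samples_split`, at `max_depth`, or when no split with positive
#' impurity decrease respects `min_samples_leaf`. With `max_features`
#' `"auto"` or `"sqrt"` each node examines a random subset of
#' `floor(sqrt(p))` features (both tokens mean square root; `"auto"` is
#' kept for familiarity), which is the only source of randomness - the fit
#' is deterministic for a fixed seed.
#'
#' @param data Data frame holding the descriptor columns (extra columns are
#'   ignored).
#' @param labels Data frame/matrix with binary `GC`, `LC` columns, aligned
#'   by row with `data`.
#' @param features Character vector of feature columns to use; default all
#'   columns except `.id`, `GC`, `LC`. Selected columns must be finite.
#' @param criterion `"gini"` or `"entropy"`.
#' @param max_depth Maximum depth (root = depth 0); `Inf` = unlimited.
#' @param min_samples_split Minimum node size eligible for splitting.
#' @param min_samples_leaf Minimum child size.
#' @param max_features `"none"` (all features at every node), `"auto"` or
#'   `"sqrt"` (random subset of size `floor(sqrt(p))`).
#' @param seed Integer seed for the per-node feature subsampling.
#' @return An `amen_tree`: list with `nodes` (tibble: `id`, `depth`,
#'   `feature`, `threshold`, `left`, `right`, `n`, `p_gc`, `p_lc`),
#'   `hyperparameters`, `features`, `n_train`, `seed`. Internal nodes send
#'   `x <= threshold` to `left`.
#' @export
fit_amen_tree <- function(data, labels, features = NULL,
                          criterion = c("gini", "entropy"),
                          max_depth = Inf, min_samples_split = 2L,
                          min_samples_leaf = 1L,
                          max_features = c("none", "auto", "sqrt"),
                          seed = 1L) {
  criterion <- match.arg(criterion)
  max_features <- match.arg(max_features)
  features <- features %||% feature_names_of(data)
  if (length(features) == 0) abort("No feature columns to fit on")
  X <- descriptor_matrix(data, features, require_finite = TRUE)
  Y <- as_label_matrix(labels)
  if (nrow(X) != nrow(Y)) abort("'data' and 'labels' must have the same number of rows")
  if (nrow(X) == 0) abort("Empty training table")
  min_samples_split <- max(2L, check_count(min_samples_split, "min_samples_split", 1L))
  min_samples_leaf <- check_count(min_samples_leaf, "min_samples_leaf", 1L)
  seed <- check_count(seed, "seed")
  if (!(is.numeric(max_depth) && length(max_depth) == 1 && (is.infinite(max_depth) || max_depth >= 0))) {
    abort("'max_depth' must be a non-negative number or Inf")
  }
  p <- ncol(X)
  imp <- impurity_fun(criterion)
  mtry <- if (max_features == "none") p else max(1L, floor(sqrt(p)))

  node_impurity <- function(y1, y2) (imp(mean(y1)) + imp(mean(y2))) / 2

  best_split <- function(idx, cand) {
    n_node <- length(idx)
    y1 <- Y[idx, 1]
    y2 <- Y[idx, 2]
    t1 <- sum(y1)
    t2 <- sum(y2)
    parent <- node_impurity(y1, y2)
    best <- NULL
    lo <- min_samples_leaf
    hi <- n_node - min_samples_leaf
    if (hi < lo) return(NULL)
    for (f in cand) {
      x <- X[idx, f]
      o <- order(x)
      xs <- x[o]
      pos <- lo:hi
      pos <- pos[xs[pos] < xs[pos + 1]]
      if (length(pos) == 0) next
      c1 <- cumsum(y1[o])[pos]
      c2 <- cumsum(y2[o])[pos]
      nl <- pos
      nr <- n_node - pos
      child <- (nl * (imp(c1 / nl) + imp(c2 / nl)) +
        nr * (imp((t1 - c1) / nr) + imp((t2 - c2) / nr))) / (2 * n_node)
      j <- which.min(child) # ties -> smallest threshold
      if (parent - child[j] > 1e-12 &&
        (is.null(best) || child[j] < best$score - 1e-15)) {
        best <- list(
          feature = f, score = child[j],
          threshold = (xs[pos[j]] + xs[pos[j] + 1]) / 2
        )
      }
    }
    best
  }

  withr::with_seed(seed, {
    nodes <- list()
    # stack entries: row indices, depth, parent node id, side ("left"/"right")
    stack <- list(list(idx = seq_len(nrow(X)), depth = 0L, parent = NA_integer_, side = NA_character_))
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      id <- length(nodes) + 1L
      if (!is.na(cur$parent)) nodes[[cur$parent]][[cur$side]] <- id
      y1 <- Y[cur$idx, 1]
      y2 <- Y[cur$idx, 2]
      node <- list(
        id = id, depth = cur$depth, feature = NA_character_,
        threshold = NA_real_, left = NA_integer_, right = NA_integer_,
        n = length(cur$idx), p_gc = mean(y1), p_lc = mean(y2)
      )
      pure <- (node$p_gc %in% c(0, 1)) && (node$p_lc %in% c(0, 1))
      can_split <- !pure && cur$depth < max_depth && node$n >= min_samples_split
      split <- NULL
      if (can_split) {
        cand <- if (mtry < p) sort(sample.int(p, mtry)) else seq_len(p)
        split <- best_split(cur$idx, cand)
      }
      if (!is.null(split)) {
        node$feature <- features[split$feature]
        node$threshold <- split$threshold
        go_left <- X[cur$idx, split$feature] <= split$threshold
        nodes[[id]] <- node
        # push right first so the left child is processed next (preorder ids)
        stack[[length(stack) + 1L]] <- list(
          idx = cur$idx[!go_left], depth = cur$depth + 1L, parent = id, side = "right"
        )
        stack[[length(stack) + 1L]] <- list(
          idx = cur$idx[go_left], depth = cur$depth + 1L, parent = id, side = "left"
        )
      } else {
        nodes[[id]] <- node
      }
    }
    nodes_tbl <- dplyr::bind_rows(lapply(nodes, tibble::as_tibble))
    structure(
      list(
        nodes = nodes_tbl,
        hyperparameters = list(
          criterion = criterion, max_depth = max_depth,
          min_samples_split = min_samples_split,
          min_samples_leaf = min_samples_leaf, max_features = max_features
        ),
        features = features,
        n_train = nrow(X),
        seed = seed
      ),
      class = "amen_tree"
    )
  })
}

#' @export
print.amen_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<amen_tree> %d nodes (%d leaves), depth %d, criterion %s, fitted on %d compounds x %d features\n",
    g$n_nodes, g$n_leaves, g$depth, x$hyperparameters$criterion,
    x$n_train, length(x$features)
  ))
  invisible(x)
}

#' Predict amenability labels or scores from a fitted tree
#'
#' Routes each row down the tree (`x <= threshold` goes left). Scores are
#' the training class-1 proportions of the reached leaf, one per label;
#' classes are `score >= 0.5` (a tie at exactly 0.5 is classified
#' positive). Columns not used by the model are ignored.
#'
#' @param object An `amen_tree`.
#' @param data Data frame containing at least the model's feature columns
#'   with finite values.
#' @param type `"class"` for binary labels, `"score"` for leaf proportions.
#' @param ... Unused.
#' @return Tibble with columns `GC` and `LC` (integer or numeric).
#' @export
predict.amen_tree <- function(object, data, type = c("class", "score"), ...) {
  type <- match.arg(type)
  X <- descriptor_matrix(data, object$features, require_finite = TRUE)
  nd <- object$nodes
  feat_idx <- match(nd$feature, object$features)
  n <- nrow(X)
  cur <- rep(1L, n)
  repeat {
    internal <- !is.na(feat_idx[cur])
    if (!any(internal)) break
    rows <- which(internal)
    f <- feat_idx[cur[rows]]
    xv <- X[cbind(rows, f)]
    thr <- nd$threshold[cur[rows]]
    cur[rows] <- ifelse(xv <= thr, nd$left[cur[rows]], nd$right[cur[rows]])
  }
  scores <- tibble(GC = nd$p_gc[cur], LC = nd$p_lc[cur])
  if (type == "score") {
    scores
  } else {
    tibble(GC = as.integer(scores$GC >= 0.5), LC = as.integer(scores$LC >= 0.5))
  }
}

#' @describeIn fit_amen_tree Node array as a tibble.
#' @param x An `amen_tree` object.
#' @param ... Unused.
#' @export
tidy.amen_tree <- function(x, ...) {
  x$nodes
}

#' @describeIn fit_amen_tree One-row structural summary.
#' @export
glance.amen_tree <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_leaves = sum(is.na(x$nodes$feature)),
    depth = max(x$nodes$depth),
    criterion = x$hyperparameters$criterion,
    max_depth = x$hyperparameters$max_depth,
    n_train = x$n_train
  )
}

#' Export a fitted tree to DOT
#'
#' One DOT node per tree node; internal nodes are labeled with their split,
#' leaves with their per-label class-1 proportions. Edges are labeled
#' `<=` and `>`.
#'
#' @param model An `amen_tree`.
#' @return A single DOT digraph string.
#' @export
export_dot <- function(model) {
  stopifnot(inherits(model, "amen_tree"))
  nd <- model$nodes
  lines <- c("digraph amenability_tree {", "  node [shape=box];")
  for (i in seq_len(nrow(nd))) {
    label <- if (is.na(nd$feature[i])) {
      sprintf("n=%d\\nP(GC)=%.3f\\nP(LC)=%.3f", nd$n[i], nd$p_gc[i], nd$p_lc[i])
    } else {
      sprintf("%s <= %.6g\\nn=%d", nd$feature[i], nd$threshold[i], nd$n[i])
    }
    lines <- c(lines, sprintf("  node%d [label=\"%s\"];", nd$id[i], label))
  }
  internal <- which(!is.na(nd$feature))
  for (i in internal) {
    lines <- c(
      lines,
      sprintf("  node%d -> node%d [label=\"<=\"];", nd$id[i], nd$left[i]),
      sprintf("  node%d -> node%d [label=\">\"];", nd$id[i], nd$right[i])
    )
  }
  paste(c(lines, "}"), collapse = "\n")
}
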