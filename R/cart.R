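# Bespoke CART engine: binary, order-respecting splits (value <= t) on
# ordinal predictors, Gini heterogeneity criterion, optional class weights,
# no pruning, no surrogate splits.  Trained on the full sample by design.

#' Control parameters for tree growing
#'
#' @param min_parent Minimum number of rows a node needs to be considered
#'   for splitting (default 10).
#' @param min_child Minimum number of rows in each child of a split
#'   (default 5).
#' @param max_depth Maximum tree depth; 0 = root only (default 5).
#' @param min_decrease Minimum weighted Gini decrease a split must achieve
#'   (default 1e-4).
#' @param class_weights Named weights for classes \code{poor} and
#'   \code{satisfactory}; raising the \code{poor} weight pushes the tree
#'   toward sensitivity (default equal weights).
#' @return A list of class \code{tree_control}.
#' @export
treeControl <- function(min_parent = 10, min_child = 5, max_depth = 5,
                        min_decrease = 1e-4,
                        class_weights = c(poor = 1, satisfactory = 1)) {
  stopifnot(
    min_parent >= 2, min_child >= 1, max_depth >= 0, min_decrease >= 0,
    all(class_weights > 0), all(c("poor", "satisfactory") %in% names(class_weights))
  )
  structure(
    list(
      min_parent = min_parent, min_child = min_child, max_depth = max_depth,
      min_decrease = min_decrease,
      class_weights = class_weights[c("poor", "satisfactory")]
    ),
    class = "tree_control"
  )
}

#' Gini heterogeneity of a two-class node
#'
#' \eqn{G = 1 - \sum_k p_k^2}; 0 for a pure node, 0.5 at a balanced binary
#' node.
#'
#' @param counts Numeric vector of nonnegative class counts (or weighted
#'   counts), not all zero.
#' @return Impurity in \code{[0, 0.5]} for two classes.
#' @export
#' @examples
#' gini(c(28, 113))
gini <- function(counts) {
  if (any(counts < 0)) stop("class counts must be nonnegative", call. = FALSE)
  total <- sum(counts)
  if (total == 0) stop("undefined node: all class counts are zero", call. = FALSE)
  p <- counts / total
  1 - sum(p^2)
}

as_outcome <- function(y) {
  y <- as.character(y)
  bad <- !y %in% c("poor", "satisfactory")
  if (any(bad)) {
    stop("outcome labels must be 'poor' or 'satisfactory'", call. = FALSE)
  }
  factor(y, levels = c("satisfactory", "poor"))
}

node_counts <- function(y) {
  c(poor = sum(y == "poor"), satisfactory = sum(y == "satisfactory"))
}

node_class <- function(counts, weights) {
  w <- counts * weights[names(counts)]
  # tie goes to at_risk: a sensitivity-first default for a screening rule
  if (w["poor"] >= w["satisfactory"]) "at_risk" else "not_at_risk"
}

check_predictors <- function(data, predictors) {
  for (p in predictors) {
    v <- data[[p]]
    if (is.null(v)) stop(sprintf("predictor '%s' not found in data", p), call. = FALSE)
    bad <- which(!is.finite(v) | v < 0 | v > 4 | v != round(v))
    if (length(bad)) {
      stop(sprintf(
        "predictor '%s' has non-finite or out-of-range values in row(s) %s",
        p, paste(utils::head(bad, 10), collapse = ", ")
      ), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Find the best Gini split of a node
#'
#' Exhaustively evaluates every (predictor, threshold) pair, with ordinal
#' thresholds \code{t} in 0..3 routing \code{value <= t} to the left child,
#' and returns the pair maximizing the weighted Gini decrease
#' \eqn{\Delta = G(parent) - (n_L/n) G(L) - (n_R/n) G(R)} (all quantities
#' on class-weighted counts).  Ties are broken by predictor order, then by
#' the lower threshold, so the search is deterministic.
#'
#' @param data Data frame of ordinal predictors (integer values 0-4).
#' @param y Outcome labels, \code{poor} / \code{satisfactory}.
#' @param predictors Character vector of predictor columns to consider.
#' @param control A \code{\link{treeControl}} list.
#' @return List with \code{predictor}, \code{threshold}, \code{decrease},
#'   or \code{NULL} when no admissible split reaches \code{min_decrease}.
#' @export
bestSplit <- function(data, y, predictors, control = treeControl()) {
  if (length(predictors) == 0L) {
    stop("empty predictor set", call. = FALSE)
  }
  y <- as_outcome(y)
  w <- control$class_weights
  counts <- node_counts(y)
  if (any(counts == 0)) {
    return(NULL) # pure node
  }
  wtot <- counts * w[names(counts)]
  g_parent <- gini(wtot)
  n_w <- sum(wtot)
  best <- NULL
  best_d <- -Inf
  for (p in predictors) {
    x <- data[[p]]
    # class-by-level counts, cumulated over levels = all thresholds at once
    lev <- factor(x, levels = 0:4)
    tab_poor <- cumsum(tabulate(as.integer(lev)[y == "poor"], nbins = 5))
    tab_sat <- cumsum(tabulate(as.integer(lev)[y == "satisfactory"], nbins = 5))
    for (t in 0:3) {
      nl_poor <- tab_poor[t + 1]
      nl_sat <- tab_sat[t + 1]
      nl <- nl_poor + nl_sat
      nr <- length(x) - nl
      if (nl < control$min_child || nr < control$min_child) next
      wl <- c(nl_poor, nl_sat) * w[c("poor", "satisfactory")]
      wr <- c(counts["poor"] - nl_poor, counts["satisfactory"] - nl_sat) *
        w[c("poor", "satisfactory")]
      d <- g_parent - sum(wl) / n_w * gini(wl) - sum(wr) / n_w * gini(wr)
      if (d > best_d + 1e-12) {
        best_d <- d
        best <- list(predictor = p, threshold = t, decrease = d)
      }
    }
  }
  if (is.null(best) || best_d < control$min_decrease) {
    return(NULL)
  }
  best
}

#' Grow a classification tree by recursive partitioning
#'
#' Greedy binary induction with the Gini criterion: at each node the best
#' admissible split (\code{\link{bestSplit}}) is applied until a stopping
#' rule fires (node smaller than \code{min_parent}, depth at
#' \code{max_depth}, node pure, or no split achieving \code{min_decrease}).
#' The full sample is used for training; there is no pruning and no
#' internal train/test split.  The result is deterministic given the data
#' and control settings.
#'
#' @param data Data frame holding the predictor columns (ordinal 0-4).
#' @param outcome Outcome labels aligned with \code{data} rows
#'   (\code{poor} / \code{satisfactory}).
#' @param predictors Character vector of predictor column names.
#' @param control A \code{\link{treeControl}} list.
#' @return An object of class \code{womac_tree}.  Leaves predict
#'   \code{at_risk} / \code{not_at_risk} by the class-weighted majority.
#' @export
growTree <- function(data, outcome, predictors, control = treeControl()) {
  y <- as_outcome(outcome)
  if (length(y) != nrow(data)) {
    stop("outcome length must match the number of rows", call. = FALSE)
  }
  if (anyNA(y)) stop("missing outcome labels are not allowed", call. = FALSE)
  check_predictors(data, predictors)
  if (nrow(data) < control$min_parent) {
    stop(sprintf(
      "need at least min_parent = %d rows to grow a tree", control$min_parent
    ), call. = FALSE)
  }
  grow <- function(idx, depth) {
    ys <- y[idx]
    counts <- node_counts(ys)
    node <- list(
      n = length(idx), counts = counts,
      class = node_class(counts, control$class_weights),
      depth = depth, split = NULL, left = NULL, right = NULL
    )
    if (depth >= control$max_depth || length(idx) < control$min_parent ||
      any(counts == 0)) {
      return(node)
    }
    s <- bestSplit(data[idx, , drop = FALSE], ys, predictors, control)
    if (is.null(s)) {
      return(node)
    }
    left_idx <- idx[data[[s$predictor]][idx] <= s$threshold]
    right_idx <- setdiff(idx, left_idx)
    node$split <- s
    node$left <- grow(left_idx, depth + 1)
    node$right <- grow(right_idx, depth + 1)
    node
  }
  structure(
    list(
      root = grow(seq_len(nrow(data)), 0L),
      predictors = predictors, control = control, n = nrow(data)
    ),
    class = "womac_tree"
  )
}

#' @export
predict.womac_tree <- function(object, newdata, ...) {
  route <- function(node, row_i) {
    while (!is.null(node$split)) {
      v <- newdata[[node$split$predictor]][row_i]
      if (is.null(v) || is.na(v)) {
        stop(sprintf(
          "row %d cannot be classified: tested predictor '%s' is missing (no surrogate splits)",
          row_i, node$split$predictor
        ), call. = FALSE)
      }
      node <- if (v <= node$split$threshold) node$left else node$right
    }
    node$class
  }
  out <- vapply(seq_len(nrow(newdata)), function(i) route(object$root, i), character(1))
  factor(out, levels = c("not_at_risk", "at_risk"))
}

#' Predictors actually used by a tree
#'
#' @param tree A \code{womac_tree}.
#' @return Sorted character vector of the distinct predictors appearing in
#'   splits.
#' @export
treeItems <- function(tree) {
  items <- character(0)
  walk <- function(node) {
    if (!is.null(node$split)) {
      items <<- c(items, node$split$predictor)
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  sort(unique(items))
}

#' Gini importance of each predictor in a tree
#'
#' Sum over a predictor's splits of the node-size-weighted Gini decrease;
#' predictors never split on score zero.
#'
#' @param tree A \code{womac_tree}.
#' @return Named numeric vector over \code{tree$predictors}.
#' @export
treeImportance <- function(tree) {
  imp <- stats::setNames(numeric(length(tree$predictors)), tree$predictors)
  walk <- function(node) {
    if (!is.null(node$split)) {
      imp[node$split$predictor] <<- imp[node$split$predictor] +
        node$n * node$split$decrease
      walk(node$left)
      walk(node$right)
    }
  }
  walk(tree$root)
  imp
}

tree_depth <- function(tree) {
  walk <- function(node) {
    if (is.null(node$split)) {
      return(node$depth)
    }
    max(walk(node$left), walk(node$right))
  }
  walk(tree$root)
}

#' @export
print.womac_tree <- function(x, ...) {
  cat(sprintf("Classification tree (%d rows, Gini criterion)\n", x$n))
  walk <- function(node, indent, label) {
    cat(sprintf(
      "%s%s n=%d (poor %d / sat %d)%s\n",
      strrep("  ", indent), label, node$n,
      node$counts["poor"], node$counts["satisfactory"],
      if (is.null(node$split)) sprintf(" -> %s", node$class) else ""
    ))
    if (!is.null(node$split)) {
      walk(node$left, indent + 1, sprintf("%s <= %d:", node$split$predictor, node$split$threshold))
      walk(node$right, indent + 1, sprintf("%s >  %d:", node$split$predictor, node$split$threshold))
    }
  }
  walk(x$root, 0, "root:")
  invisible(x)
}

node_to_list <- function(node, id) {
  out <- list(
    id = id, n = node$n,
    counts = as.list(node$counts),
    class = node$class, depth = node$depth
  )
  if (!is.null(node$split)) {
    out$split <- list(
      predictor = node$split$predictor,
      threshold = node$split$threshold,
      decrease = node$split$decrease
    )
    out$left <- node_to_list(node$left, paste0(id, "L"))
    out$right <- node_to_list(node$right, paste0(id, "R"))
  }
  out
}

list_to_node <- function(lst, depth = 0L) {
  node <- list(
    n = lst$n,
    counts = c(
      poor = as.numeric(lst$counts$poor),
      satisfactory = as.numeric(lst$counts$satisfactory)
    ),
    class = lst$class, depth = as.integer(lst$depth),
    split = NULL, left = NULL, right = NULL
  )
  if (!is.null(lst$split)) {
    node$split <- list(
      predictor = lst$split$predictor,
      threshold = as.integer(lst$split$threshold),
      decrease = as.numeric(lst$split$decrease)
    )
    node$left <- list_to_node(lst$left, depth + 1L)
    node$right <- list_to_node(lst$right, depth + 1L)
  }
  node
}

#' Serialize / deserialize a tree as JSON
#'
#' Round-tripping through \code{writeTree} and \code{readTree} is lossless:
#' node ids, splits, class counts and predicted classes are preserved.
#'
#' @param tree A \code{womac_tree}.
#' @param path Output (input) file path.
#' @return \code{writeTree}: invisibly, the path.  \code{readTree}: the
#'   reconstructed \code{womac_tree}.
#' @export
writeTree <- function(tree, path) {
  doc <- list(
    format = "womacpr_tree", version = 1L,
    n = tree$n, predictors = tree$predictors,
    control = unclass(tree$control)[c(
      "min_parent", "min_child", "max_depth", "min_decrease"
    )],
    class_weights = as.list(tree$control$class_weights),
    root = node_to_list(tree$root, "n0")
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTree
#' @export
readTree <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$format, "womacpr_tree")) {
    stop("not a womacpr tree file", call. = FALSE)
  }
  ctl <- treeControl(
    min_parent = doc$control$min_parent, min_child = doc$control$min_child,
    max_depth = doc$control$max_depth, min_decrease = doc$control$min_decrease,
    class_weights = c(
      poor = as.numeric(doc$class_weights$poor),
      satisfactory = as.numeric(doc$class_weights$satisfactory)
    )
  )
  structure(
    list(
      root = list_to_node(doc$root),
      predictors = unlist(doc$predictors), control = ctl,
      n = as.integer(doc$n)
    ),
    class = "womac_tree"
  )
}
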