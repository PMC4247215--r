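# Independent oracles, written against the definitions rather than the
# package implementation: plain-loop Gini arithmetic, brute-force split
# enumeration and a naive depth-limited recursive partitioner.  Kept free
# of any call into the package's tree code so the two routes stay
# independent.

oracle_gini <- function(n_poor, n_sat) {
  tot <- n_poor + n_sat
  1 - (n_poor / tot)^2 - (n_sat / tot)^2
}

# brute force over every (predictor, threshold) pair; first strict
# improvement wins, mirroring the documented lowest-index/lowest-threshold
# tie-break
oracle_best_split <- function(X, y01, min_child = 1, min_decrease = 0) {
  n <- length(y01)
  if (sum(y01) == 0 || sum(y01) == n) {
    return(NULL)
  }
  g_parent <- oracle_gini(sum(y01), n - sum(y01))
  best <- NULL
  best_d <- -Inf
  for (j in seq_len(ncol(X))) {
    for (t in 0:3) {
      left <- X[, j] <= t
      nl <- sum(left)
      if (nl < min_child || (n - nl) < min_child) next
      gl <- oracle_gini(sum(y01[left]), nl - sum(y01[left]))
      gr <- oracle_gini(sum(y01[!left]), (n - nl) - sum(y01[!left]))
      d <- g_parent - nl / n * gl - (n - nl) / n * gr
      if (d > best_d + 1e-12) {
        best_d <- d
        best <- list(j = j, t = t, d = d)
      }
    }
  }
  if (is.null(best) || best_d < min_decrease) {
    return(NULL)
  }
  best
}

# naive recursive partitioner enumerating all pairs at each level;
# returns the predicted class (1 = at risk) per row
oracle_tree_predict <- function(X, y01, max_depth = 2,
                                min_parent = 2, min_child = 1,
                                min_decrease = 0) {
  classify <- function(idx) as.integer(sum(y01[idx]) >= (length(idx) - sum(y01[idx])))
  out <- integer(length(y01))
  recurse <- function(idx, depth) {
    if (depth >= max_depth || length(idx) < min_parent ||
      sum(y01[idx]) == 0 || sum(y01[idx]) == length(idx)) {
      out[idx] <<- classify(idx)
      return(invisible())
    }
    s <- oracle_best_split(X[idx, , drop = FALSE], y01[idx], min_child, min_decrease)
    if (is.null(s)) {
      out[idx] <<- classify(idx)
      return(invisible())
    }
    left <- idx[X[idx, s$j] <= s$t]
    recurse(left, depth + 1)
    recurse(setdiff(idx, left), depth + 1)
  }
  recurse(seq_along(y01), 0)
  out
}

# small builders ------------------------------------------------------------

# a complete 24-item answer vector, constant by default
make_items <- function(value = 0, ...) {
  items <- stats::setNames(rep(value, 24), womacItems())
  over <- list(...)
  items[names(over)] <- unlist(over)
  items
}

make_item_df <- function(n, value = 0) {
  df <- as.data.frame(matrix(value, nrow = n, ncol = 24))
  names(df) <- womacItems()
  df
}

random_labelled_data <- function(n, n_pred = 3, seed = 1, noise = 0.1) {
  set.seed(seed)
  X <- matrix(sample(0:4, n * n_pred, replace = TRUE), n, n_pred)
  s0 <- list(j = sample(n_pred, 1), t = sample(0:3, 1))
  s1 <- list(j = sample(n_pred, 1), t = sample(0:3, 1))
  s2 <- list(j = sample(n_pred, 1), t = sample(0:3, 1))
  leaf <- sample(0:1, 4, replace = TRUE)
  y <- ifelse(X[, s0$j] <= s0$t,
    ifelse(X[, s1$j] <= s1$t, leaf[1], leaf[2]),
    ifelse(X[, s2$j] <= s2$t, leaf[3], leaf[4])
  )
  flip <- stats::runif(n) < noise
  y[flip] <- 1 - y[flip]
  df <- as.data.frame(X)
  names(df) <- paste0("X", seq_len(n_pred))
  list(
    data = df,
    outcome = factor(ifelse(y == 1, "poor", "satisfactory"),
      levels = c("satisfactory", "poor")
    ),
    y01 = y
  )
}
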