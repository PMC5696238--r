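# Independent reference implementations used as oracles. Deliberately naive
# and structured differently from the package code paths they check.

# entropy of a label vector, in bits, via frequency table
oracle_entropy <- function(labels) {
  p <- as.vector(table(labels)) / length(labels)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# exhaustive enumeration of every candidate midpoint threshold
oracle_best_split <- function(values, labels, min_leaf = 1L) {
  n <- length(values)
  sv <- sort(unique(values))
  if (length(sv) < 2L) return(NULL)
  cands <- (sv[-length(sv)] + sv[-1L]) / 2
  best <- NULL
  for (thr in cands) {
    left <- labels[values <= thr]
    right <- labels[values > thr]
    if (length(left) < min_leaf || length(right) < min_leaf) next
    gain <- oracle_entropy(labels) -
      (length(left) * oracle_entropy(left) +
       length(right) * oracle_entropy(right)) / n
    if (is.null(best) || gain > best$gain)  # ties keep the smaller threshold
      best <- list(threshold = thr, gain = gain)
  }
  if (is.null(best) || best$gain <= 1e-12) return(NULL)
  best
}

# naive recursive regrowth of a single tree with the same growth rules
# (greedy max-gain over the pool in column order, min_leaf, max_depth,
# G-test gate), written over data frames instead of index recursion
oracle_grow_tree <- function(df, y01, pool, min_leaf = 5L, max_depth = Inf,
                             alpha = 0.05, depth = 0L) {
  n <- nrow(df)
  npos <- sum(y01)
  leaf <- list(leaf = TRUE, binder_fraction = npos / n, n_train = n)
  if (npos %in% c(0L, n) || depth >= max_depth || n < 2L * min_leaf)
    return(leaf)
  best <- NULL
  for (d in pool) {
    s <- oracle_best_split(df[[d]], y01, min_leaf)
    if (!is.null(s) && (is.null(best) || s$gain > best$gain))
      best <- c(s, descriptor = d)
  }
  if (is.null(best)) return(leaf)
  if (!is.null(alpha)) {
    g <- 2 * n * log(2) * best$gain
    if (stats::pchisq(g, 1, lower.tail = FALSE) *
        length(pool) * (n - 1L) > alpha)
      return(leaf)
  }
  go_left <- df[[best$descriptor]] <= best$threshold
  list(leaf = FALSE, descriptor = best$descriptor,
       threshold = best$threshold,
       left = oracle_grow_tree(df[go_left, , drop = FALSE], y01[go_left],
                               pool, min_leaf, max_depth, alpha, depth + 1L),
       right = oracle_grow_tree(df[!go_left, , drop = FALSE], y01[!go_left],
                                pool, min_leaf, max_depth, alpha, depth + 1L))
}
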