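# The Decision Forest learner. Trees are grown deep (greedy binary splits
# maximising information gain) on the full sample; each successive tree draws
# from the descriptor pool left over by its predecessors, so the per-tree
# descriptor sets are pairwise disjoint. The consensus binder probability is
# the unweighted mean of the leaf binder fractions the trees route a compound
# to.

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    bad <- setdiff(unique(labels), c(.BINDER, .NONBINDER))
    if (length(bad)) stop("invalid label '", bad[1L], "'", call. = FALSE)
    return(as.integer(labels == .BINDER))
  }
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(as.integer(labels))
  }
  stop("cannot interpret labels of class ", class(labels)[1L], call. = FALSE)
}

# binary Shannon entropy in bits, vectorised, H(0)=H(1)=0
binary_entropy <- function(p) {
  h <- numeric(length(p))
  i <- p > 0 & p < 1
  q <- p[i]
  h[i] <- -(q * log2(q) + (1 - q) * log2(1 - q))
  h
}

#' Configuration for Decision Forest training
#'
#' @param max_trees Maximum number of trees; forest growth also stops when the
#'   descriptor pool is exhausted or when an additional tree no longer
#'   improves consensus training balanced accuracy.
#' @param min_leaf Minimum number of training compounds per leaf. Guards
#'   against singleton leaves dominating the consensus.
#' @param max_depth Maximum tree depth (root = depth 0); `Inf` grows trees to
#'   purity, the behaviour that distinguishes Decision Forests from the
#'   shallow trees of Random Forests.
#' @param improvement_epsilon Tolerance on consensus degradation: a candidate
#'   tree is discarded (and forest growth stops) when it lowers consensus
#'   training balanced accuracy by more than this amount; ties are kept, so
#'   the ensemble keeps combining every individually qualified tree.
#' @param split_alpha Family-wise significance level for accepting a node
#'   split: the best split's G-statistic (`2 n ln(2) * gain`) is tested
#'   against the chi-squared(1) no-association null with a Bonferroni
#'   correction for every candidate threshold scanned at the node, and the
#'   node becomes a leaf if the adjusted p-value exceeds `split_alpha`.
#'   This pre-pruning keeps deep trees from elaborating chance structure:
#'   a tree grown on a signal-free descriptor pool collapses to a single
#'   leaf instead of memorising the training labels. `NULL` disables the
#'   test.
#' @return A validated list of class `forest_config`.
#' @export
forest_config <- function(max_trees = 10L, min_leaf = 5L, max_depth = Inf,
                          improvement_epsilon = 0, split_alpha = 0.05) {
  stopifnot(max_trees >= 1, min_leaf >= 1,
            max_depth >= 1, improvement_epsilon >= 0,
            is.null(split_alpha) ||
              (split_alpha > 0 && split_alpha <= 1))
  structure(list(max_trees = as.integer(max_trees),
                 min_leaf = as.integer(min_leaf),
                 max_depth = as.numeric(max_depth),
                 improvement_epsilon = as.numeric(improvement_epsilon),
                 split_alpha = if (!is.null(split_alpha))
                   as.numeric(split_alpha)),
            class = "forest_config")
}

#' Best binary split of one descriptor
#'
#' Scans every admissible threshold (midpoints between adjacent distinct
#' sorted values whose two sides both hold at least `min_leaf` samples) and
#' returns the one maximising information gain (Shannon entropy reduction, in
#' bits). Returns `NULL` ("no split") when the labels are pure, no threshold
#' is admissible, or the best achievable gain is zero. Ties between
#' thresholds go to the smallest threshold.
#'
#' @param values Numeric descriptor values.
#' @param labels Aligned binary labels (`"binder"`/`"non_binder"`, logical,
#'   or 0/1).
#' @param min_leaf Minimum samples on each side of the split.
#' @return `list(threshold=, gain=)`, or `NULL` if no admissible split.
#' @export
best_split <- function(values, labels, min_leaf = 1L) {
  y <- as_binary_labels(labels)
  if (length(values) != length(y))
    stop("values and labels differ in length", call. = FALSE)
  n <- length(y)
  if (n < 2L * min_leaf) return(NULL)
  npos <- sum(y)
  if (npos == 0L || npos == n) return(NULL)
  ord <- order(values, method = "radix")
  sv <- values[ord]
  cpos <- cumsum(y[ord])
  i <- seq_len(n - 1L)
  admissible <- (sv[i] < sv[i + 1L]) & (i >= min_leaf) & ((n - i) >= min_leaf)
  if (!any(admissible)) return(NULL)
  nl <- i
  nr <- n - i
  gain <- binary_entropy(npos / n) -
    (nl * binary_entropy(cpos[i] / nl) +
     nr * binary_entropy((npos - cpos[i]) / nr)) / n
  gain[!admissible] <- -Inf
  b <- which.max(gain)  # first maximum = smallest threshold on ties
  if (gain[b] <= 1e-12) return(NULL)
  list(threshold = unname(sv[b] + sv[b + 1L]) / 2, gain = unname(gain[b]))
}

# Recursive grower shared by build_tree/train_forest. x: full matrix,
# yb: 0/1 vector, pool_idx: candidate column indices.
grow_tree <- function(x, yb, pool_idx, min_leaf, max_depth,
                      split_alpha = NULL) {
  grow <- function(idx, depth) {
    n <- length(idx)
    npos <- sum(yb[idx])
    leaf <- function() list(leaf = TRUE, binder_fraction = npos / n,
                            n_train = n)
    if (npos == 0L || npos == n || depth >= max_depth || n < 2L * min_leaf)
      return(leaf())
    yi <- yb[idx]
    best_gain <- -Inf
    best_col <- NA_integer_
    best_thr <- NA_real_
    for (j in pool_idx) {       # ties in gain: first (column-order) wins
      s <- best_split(x[idx, j], yi, min_leaf)
      if (!is.null(s) && s$gain > best_gain) {
        best_gain <- s$gain
        best_col <- j
        best_thr <- s$threshold
      }
    }
    if (is.na(best_col)) return(leaf())
    if (!is.null(split_alpha)) {
      # G-test of the best split vs chance, Bonferroni-corrected for every
      # candidate threshold scanned at this node (conservative count)
      g <- 2 * n * log(2) * best_gain
      p_adj <- stats::pchisq(g, df = 1L, lower.tail = FALSE) *
        length(pool_idx) * (n - 1L)
      if (p_adj > split_alpha) return(leaf())
    }
    v <- x[idx, best_col]
    list(leaf = FALSE,
         descriptor = colnames(x)[best_col],
         threshold = best_thr,
         left = grow(idx[v <= best_thr], depth + 1L),
         right = grow(idx[v > best_thr], depth + 1L))
  }
  grow(seq_along(yb), 0L)
}

#' Grow a single decision tree
#'
#' Greedy recursive growth: at each node the pool descriptor with maximal
#' information gain is chosen (ties broken by descriptor column order, so
#' growth is deterministic and seed-independent). Growth stops at purity,
#' `min_leaf`, `max_depth`, when no split yields positive gain, or when the
#' best split fails the `split_alpha` significance gate (see
#' [forest_config()]). Leaves store the binder fraction of their training
#' compounds. A single-class dataset yields a single leaf.
#'
#' @param dataset A [labeled_dataset()].
#' @param pool Character vector of descriptor names the tree may use;
#'   default all columns.
#' @param config A [forest_config()].
#' @return Nested-list tree; internal nodes route `value <= threshold` left.
#' @export
build_tree <- function(dataset, pool = NULL, config = forest_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (is.null(pool)) pool <- colnames(dataset$x)
  if (!length(pool)) stop("descriptor pool is empty", call. = FALSE)
  missing <- setdiff(pool, colnames(dataset$x))
  if (length(missing))
    stop("pool descriptor '", missing[1L], "' not in dataset", call. = FALSE)
  grow_tree(dataset$x, as_binary_labels(dataset$y),
            match(pool, colnames(dataset$x)),
            config$min_leaf, config$max_depth, config$split_alpha)
}

# leaf fractions for every row of x routed through one tree
predict_tree <- function(node, x) {
  out <- numeric(nrow(x))
  rec <- function(node, idx) {
    if (!length(idx)) return(invisible(NULL))
    if (node$leaf) {
      out[idx] <<- node$binder_fraction
      return(invisible(NULL))
    }
    v <- x[idx, node$descriptor]
    rec(node$left, idx[v <= node$threshold])
    rec(node$right, idx[v > node$threshold])
  }
  rec(node, seq_len(nrow(x)))
  out
}

#' Descriptors used in the split nodes of a tree
#'
#' @param tree A tree from [build_tree()].
#' @return Character vector of unique descriptor names (empty for a leaf).
#' @export
tree_descriptors <- function(tree) {
  if (tree$leaf) return(character(0L))
  unique(c(tree$descriptor,
           tree_descriptors(tree$left),
           tree_descriptors(tree$right)))
}

balanced_accuracy_01 <- function(yb, pred_binder) {
  sens <- mean(pred_binder[yb == 1L])
  spec <- mean(!pred_binder[yb == 0L])
  (sens + spec) / 2
}

#' Train a Decision Forest
#'
#' Trees are built sequentially. After each accepted tree, the descriptors it
#' used are removed from the pool, so descriptor sets are pairwise disjoint.
#' Growth stops when `max_trees` is reached, the pool is exhausted, the next
#' tree degenerates to a single leaf (which the `split_alpha` significance
#' gate forces once the pool holds no real signal), or the candidate tree
#' degrades consensus training balanced accuracy by more than
#' `improvement_epsilon` (the degrading tree is discarded), so the consensus
#' training balanced accuracy of the returned forest never falls below that
#' of its first tree. Balanced accuracy is used as the consensus measure
#' because with heavy class imbalance plain accuracy is saturated by the
#' majority class. If even the
#' first tree is degenerate — no descriptor shows significant class
#' association — the model is the single prior-rate leaf.
#'
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param config A [forest_config()].
#' @return Object of class `decision_forest`: `trees`, `descriptor_sets`
#'   (per-tree descriptors actually used), `config`, `kept_names` (the
#'   descriptor columns the model expects), `n_train`, `class_counts`, and
#'   `training_balanced_accuracy` (consensus, per accepted tree).
#' @export
train_forest <- function(dataset, config = forest_config()) {
  stopifnot(inherits(dataset, "labeled_dataset"),
            inherits(config, "forest_config"))
  x <- dataset$x
  yb <- as_binary_labels(dataset$y)
  if (sum(yb) == 0L || sum(yb) == length(yb))
    stop("training requires both classes present", call. = FALSE)
  pool <- seq_len(ncol(x))
  trees <- list()
  dsets <- list()
  ba_trace <- numeric(0L)
  tree_preds <- NULL
  ba_cur <- -Inf
  while (length(trees) < config$max_trees && length(pool)) {
    tree <- grow_tree(x, yb, pool, config$min_leaf, config$max_depth,
                      config$split_alpha)
    used <- tree_descriptors(tree)
    if (!length(used)) {
      # degenerate: no usable signal left in the pool. If it is the very
      # first tree, keep the prior-rate leaf so the model can still predict.
      if (!length(trees)) {
        trees <- list(tree)
        dsets <- list(character(0L))
        ba_trace <- balanced_accuracy_01(yb, predict_tree(tree, x) >= 0.5)
      }
      break
    }
    p_t <- predict_tree(tree, x)
    cand <- cbind(tree_preds, p_t)
    ba <- balanced_accuracy_01(yb, rowMeans(cand) >= 0.5)
    if (length(trees) > 0L && ba < ba_cur - config$improvement_epsilon)
      break  # degrading candidate discarded
    trees[[length(trees) + 1L]] <- tree
    dsets[[length(dsets) + 1L]] <- used
    ba_trace <- c(ba_trace, ba)
    tree_preds <- cand
    ba_cur <- ba
    pool <- setdiff(pool, match(used, colnames(x)))
  }
  structure(
    list(trees = trees,
         descriptor_sets = dsets,
         config = config,
         kept_names = colnames(x),
         n_train = nrow(x),
         class_counts = c(binder = sum(yb),
                          non_binder = length(yb) - sum(yb)),
         training_balanced_accuracy = ba_trace),
    class = "decision_forest")
}

#' @export
print.decision_forest <- function(x, ...) {
  cat("Decision Forest:", length(x$trees), "tree(s) on", x$n_train,
      "compounds (", x$class_counts[["binder"]], "binders /",
      x$class_counts[["non_binder"]], "non-binders )\n")
  for (i in seq_along(x$trees))
    cat(sprintf("  tree %d: %d descriptor(s), consensus training BA %.3f\n",
                i, length(x$descriptor_sets[[i]]),
                x$training_balanced_accuracy[i]))
  invisible(x)
}

#' Predict with a Decision Forest
#'
#' The consensus binder probability P is the unweighted arithmetic mean of
#' the leaf binder fractions each tree routes a compound to. The class call
#' is `"binder"` iff P >= 0.5 and the prediction confidence is
#' `|P - 0.5| / 0.5`.
#'
#' @param object A `decision_forest`.
#' @param newdata Numeric matrix or data frame containing every descriptor in
#'   `object$kept_names` (extra columns are ignored).
#' @param type `"full"` (data frame with probability, label and confidence),
#'   `"prob"` (numeric P vector) or `"class"` (label vector).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.decision_forest <- function(object, newdata,
                                    type = c("full", "prob", "class"), ...) {
  type <- match.arg(type)
  if (is.data.frame(newdata)) {
    ids <- rownames(newdata)
    newdata <- as.matrix(newdata[vapply(newdata, is.numeric, logical(1L))])
    rownames(newdata) <- ids
  }
  missing <- setdiff(object$kept_names, colnames(newdata))
  if (length(missing))
    stop("descriptor '", missing[1L], "' missing from newdata", call. = FALSE)
  x <- newdata[, object$kept_names, drop = FALSE]
  per_tree <- vapply(object$trees, predict_tree, numeric(nrow(x)), x = x)
  if (nrow(x) == 1L) per_tree <- matrix(per_tree, nrow = 1L)
  p <- rowMeans(per_tree)
  switch(type,
    prob = p,
    class = classify(p),
    full = data.frame(
      compound_id = if (is.null(rownames(x))) as.character(seq_len(nrow(x)))
                    else rownames(x),
      probability = p,
      label = classify(p),
      confidence = prediction_confidence(p),
      stringsAsFactors = FALSE, row.names = NULL))
}

#' Class call from a consensus probability
#'
#' `"binder"` iff `P >= 0.5` (the boundary is part of the binder interval).
#'
#' @param p Probability vector in \[0, 1\].
#' @return Character vector of `"binder"` / `"non_binder"`.
#' @export
classify <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  ifelse(p >= 0.5, .BINDER, .NONBINDER)
}
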