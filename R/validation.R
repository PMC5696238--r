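# Repeated k-fold cross-validation and label-permutation (y-scrambling)
# testing. All randomness is governed by explicit seeds: iteration i of a CV
# draws its folds with seed base_seed + i, and permutation replicate r
# scrambles labels with seed base_seed + r while its internal CV uses
# base_seed + replicates + r, so every random draw is independently
# reproducible.

#' Random k-fold partition
#'
#' Unstratified uniform random partition into k folds whose sizes differ by
#' at most one.
#'
#' @param n Number of samples (`n >= k`).
#' @param k Number of folds (`k >= 2`).
#' @param seed Integer seed.
#' @return Integer vector of fold indices in `1..k`, one per sample.
#' @export
kfold_split <- function(n, k, seed) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  if (n < k) stop("n (", n, ") must be at least k (", k, ")", call. = FALSE)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  set.seed(seed)
  sample(rep.int(seq_len(k), sizes))
}

stratified_kfold_split <- function(yb, k, seed) {
  n <- length(yb)
  set.seed(seed)
  folds <- integer(n)
  for (cls in unique(yb)) {
    idx <- which(yb == cls)
    m <- length(idx)
    sizes <- rep(m %/% k, k) + (seq_len(k) <= m %% k)
    folds[idx] <- sample(rep.int(seq_len(k), sizes))
  }
  folds
}

# One k-fold CV pass: trains k forests, pools the out-of-fold predictions,
# returns pooled metrics plus per-model descriptor usage.
run_cv_iteration <- function(dataset, k, fold_seed, config, stratified) {
  x <- dataset$x
  y <- as.character(dataset$y)
  yb <- as_binary_labels(dataset$y)
  n <- nrow(x)
  folds <- if (stratified) stratified_kfold_split(yb, k, fold_seed)
           else kfold_split(n, k, fold_seed)
  preds <- vector("list", k)
  usage <- vector("list", k)
  skipped <- integer(0L)
  for (f in seq_len(k)) {
    train_idx <- which(folds != f)
    test_idx <- which(folds == f)
    if (length(unique(yb[train_idx])) < 2L) {
      skipped <- c(skipped, f)  # single-class training fold: no model
      next
    }
    sub <- labeled_dataset(x[train_idx, , drop = FALSE], y[train_idx])
    model <- train_forest(sub, config)
    p <- predict(model, x[test_idx, , drop = FALSE], type = "prob")
    preds[[f]] <- data.frame(
      compound_id = rownames(x)[test_idx],
      fold = f,
      actual = y[test_idx],
      probability = p,
      label = classify(p),
      confidence = prediction_confidence(p),
      stringsAsFactors = FALSE, row.names = NULL)
    usage[[f]] <- unique(unlist(model$descriptor_sets, use.names = FALSE))
  }
  pooled <- do.call(rbind, preds[!vapply(preds, is.null, logical(1L))])
  if (is.null(pooled))
    stop("every training fold was single-class; cannot cross-validate",
         call. = FALSE)
  list(predictions = pooled,
       metrics = compute_metrics(confusion(pooled$actual, pooled$label)),
       usage = usage[setdiff(seq_len(k), skipped)],
       skipped_folds = skipped)
}

summarise_metric_rows <- function(df) {
  data.frame(
    metric = metric_names,
    mean = vapply(metric_names, function(m) mean(df[[m]], na.rm = TRUE),
                  numeric(1L)),
    sd = vapply(metric_names, function(m) stats::sd(df[[m]], na.rm = TRUE),
                numeric(1L)),
    row.names = NULL)
}

#' Repeated k-fold cross-validation of a Decision Forest
#'
#' Each iteration draws a fresh random k-fold partition (seed
#' `base_seed + iteration`), trains one forest per fold on the remaining
#' folds, and evaluates on the pooled out-of-fold predictions of that
#' iteration. Pooling (rather than averaging fold-level metrics) keeps
#' specificity defined even when a single fold happens to contain no
#' non-binders, which unstratified splits of heavily imbalanced data can
#' produce. A training fold that is entirely single-class is skipped and
#' recorded in `flagged`.
#'
#' @param dataset A [labeled_dataset()] with both classes.
#' @param k Number of folds, default 5.
#' @param iterations Number of repeated CVs.
#' @param base_seed Integer seed ladder base.
#' @param config A [forest_config()].
#' @param stratified Use class-stratified folds (non-default; the reference
#'   protocol divides compounds uniformly at random).
#' @param keep_predictions Retain the pooled out-of-fold predictions of every
#'   iteration (needed for confidence analysis).
#' @return Object of class `cv_result`: `iterations` (per-iteration metric
#'   data frame), `summary` (mean/sd per metric), `predictions` (pooled
#'   out-of-fold predictions, all iterations), `usage` (per-model descriptor
#'   usage, list of character vectors), `n_models`, `descriptor_names`,
#'   `flagged` (iterations with skipped folds), and the call parameters.
#' @export
cross_validate <- function(dataset, k = 5L, iterations = 1L, base_seed = 1L,
                           config = forest_config(), stratified = FALSE,
                           keep_predictions = TRUE) {
  stopifnot(inherits(dataset, "labeled_dataset"), iterations >= 1L)
  rows <- vector("list", iterations)
  pred_list <- vector("list", iterations)
  usage <- list()
  flagged <- integer(0L)
  for (it in seq_len(iterations)) {
    res <- run_cv_iteration(dataset, k, base_seed + it, config, stratified)
    mv <- metrics_vector(res$metrics)
    rows[[it]] <- data.frame(iteration = it, t(mv), row.names = NULL)
    if (keep_predictions) {
      res$predictions$iteration <- it
      pred_list[[it]] <- res$predictions
    }
    usage <- c(usage, res$usage)
    if (length(res$skipped_folds)) flagged <- c(flagged, it)
  }
  structure(
    list(iterations = do.call(rbind, rows),
         summary = summarise_metric_rows(do.call(rbind, rows)),
         predictions = if (keep_predictions) do.call(rbind, pred_list),
         usage = usage,
         n_models = length(usage),
         descriptor_names = colnames(dataset$x),
         flagged = flagged,
         k = k, base_seed = base_seed, config = config,
         stratified = stratified),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Cross-validation: %d iteration(s) of %d-fold CV, %d models\n",
              nrow(x$iterations), x$k, x$n_models))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s mean %.3f  sd %.3f\n", s$metric[i], s$mean[i],
                s$sd[i]))
  if (length(x$flagged))
    cat("  flagged iterations (single-class training fold):",
        paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Label-permutation (y-scrambling) test
#'
#' Estimates chance-correlation performance: each replicate randomly permutes
#' the class labels (class counts preserved) and runs one full k-fold
#' cross-validation on the scrambled dataset. For data with no usable signal
#' the replicate metrics concentrate at the random-classifier null (MCC 0,
#' balanced accuracy 0.5).
#'
#' @param dataset A [labeled_dataset()].
#' @param replicates Number of permutation replicates.
#' @param k Folds per replicate CV.
#' @param base_seed Seed ladder base; replicate r permutes with
#'   `base_seed + r` and its CV folds use `base_seed + replicates + r`.
#' @param config A [forest_config()].
#' @param stratified Passed to the internal CV.
#' @return Object of class `permutation_result`: `replicates` (per-replicate
#'   pooled metrics), `summary` (mean/sd per metric), `flagged`, and call
#'   parameters.
#' @export
permutation_test <- function(dataset, replicates = 100L, k = 5L,
                             base_seed = 1L, config = forest_config(),
                             stratified = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"), replicates >= 1L)
  y <- as.character(dataset$y)
  rows <- vector("list", replicates)
  flagged <- integer(0L)
  for (r in seq_len(replicates)) {
    set.seed(base_seed + r)
    perm <- labeled_dataset(dataset$x, y[sample.int(length(y))])
    res <- run_cv_iteration(perm, k, base_seed + replicates + r, config,
                            stratified)
    rows[[r]] <- data.frame(replicate = r, t(metrics_vector(res$metrics)),
                            row.names = NULL)
    if (length(res$skipped_folds)) flagged <- c(flagged, r)
  }
  structure(
    list(replicates = do.call(rbind, rows),
         summary = summarise_metric_rows(do.call(rbind, rows)),
         flagged = flagged,
         k = k, base_seed = base_seed, config = config),
    class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "Permutation test: %d replicate(s) of %d-fold CV on scrambled labels\n",
    nrow(x$replicates), x$k))
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-18s mean %.3f  sd %.3f\n", s$metric[i], s$mean[i],
                s$sd[i]))
  invisible(x)
}
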