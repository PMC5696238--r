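# Prediction-confidence statistic and the 10-bin confidence/performance
# analysis. Confidence rescales the consensus probability's distance from
# the decision boundary to [0, 1]: 0 at P = 0.5 (uninformative), 1 at P = 0
# or P = 1 (unanimous trees).

#' Prediction confidence from a consensus probability
#'
#' `|P - 0.5| / 0.5`, symmetric around the decision boundary:
#' `prediction_confidence(p) == prediction_confidence(1 - p)`.
#'
#' @param p Probability vector in \[0, 1\].
#' @return Confidence values in \[0, 1\].
#' @export
prediction_confidence <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  abs(p - 0.5) / 0.5
}

#' Bin predictions by confidence and evaluate each bin
#'
#' Predictions are placed into `n_bins` equal-width bins over confidence in
#' \[0, 1\], left-closed right-open, with the final bin closed at 1 so a
#' confidence of exactly 1 is binned. Per-bin performance metrics are
#' computed from the actual and predicted labels; empty bins are reported
#' with count 0 and `NA` metrics.
#'
#' @param predictions Data frame with columns `actual`, `label` (the
#'   predicted class) and `confidence` — e.g. the `predictions` element of a
#'   [cross_validate()] result, or [predict.decision_forest()] output merged
#'   with actual labels. A `cv_result` may be passed directly.
#' @param n_bins Number of equal-width bins, default 10.
#' @return Data frame of class `confidence_bins`: `bin`, `bin_low`,
#'   `bin_high`, `n`, `accuracy`, `sensitivity`, `specificity`,
#'   `balanced_accuracy`, `mcc`.
#' @export
bin_predictions <- function(predictions, n_bins = 10L) {
  if (inherits(predictions, "cv_result")) {
    predictions <- predictions$predictions
    if (is.null(predictions))
      stop("cv_result was run with keep_predictions = FALSE", call. = FALSE)
  }
  need <- c("actual", "label", "confidence")
  if (!all(need %in% names(predictions)))
    stop("predictions must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!nrow(predictions)) stop("no predictions to bin", call. = FALSE)
  stopifnot(n_bins >= 1L)
  conf <- predictions$confidence
  if (any(!is.finite(conf) | conf < 0 | conf > 1))
    stop("confidence values must lie in [0, 1]", call. = FALSE)
  bin <- pmin(floor(conf * n_bins) + 1L, n_bins)  # top bin closed at 1
  edges <- seq(0, 1, length.out = n_bins + 1L)
  rows <- lapply(seq_len(n_bins), function(b) {
    in_bin <- bin == b
    base <- data.frame(bin = b, bin_low = edges[b], bin_high = edges[b + 1L],
                       n = sum(in_bin))
    if (!any(in_bin)) {
      base[metric_names] <- NA_real_
      return(base)
    }
    m <- compute_metrics(confusion(predictions$actual[in_bin],
                                   predictions$label[in_bin]))
    base[metric_names] <- as.list(metrics_vector(m))
    base
  })
  out <- do.call(rbind, rows)
  class(out) <- c("confidence_bins", class(out))
  out
}
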