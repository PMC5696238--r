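# Confusion-matrix construction and the five performance metrics used to
# evaluate binder/non-binder classifiers: accuracy, sensitivity, specificity,
# Matthews correlation coefficient and balanced accuracy.

#' Construct a confusion matrix from counts
#'
#' The positive class is binder/active throughout: TP = actual binders
#' predicted binder, TN = actual non-binders predicted non-binder, FP =
#' actual non-binders predicted binder, FN = actual binders predicted
#' non-binder.
#'
#' @param tp,fp,fn,tn Non-negative counts.
#' @return Object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("confusion counts must be non-negative integers", call. = FALSE)
  structure(as.list(counts), class = "confusion_matrix")
}

#' Confusion matrix from actual and predicted label vectors
#'
#' @param actual,predicted Aligned label vectors; values in
#'   `positive`/anything-else form (factors and characters accepted).
#' @param positive The positive-class label; default `"binder"`. Use
#'   `"active"` when the reference labels are assay outcomes.
#' @return Object of class `confusion_matrix`.
#' @export
confusion <- function(actual, predicted, positive = "binder") {
  if (length(actual) != length(predicted))
    stop("actual and predicted differ in length", call. = FALSE)
  if (!length(actual)) stop("empty label vectors", call. = FALSE)
  a <- as.character(actual) == positive
  p <- as.character(predicted) == positive
  confusion_matrix(tp = sum(a & p), fp = sum(!a & p),
                   fn = sum(a & !p), tn = sum(!a & !p))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2L, 2L,
              dimnames = list(predicted = c("positive", "negative"),
                              actual = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Performance metrics from a confusion matrix
#'
#' Computes accuracy \eqn{(TP+TN)/n}, sensitivity \eqn{TP/(TP+FN)},
#' specificity \eqn{TN/(TN+FP)}, Matthews correlation coefficient
#' \eqn{(TP \cdot TN - FP \cdot FN)/\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}
#' and balanced accuracy \eqn{(sensitivity+specificity)/2}.
#'
#' A metric whose denominator is zero is reported as `NA` (undefined). MCC
#' with any zero denominator factor is reported as 0 by convention, with the
#' `mcc_undefined` flag set — the value a permutation null converges to.
#'
#' @param cm A `confusion_matrix`.
#' @return Object of class `metrics_report`: `accuracy`, `sensitivity`,
#'   `specificity`, `balanced_accuracy`, `mcc` (fractions / correlation on
#'   the raw scale), plus logical `mcc_undefined`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  n <- tp + fp + fn + tn
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  denom <- as.numeric(tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc_undef <- denom == 0
  mcc <- if (mcc_undef) 0 else
    (as.numeric(tp) * tn - as.numeric(fp) * fn) / sqrt(denom)
  structure(
    list(accuracy = (tp + tn) / n,
         sensitivity = sens,
         specificity = spec,
         balanced_accuracy = if (is.na(sens) || is.na(spec)) NA_real_
                             else (sens + spec) / 2,
         mcc = mcc,
         mcc_undefined = mcc_undef,
         n = n),
    class = "metrics_report")
}

#' Round half away from zero
#'
#' Plain `round()` rounds half to even; reported percentages here follow the
#' round-half-up presentation convention (92.55 -> 92.6).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

metric_names <- c("accuracy", "sensitivity", "specificity",
                  "balanced_accuracy", "mcc")

#' @export
print.metrics_report <- function(x, ...) {
  fmt <- function(v, pct = TRUE) {
    if (is.na(v)) return("undefined")
    if (pct) sprintf("%.1f%%", round_half_up(100 * v, 1L))
    else sprintf("%.3f", v)
  }
  cat(sprintf("n = %d\n", x$n))
  cat("  accuracy:          ", fmt(x$accuracy), "\n")
  cat("  sensitivity:       ", fmt(x$sensitivity), "\n")
  cat("  specificity:       ", fmt(x$specificity), "\n")
  cat("  balanced accuracy: ", fmt(x$balanced_accuracy), "\n")
  cat("  MCC:               ", fmt(x$mcc, pct = FALSE),
      if (x$mcc_undefined) " (undefined denominator, 0 by convention)" else "",
      "\n", sep = "")
  invisible(x)
}

# metrics_report -> named numeric vector (internal helper for summaries)
metrics_vector <- function(report) {
  vapply(metric_names, function(m) {
    v <- report[[m]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  }, numeric(1L))
}
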