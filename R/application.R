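# Applying a trained forest to an external descriptor table with assay
# outcomes, and label-set concordance between two experimental sources.

#' Apply a trained model to an external assay dataset
#'
#' Predicts every assay compound with a determined outcome, evaluates the
#' predictions against the outcomes (actives are the positive class, matched
#' to predicted binders), and additionally stratifies the evaluation into
#' high-confidence (`confidence >= confidence_cut`) and low-confidence
#' predictions. Compounds with outcome `"not_determined"` are excluded from
#' the evaluation and counted in `n_not_determined`.
#'
#' @param model A `decision_forest`.
#' @param table Descriptor matrix covering `model$kept_names`; rownames must
#'   include every assay compound.
#' @param assay Data frame with columns `compound_id` and `outcome`
#'   (`"active"` / `"inactive"` / `"not_determined"`).
#' @param confidence_cut Confidence threshold separating the high and low
#'   strata, default 0.5.
#' @return Object of class `application_result`: `predictions` (with assay
#'   outcomes attached), `confusion`, `metrics`, `confusion_high`/`_low`,
#'   `metrics_high`/`_low` (`NULL` for an empty stratum), `confidence_cut`,
#'   `n_not_determined`.
#' @export
apply_model <- function(model, table, assay, confidence_cut = 0.5) {
  stopifnot(inherits(model, "decision_forest"))
  validate_descriptor_table(table)
  if (!all(c("compound_id", "outcome") %in% names(assay)))
    stop("assay must have columns 'compound_id' and 'outcome'", call. = FALSE)
  ids <- as.character(assay$compound_id)
  unknown <- setdiff(ids, rownames(table))
  if (length(unknown))
    stop("assay compound '", unknown[1L], "' has no descriptor row",
         call. = FALSE)
  determined <- assay$outcome %in% c("active", "inactive")
  n_nd <- sum(!determined)
  if (!any(determined))
    stop("no assay compounds with a determined outcome", call. = FALSE)
  ids <- ids[determined]
  outcome <- as.character(assay$outcome)[determined]
  preds <- predict(model, table[ids, , drop = FALSE], type = "full")
  preds$outcome <- outcome
  actual <- ifelse(outcome == "active", .BINDER, .NONBINDER)
  cm <- confusion(actual, preds$label)
  hi <- preds$confidence >= confidence_cut
  stratum <- function(sel) {
    if (!any(sel)) return(list(confusion = NULL, metrics = NULL))
    c_ <- confusion(actual[sel], preds$label[sel])
    list(confusion = c_, metrics = compute_metrics(c_))
  }
  s_hi <- stratum(hi)
  s_lo <- stratum(!hi)
  if (n_nd > 0L)
    message("apply_model: ", n_nd,
            " compound(s) with outcome not_determined excluded")
  structure(
    list(predictions = preds,
         confusion = cm,
         metrics = compute_metrics(cm),
         confusion_high = s_hi$confusion, metrics_high = s_hi$metrics,
         confusion_low = s_lo$confusion, metrics_low = s_lo$metrics,
         confidence_cut = confidence_cut,
         n_not_determined = n_nd),
    class = "application_result")
}

#' @export
print.application_result <- function(x, ...) {
  cat("Model application:", nrow(x$predictions), "compounds evaluated (",
      x$n_not_determined, "not determined, excluded )\n")
  cat("Overall:\n"); print(x$metrics)
  if (!is.null(x$metrics_high)) {
    cat("High confidence (>=", x$confidence_cut, "):\n")
    print(x$metrics_high)
  }
  if (!is.null(x$metrics_low)) {
    cat("Low confidence (<", x$confidence_cut, "):\n")
    print(x$metrics_low)
  }
  invisible(x)
}

#' Concordance between two label sets over the same compounds
#'
#' Treats `set_a` (e.g. binding-assay calls) as a prediction of `set_b`
#' (e.g. high-throughput dimerization outcomes) and returns the resulting
#' 2x2 table and metrics; the agreement fraction is the accuracy. When one
#' source contains a single class the table has an empty row and
#' specificity/balanced accuracy come back `NA` (undefined).
#'
#' @param set_a,set_b Aligned label vectors over the same compounds. If both
#'   are named, they are matched by name and differing compound sets are an
#'   error.
#' @param positive_a,positive_b The positive-class label in each vector
#'   (defaults `"binder"` and `"active"`).
#' @return List with `confusion` (a `confusion_matrix`) and `metrics`.
#' @export
compare_label_sets <- function(set_a, set_b, positive_a = "binder",
                               positive_b = "active") {
  a_names <- names(set_a)
  b_names <- names(set_b)
  if (!is.null(a_names) && !is.null(b_names)) {
    if (!setequal(a_names, b_names))
      stop("label sets cover different compounds (e.g. '",
           setdiff(union(a_names, b_names),
                   intersect(a_names, b_names))[1L], "')", call. = FALSE)
    set_b <- set_b[a_names]
  } else if (length(set_a) != length(set_b)) {
    stop("label sets differ in length", call. = FALSE)
  }
  a <- ifelse(as.character(set_a) == positive_a, .BINDER, .NONBINDER)
  b <- ifelse(as.character(set_b) == positive_b, .BINDER, .NONBINDER)
  cm <- confusion(actual = b, predicted = a)
  list(confusion = cm, metrics = compute_metrics(cm))
}
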