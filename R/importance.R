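# Descriptor importance by frequency of use across cross-validation models.
# A descriptor counts as "used" in a model iff it appears in a split node of
# at least one of that model's trees — pool membership alone reflects
# ordering, not contribution.

#' Descriptor usage frequencies across CV models
#'
#' For every descriptor in the cross-validated dataset, counts the fraction
#' of trained models whose trees split on it at least once. Ranked by
#' fraction descending, ties broken alphabetically by descriptor name.
#'
#' @param cv_result A [cross_validate()] result (its `usage` element holds
#'   one descriptor set per trained model).
#' @return Data frame: `descriptor`, `n_models_used`, `fraction`, ordered by
#'   decreasing fraction.
#' @export
descriptor_frequencies <- function(cv_result) {
  stopifnot(inherits(cv_result, "cv_result"))
  usage <- cv_result$usage
  if (!length(usage))
    stop("cv_result contains no per-model descriptor usage", call. = FALSE)
  total <- length(usage)
  counts <- table(factor(unlist(usage, use.names = FALSE),
                         levels = cv_result$descriptor_names))
  out <- data.frame(descriptor = names(counts),
                    n_models_used = as.integer(counts),
                    fraction = as.integer(counts) / total,
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$fraction, out$descriptor), , drop = FALSE]
}

#' Select informative descriptors by frequency threshold
#'
#' Returns the descriptors used in strictly more than `threshold_fraction`
#' of the models ("more than 90%" by default).
#'
#' @param frequencies Output of [descriptor_frequencies()].
#' @param threshold_fraction Strict lower bound on the usage fraction.
#' @return Character vector of descriptor names.
#' @export
select_informative <- function(frequencies, threshold_fraction = 0.9) {
  if (!all(c("descriptor", "fraction") %in% names(frequencies)) ||
      !nrow(frequencies))
    stop("frequencies must be a non-empty descriptor_frequencies result",
         call. = FALSE)
  frequencies$descriptor[frequencies$fraction > threshold_fraction]
}
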