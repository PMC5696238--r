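# Binder/non-binder labelling from logRBA (log10 relative binding affinity)
# and assembly of the labelled training dataset.

#' Label a compound from its logRBA measurements
#'
#' A single measurement labels the compound `"binder"` when
#' `logRBA >= threshold` (the boundary is inclusive) and `"non_binder"`
#' otherwise. With several measurements each is labelled individually and a
#' strict majority decides; an exact tie yields `"excluded"`, because an
#' ambiguous consensus would corrupt training.
#'
#' @param logrba_values Numeric vector of logRBA measurements (non-empty,
#'   finite).
#' @param threshold Binder threshold on the logRBA scale; default -5.
#' @return One of `"binder"`, `"non_binder"`, `"excluded"`.
#' @examples
#' label_compound(-5)              # "binder" (boundary inclusive)
#' label_compound(c(-4, -6, -4.5)) # "binder" (2-of-3 majority)
#' label_compound(c(-4, -6))       # "excluded" (tie)
#' @export
label_compound <- function(logrba_values, threshold = -5) {
  if (length(logrba_values) == 0L)
    stop("logrba_values must be non-empty", call. = FALSE)
  if (!is.numeric(logrba_values) || any(!is.finite(logrba_values)))
    stop("logrba_values must be finite numbers", call. = FALSE)
  n_bind <- sum(logrba_values >= threshold)
  n_non <- length(logrba_values) - n_bind
  if (n_bind > n_non) .BINDER
  else if (n_non > n_bind) .NONBINDER
  else .EXCLUDED
}

#' Construct a labelled dataset
#'
#' Bundles a descriptor matrix with aligned binary class labels. This is the
#' container every training and validation function consumes.
#'
#' @param x Numeric descriptor matrix (rownames = compound IDs).
#' @param labels Character vector or factor of `"binder"` / `"non_binder"`,
#'   one per row of `x`.
#' @return Object of class `labeled_dataset` with elements `x` (matrix) and
#'   `y` (factor with levels `non_binder`, `binder`).
#' @export
labeled_dataset <- function(x, labels) {
  validate_descriptor_table(x)
  labels <- as.character(labels)
  if (length(labels) != nrow(x))
    stop("label count (", length(labels), ") does not match row count (",
         nrow(x), ")", call. = FALSE)
  bad <- setdiff(unique(labels), c(.BINDER, .NONBINDER))
  if (length(bad))
    stop("invalid label '", bad[1L], "'", call. = FALSE)
  structure(
    list(x = x, y = factor(labels, levels = c(.NONBINDER, .BINDER))),
    class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labelled descriptor dataset:", nrow(x$x), "compounds x",
      ncol(x$x), "descriptors\n")
  cat("  binders:", sum(x$y == .BINDER),
      " non-binders:", sum(x$y == .NONBINDER), "\n")
  invisible(x)
}

#' Assemble a labelled training dataset from activity records
#'
#' Labels every compound with activity data via [label_compound()], drops
#' compounds whose replicate measurements tie (consensus `"excluded"`), and
#' returns the descriptor rows of the remaining compounds joined to their
#' labels. Compound ID matching is case-sensitive exact string equality.
#'
#' @param table Numeric descriptor matrix (rownames = compound IDs).
#' @param activity `data.frame` with columns `compound_id` and `logrba`
#'   (long format: one row per measurement).
#' @param threshold Binder threshold passed to [label_compound()].
#' @param quiet Suppress the class-count summary message.
#' @return A [labeled_dataset()] containing the labelled compounds, with
#'   attribute `"excluded"` listing the compound IDs dropped for tied
#'   consensus.
#' @export
assemble_dataset <- function(table, activity, threshold = -5, quiet = FALSE) {
  validate_descriptor_table(table)
  if (!all(c("compound_id", "logrba") %in% names(activity)))
    stop("activity must have columns 'compound_id' and 'logrba'",
         call. = FALSE)
  ids <- unique(as.character(activity$compound_id))
  missing <- setdiff(ids, rownames(table))
  if (length(missing))
    stop("compound '", missing[1L], "' has activity data but no descriptor row",
         call. = FALSE)
  values <- split(as.numeric(activity$logrba),
                  factor(as.character(activity$compound_id), levels = ids))
  lab <- vapply(values, label_compound, character(1L), threshold = threshold)
  keep <- names(lab)[lab != .EXCLUDED]
  excluded <- names(lab)[lab == .EXCLUDED]
  if (!length(keep))
    stop("all compounds excluded by consensus ties; empty dataset",
         call. = FALSE)
  if (!quiet)
    message("assemble_dataset: ", sum(lab[keep] == .BINDER), " binders, ",
            sum(lab[keep] == .NONBINDER), " non-binders, ",
            length(excluded), " excluded (tied consensus)")
  ds <- labeled_dataset(table[keep, , drop = FALSE], unname(lab[keep]))
  attr(ds, "excluded") <- excluded
  ds
}
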