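# Low-information descriptor filtering. Mirrors the pre-modelling reduction
# step in which descriptors taking the same value for most training compounds
# are dropped before tree induction.

#' Remove low-information descriptors
#'
#' A descriptor is removed when its single most frequent value occurs in more
#' than `dominance_threshold` of the compounds; constant descriptors are
#' always removed. "Same value" means exact floating-point equality —
#' descriptor generators emit discretised values, so no epsilon-bucketing is
#' applied. Filtering statistics must be computed on the training table only;
#' apply the resulting `kept_names` to application tables with
#' [apply_filter()] to avoid leakage.
#'
#' @param table Numeric descriptor matrix.
#' @param dominance_threshold Fraction in (0.5, 1]; default 0.95.
#' @return List with `table` (the filtered matrix, surviving column order
#'   preserved) and `report`, a `filter_report` with `kept_names`,
#'   `removed_names` and `dominance_threshold`.
#' @export
filter_low_information <- function(table, dominance_threshold = 0.95) {
  validate_descriptor_table(table)
  if (nrow(table) == 0L) stop("empty descriptor table", call. = FALSE)
  if (!(dominance_threshold > 0.5 && dominance_threshold <= 1))
    stop("dominance_threshold must be in (0.5, 1]", call. = FALSE)
  n <- nrow(table)
  top_freq <- vapply(seq_len(ncol(table)), function(j) {
    max(tabulate(match(table[, j], unique(table[, j]))))
  }, integer(1L))
  drop <- (top_freq / n > dominance_threshold) | (top_freq == n)
  kept <- colnames(table)[!drop]
  removed <- colnames(table)[drop]
  if (!length(kept))
    stop("all descriptors removed as low-information; nothing to train on",
         call. = FALSE)
  report <- structure(
    list(kept_names = kept, removed_names = removed,
         dominance_threshold = dominance_threshold),
    class = "filter_report")
  list(table = table[, kept, drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Descriptor filter (dominance threshold", x$dominance_threshold, "):",
      length(x$removed_names), "removed,", length(x$kept_names), "kept\n")
  invisible(x)
}

#' Apply a training-set descriptor filter to another table
#'
#' Subsets `table` to the `kept_names` of a [filter_low_information()] report,
#' in the same column order, so application sets match the training feature
#' space exactly.
#'
#' @param table Numeric descriptor matrix.
#' @param report A `filter_report`, or a character vector of kept names.
#' @return Filtered matrix.
#' @export
apply_filter <- function(table, report) {
  validate_descriptor_table(table)
  kept <- if (inherits(report, "filter_report")) report$kept_names
          else as.character(report)
  missing <- setdiff(kept, colnames(table))
  if (length(missing))
    stop("descriptor '", missing[1L], "' missing from table", call. = FALSE)
  table[, kept, drop = FALSE]
}

#' Serialise / deserialise a filter report as JSON
#'
#' @param report A `filter_report`.
#' @param path JSON file path.
#' @return `write_filter_report` returns `path` invisibly;
#'   `read_filter_report` returns the `filter_report`.
#' @export
write_filter_report <- function(report, path) {
  stopifnot(inherits(report, "filter_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_report
#' @export
read_filter_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("kept_names", "removed_names", "dominance_threshold")
  if (!all(need %in% names(obj)))
    stop("not a filter report: missing ",
         paste(setdiff(need, names(obj)), collapse = ", "), call. = FALSE)
  structure(obj[need], class = "filter_report")
}
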