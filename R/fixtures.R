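# Packaged reference summaries of the two ToxCast ERbeta dimerization
# reporter assays (OT_ER_ERbERb_0480 and OT_ER_ERbERb_1440): the 2x2
# concordance tables of the 21 compounds shared between the binding-affinity
# training source and ToxCast, and the 2x2 application tables of the trained
# model's predictions on the full assay sets. Only the published counts are
# stored; per-compound identities are not.

#' Path to a packaged example file
#'
#' @param file File name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return Full path, or a character vector of file names.
#' @export
erbforest_example <- function(file = NULL) {
  if (is.null(file))
    return(dir(system.file("extdata", package = "erbforest")))
  path <- system.file("extdata", file, package = "erbforest")
  if (path == "") stop("no packaged file '", file, "'", call. = FALSE)
  path
}

#' Load the packaged ERbeta dimerization assay summaries
#'
#' Reads the 2x2 count tables for the two dimerization assays and expands
#' them into ready-to-use objects: for each assay, `concordance` holds the
#' aligned label vectors of the shared compounds (binding calls vs assay
#' outcomes, for [compare_label_sets()]) and `application` holds the
#' prediction-vs-outcome counts as a [confusion_matrix()] (predicted binders
#' on actives are the true positives).
#'
#' @param path CSV of counts; defaults to the packaged table.
#' @return Named list (one element per assay), each with elements
#'   `concordance` (list `binding`, `assay`: label vectors) and
#'   `application` (a `confusion_matrix`).
#' @export
load_assay_summaries <- function(path = erbforest_example(
                                   "toxcast_dimerization_counts.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("table", "assay", "group", "active", "inactive")
  if (!all(need %in% names(df)))
    stop("assay summary CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- list()
  for (assay in unique(df$assay)) {
    sub <- df[df$assay == assay, ]
    conc <- sub[sub$table == "concordance", ]
    appl <- sub[sub$table == "application", ]
    expand <- function(rows) {
      # one compound per count, labels in table order
      binding <- rep(ifelse(rows$group == "binder", "binder", "non_binder"),
                     rows$active + rows$inactive)
      assay_lab <- unlist(Map(function(a, i) rep(c("active", "inactive"),
                                                 c(a, i)),
                              rows$active, rows$inactive))
      n <- length(binding)
      names(binding) <- names(assay_lab) <- sprintf("common_%02d", seq_len(n))
      list(binding = binding, assay = assay_lab)
    }
    out[[assay]] <- list(
      concordance = if (nrow(conc)) expand(conc),
      application = if (nrow(appl)) {
        b <- appl[appl$group == "predicted_binder", ]
        nb <- appl[appl$group == "predicted_non_binder", ]
        confusion_matrix(tp = b$active, fp = b$inactive,
                         fn = nb$active, tn = nb$inactive)
      })
  }
  out
}
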