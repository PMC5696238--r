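# Descriptor tables are plain numeric matrices: rownames are compound IDs,
# colnames are descriptor names. Readers enforce the invariants (unique IDs,
# unique descriptor names, every cell finite); downstream code can then trust
# the matrix without re-checking.

validate_descriptor_table <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("descriptor table must be a numeric matrix", call. = FALSE)
  ids <- rownames(x)
  nms <- colnames(x)
  if (is.null(ids) || is.null(nms))
    stop("descriptor table must have compound IDs as rownames and descriptor names as colnames",
         call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate compound ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  if (anyDuplicated(nms))
    stop("duplicate descriptor name: ", nms[duplicated(nms)][1L], call. = FALSE)
  if (!all(is.finite(x))) {
    bad <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite descriptor value at compound '", ids[bad[1L]],
         "', descriptor '", nms[bad[2L]], "'", call. = FALSE)
  }
  invisible(x)
}

#' Read a molecular-descriptor table
#'
#' Reads a delimited text file with one row per compound and one column per
#' numeric molecular descriptor (e.g. a Mold2 export) into a numeric matrix
#' with compound IDs as rownames. Missing or non-numeric cells and duplicated
#' compound IDs are hard errors: descriptor generators emit complete tables,
#' and silent imputation would change the feature space.
#'
#' @param path Path to a delimited text file with a header row.
#' @param id_column Name of the column holding compound IDs.
#' @param delimiter Field delimiter, default comma.
#' @return Numeric matrix; rownames are compound IDs, colnames descriptor
#'   names, in file order.
#' @seealso [write_descriptor_table()] for the inverse.
#' @export
read_descriptor_table <- function(path, id_column = "compound_id",
                                  delimiter = ",") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = delimiter,
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fileEncoding = "UTF-8")
  if (!id_column %in% names(df))
    stop("id column '", id_column, "' not found in header", call. = FALSE)
  ids <- df[[id_column]]
  if (anyDuplicated(ids))
    stop("duplicate compound ID: ", ids[duplicated(ids)][1L], call. = FALSE)
  desc <- df[setdiff(names(df), id_column)]
  if (ncol(desc) == 0L) stop("no descriptor columns in file", call. = FALSE)
  vals <- matrix(NA_real_, nrow = nrow(desc), ncol = ncol(desc),
                 dimnames = list(ids, names(desc)))
  for (j in seq_along(desc)) {
    v <- suppressWarnings(as.numeric(desc[[j]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop("non-numeric or missing value in column '", names(desc)[j],
           "', row ", bad[1L], " (compound '", ids[bad[1L]], "')",
           call. = FALSE)
    vals[, j] <- v
  }
  validate_descriptor_table(vals)
  vals
}

#' Write a descriptor table to delimited text
#'
#' Values are written with 17 significant digits so that
#' `read_descriptor_table(write_descriptor_table(x))` reproduces `x` exactly.
#'
#' @param table Numeric descriptor matrix (rownames = compound IDs).
#' @param path Output file path.
#' @param id_column Header name for the ID column.
#' @param delimiter Field delimiter.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(table, path, id_column = "compound_id",
                                   delimiter = ",") {
  validate_descriptor_table(table)
  txt <- apply(table, 2L, function(col) sprintf("%.17g", col))
  if (is.null(dim(txt))) txt <- matrix(txt, nrow = nrow(table))
  out <- cbind(rownames(table), txt)
  colnames(out) <- c(id_column, colnames(table))
  utils::write.table(out, path, sep = delimiter, quote = FALSE,
                     row.names = FALSE, col.names = TRUE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read activity measurements (logRBA) in long format
#'
#' Expects columns `compound_id` and `logrba`; a compound with several
#' measurements appears on several rows.
#'
#' @param path CSV file path.
#' @return `data.frame` with character `compound_id` and numeric `logrba`.
#' @export
read_activity_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("compound_id", "logrba") %in% names(df)))
    stop("activity table needs columns 'compound_id' and 'logrba'",
         call. = FALSE)
  df$compound_id <- as.character(df$compound_id)
  df$logrba <- as.numeric(df$logrba)
  if (any(!is.finite(df$logrba)))
    stop("non-finite logRBA value at row ",
         which(!is.finite(df$logrba))[1L], call. = FALSE)
  df[c("compound_id", "logrba")]
}

#' Read assay outcomes
#'
#' Expects columns `compound_id` and `outcome`, the latter one of
#' `"active"`, `"inactive"` or `"not_determined"`.
#'
#' @param path CSV file path.
#' @return `data.frame` with columns `compound_id`, `outcome`.
#' @export
read_assay_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (!all(c("compound_id", "outcome") %in% names(df)))
    stop("assay table needs columns 'compound_id' and 'outcome'",
         call. = FALSE)
  ok <- c("active", "inactive", "not_determined")
  bad <- setdiff(unique(df$outcome), ok)
  if (length(bad))
    stop("unknown assay outcome '", bad[1L], "' (expected ",
         paste(ok, collapse = ", "), ")", call. = FALSE)
  df$compound_id <- as.character(df$compound_id)
  df[c("compound_id", "outcome")]
}
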