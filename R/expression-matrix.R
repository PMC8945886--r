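#' Validate a gene-by-sample expression matrix
#'
#' An expression matrix in this package is a plain numeric matrix with unique
#' gene identifiers as rownames and unique sample identifiers as colnames.
#' Values are assumed to be already normalized, log-scale expression; no
#' transformation is applied anywhere downstream. This helper enforces the
#' container invariants shared by all scoring functions.
#'
#' @param values Numeric matrix, genes in rows, samples in columns, with
#'   rownames and colnames set.
#' @param allow_duplicate_genes Logical; in-memory matrices may carry several
#'   probe rows per gene id (scoring functions average them by a documented
#'   rule), whereas matrices read from disk must have unique gene ids.
#' @return The validated matrix, invisibly unchanged.
#' @export
validate_expression_matrix <- function(values, allow_duplicate_genes = FALSE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("expression matrix must have gene rownames and sample colnames",
         call. = FALSE)
  }
  if (nrow(values) < 2L || ncol(values) < 1L) {
    stop("expression matrix needs at least 2 genes and 1 sample", call. = FALSE)
  }
  if (!allow_duplicate_genes && anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate gene id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    stop("duplicate sample id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!all(is.finite(values))) {
    stop("expression matrix contains missing or non-finite values", call. = FALSE)
  }
  invisible(values)
}

#' Read an expression matrix from delimited text
#'
#' Expects genes in rows and a header row of sample ids; the first column
#' holds gene ids. The delimiter is taken from the file extension
#' (`.csv` is comma, anything else tab) unless given explicitly. Gene ids are
#' matched case-sensitively throughout the package, so any identifier
#' harmonisation belongs upstream of this reader.
#'
#' Missing or non-numeric cells are rejected with the offending row and
#' column named; the scoring procedure defines no imputation.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Optional single-character field separator overriding the
#'   extension-based default.
#' @return A numeric matrix (genes x samples) passing
#'   [validate_expression_matrix()], row and column order as in the file.
#' @export
read_expression_matrix <- function(path, delimiter = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delimiter <- delimiter %||% delim_from_path(path)
  raw <- tryCatch(
    utils::read.table(path, sep = delimiter, header = TRUE,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      comment.char = "", quote = "\""),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e),
                             call. = FALSE)
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) {
    stop("expression file ", path, " has no data cells", call. = FALSE)
  }
  gene_ids <- as.character(raw[[1L]])
  if (anyDuplicated(gene_ids)) {
    dup <- unique(gene_ids[duplicated(gene_ids)])
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  values <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
                   dimnames = list(gene_ids, colnames(raw)[-1L]))
  for (j in seq_len(ncol(values))) {
    col <- raw[[j + 1L]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num))
    if (length(bad) > 0L) {
      stop(sprintf("non-numeric or missing value at gene '%s' (row %d), sample '%s'",
                   gene_ids[bad[1L]], bad[1L], colnames(values)[j]),
           call. = FALSE)
    }
    values[, j] <- num
  }
  validate_expression_matrix(values)
  values
}

#' Write an expression matrix to delimited text
#'
#' Values are formatted with 17 significant digits, which round-trips IEEE
#' doubles exactly: `read_expression_matrix(write_expression_matrix(x))`
#' reproduces `x` bit for bit.
#'
#' @param values Expression matrix as in [validate_expression_matrix()].
#' @param path Output path; extension picks the delimiter unless overridden.
#' @param delimiter Optional field separator.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(values, path, delimiter = NULL) {
  validate_expression_matrix(values, allow_duplicate_genes = TRUE)
  delimiter <- delimiter %||% delim_from_path(path)
  txt <- matrix(sprintf("%.17g", values), nrow = nrow(values))
  lines <- c(
    paste(c("gene_id", colnames(values)), collapse = delimiter),
    vapply(seq_len(nrow(values)), function(i) {
      paste(c(rownames(values)[i], txt[i, ]), collapse = delimiter)
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}
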