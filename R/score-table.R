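#' Construct a per-sample signature score table
#'
#' Holds one raw score per sample and signature, and optionally the
#' median/IQR-standardized scores of the same shape. Rownames are sample ids,
#' colnames signature names.
#'
#' @param raw Numeric matrix, samples x signatures, with dimnames.
#' @param standardized Optional numeric matrix of identical shape and
#'   dimnames; each column must have median 0 and IQR 1 (type-7 quantiles)
#'   to within 1e-9.
#' @return An object of class `score_table`.
#' @export
score_table <- function(raw, standardized = NULL) {
  if (!is.matrix(raw) || !is.numeric(raw)) {
    stop("raw scores must be a numeric matrix (samples x signatures)",
         call. = FALSE)
  }
  if ((nrow(raw) > 0L && is.null(rownames(raw))) || is.null(colnames(raw))) {
    stop("score matrix needs sample rownames and signature colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(raw)) || anyDuplicated(colnames(raw))) {
    stop("sample ids and signature names must be unique", call. = FALSE)
  }
  if (!all(is.finite(raw))) stop("raw scores must be finite", call. = FALSE)
  if (!is.null(standardized)) {
    stopifnot(is.matrix(standardized),
              identical(dim(standardized), dim(raw)),
              identical(dimnames(standardized), dimnames(raw)))
    for (j in seq_len(ncol(standardized))) {
      col <- standardized[, j]
      if (abs(stats::median(col)) > 1e-9 ||
          abs(stats::IQR(col, type = 7) - 1) > 1e-9) {
        stop("standardized column '", colnames(raw)[j],
             "' does not have median 0 and IQR 1", call. = FALSE)
      }
    }
  }
  structure(list(raw = raw, standardized = standardized),
            class = "score_table")
}

#' @export
print.score_table <- function(x, ...) {
  cat(sprintf("<score_table> %d samples x %d signatures (%s)\n",
              nrow(x$raw), ncol(x$raw),
              if (is.null(x$standardized)) "raw only" else "raw + standardized"))
  utils::str(dimnames(x$raw), give.attr = FALSE)
  invisible(x)
}

#' @export
as.data.frame.score_table <- function(x, ...) {
  out <- data.frame(sample_id = rownames(x$raw), stringsAsFactors = FALSE)
  for (sig in colnames(x$raw)) {
    out[[paste0(sig, "_raw")]] <- x$raw[, sig]
  }
  if (!is.null(x$standardized)) {
    for (sig in colnames(x$raw)) {
      out[[paste0(sig, "_std")]] <- x$standardized[, sig]
    }
  }
  rownames(out) <- NULL
  out
}

#' Write a score table as TSV
#'
#' Columns are `sample_id` then one `<signature>_raw` column per signature
#' and, when standardized scores are present, matching `<signature>_std`
#' columns. Values use 17 significant digits so [read_score_table()] restores
#' them exactly.
#'
#' @param table A [score_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(table, path) {
  stopifnot(inherits(table, "score_table"))
  df <- as.data.frame(table)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a score table written by [write_score_table()]
#'
#' @param path Path to the TSV.
#' @return A [score_table()].
#' @export
read_score_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  raw_cols <- grep("_raw$", colnames(df), value = TRUE)
  std_cols <- grep("_std$", colnames(df), value = TRUE)
  if (length(raw_cols) == 0L) {
    stop("no *_raw score columns found in ", path, call. = FALSE)
  }
  raw <- as.matrix(df[, raw_cols, drop = FALSE])
  dimnames(raw) <- list(df$sample_id, sub("_raw$", "", raw_cols))
  std <- NULL
  if (length(std_cols) > 0L) {
    std <- as.matrix(df[, std_cols, drop = FALSE])
    dimnames(std) <- list(df$sample_id, sub("_std$", "", std_cols))
    std <- std[, colnames(raw), drop = FALSE]
  }
  score_table(raw, std)
}
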