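#' Chi-square test on a contingency table
#'
#' Two variants. `"pearson"` is the classical test of independence on an
#' r x c count table: statistic `sum((O - E)^2 / E)` with expected counts
#' from the marginals, `(r-1)(c-1)` degrees of freedom, no continuity
#' correction. `"trend"` is the Cochran-Armitage trend test for a 2 x k
#' table whose columns are ordered, with user-supplied (default equally
#' spaced) column scores and 1 degree of freedom. Cells with expected count
#' below 5 trigger a warning, never a silent method switch.
#'
#' @param counts Non-negative count matrix (at least 2 x 2 for pearson;
#'   exactly 2 rows for trend).
#' @param variant `"pearson"` or `"trend"`.
#' @param trend_scores Numeric column scores for the trend variant; defaults
#'   to `1..k`.
#' @return A list of class `chi_square_result` with `statistic`, `df`,
#'   `p_value` and `variant`.
#' @export
chi_square_test <- function(counts, variant = c("pearson", "trend"),
                            trend_scores = NULL) {
  variant <- match.arg(variant)
  counts <- as.matrix(counts)
  if (!is.numeric(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be a matrix of non-negative integers", call. = FALSE)
  }
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("contingency table has a zero marginal row or column", call. = FALSE)
  }
  if (variant == "pearson") {
    if (nrow(counts) < 2L || ncol(counts) < 2L) {
      stop("pearson variant needs at least a 2 x 2 table", call. = FALSE)
    }
    expected <- outer(rowSums(counts), colSums(counts)) / sum(counts)
    if (any(expected < 5)) {
      warning("some expected counts are below 5; the chi-square approximation may be poor",
              call. = FALSE)
    }
    res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    out <- list(statistic = unname(res$statistic), df = unname(res$parameter),
                p_value = unname(res$p.value), variant = "pearson")
  } else {
    if (nrow(counts) != 2L) {
      stop("trend variant requires a 2 x k table", call. = FALSE)
    }
    k <- ncol(counts)
    trend_scores <- trend_scores %||% seq_len(k)
    if (length(trend_scores) != k) {
      stop("trend_scores must have one score per column", call. = FALSE)
    }
    res <- suppressWarnings(
      stats::prop.trend.test(counts[1L, ], colSums(counts), score = trend_scores)
    )
    out <- list(statistic = unname(res$statistic), df = 1L,
                p_value = unname(res$p.value), variant = "trend")
  }
  structure(out, class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Chi-square (%s): statistic = %.4g, df = %d, p = %.4g\n",
              x$variant, x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Pearson correlation with its t-based p-value
#'
#' Product-moment correlation between two score vectors, with the two-sided
#' p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return A list of class `correlation_result` with `r`, `n`, `t_statistic`
#'   and `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("x and y must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  res <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(res$estimate), n = length(x),
                 t_statistic = unname(res$statistic),
                 p_value = unname(res$p.value)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson correlation: r = %.4f (n = %d), t = %.4g, p = %.4g\n",
              x$r, x$n, x$t_statistic, x$p_value))
  invisible(x)
}
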