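#' Run the full dual-signature analysis
#'
#' Wires the stages together: score every signature in the GMT (ssGSEA-style
#' or ratio-mean), standardize by cohort median/IQR, assign score-plane
#' quadrants on the 18-gene and 13-gene axes, tabulate CMS class against
#' quadrant, test that association with a chi-square test (classes with no
#' samples are dropped from the table first, as an all-zero row would make
#' the test undefined), and correlate the 13-gene and SRC-activation
#' standardized scores. Deterministic given its inputs; when `outdir` is
#' given every intermediate is written there.
#'
#' @param expression Expression matrix or path to one
#'   ([read_expression_matrix()]).
#' @param gene_sets List of [gene_set()] objects or path to a GMT file.
#' @param annotations Annotation data.frame or path to a CSV
#'   ([read_annotations()]).
#' @param sig18,sig13,src Names of the three signatures in the GMT.
#' @param config A [scoring_config()].
#' @param threshold18,threshold13 Quadrant boundaries on the standardized
#'   scores, default 0 (the median).
#' @param outdir Optional output directory for the report bundle
#'   (scores.tsv, quadrant_calls.tsv, quadrant_counts.tsv, stats.tsv/json).
#' @param report_format `"tsv"` or `"json"` for the stats report file.
#' @return A list with `scores` ([score_table()]), `calls`
#'   ([assign_quadrants()] output), `quadrant_counts`, `chi_square`
#'   ([chi_square_test()] result) and `correlation`
#'   ([pearson_correlation()] result), invisibly.
#' @export
run_pipeline <- function(expression, gene_sets, annotations,
                         sig18 = "RAS18", sig13 = "MEKR13", src = "SRC61",
                         config = scoring_config(),
                         threshold18 = 0, threshold13 = 0,
                         outdir = NULL, report_format = c("tsv", "json")) {
  report_format <- match.arg(report_format)
  if (is.character(expression)) expression <- read_expression_matrix(expression)
  if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  gene_sets <- as_gene_set_list(gene_sets)

  needed <- c(sig18 = sig18, sig13 = sig13, src = src)
  absent <- needed[!needed %in% names(gene_sets)]
  if (length(absent) > 0L) {
    stop("signature(s) not found in gene sets: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }

  message(sprintf("scoring %d samples x %d gene sets (method = %s, alpha = %g)",
                  ncol(expression), length(gene_sets), config$method,
                  config$alpha))
  scores <- switch(config$method,
    ssgsea = ssgsea_scores(expression, gene_sets, config),
    ratio_mean = ratio_mean_scores(expression, gene_sets, config)
  )
  scores <- standardize_scores(scores)
  calls <- assign_quadrants(scores, sig18 = sig18, sig13 = sig13,
                            threshold18 = threshold18,
                            threshold13 = threshold13)
  counts <- quadrant_summary(calls, annotations)

  populated <- counts[rowSums(counts) > 0L, , drop = FALSE]
  occupied <- populated[, colSums(populated) > 0L, drop = FALSE]
  chisq <- chi_square_test(occupied, variant = "pearson")
  correlation <- pearson_correlation(scores$standardized[, sig13],
                                     scores$standardized[, src])

  result <- list(scores = scores, calls = calls, quadrant_counts = counts,
                 chi_square = chisq, correlation = correlation)
  if (!is.null(outdir)) write_report_bundle(result, outdir, report_format)
  invisible(result)
}

write_report_bundle <- function(result, outdir, report_format) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_score_table(result$scores, file.path(outdir, "scores.tsv"))
  calls <- result$calls
  calls$score18 <- sprintf("%.17g", calls$score18)
  calls$score13 <- sprintf("%.17g", calls$score13)
  utils::write.table(calls, file.path(outdir, "quadrant_calls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts <- data.frame(cms_class = rownames(result$quadrant_counts),
                       result$quadrant_counts, check.names = FALSE)
  utils::write.table(counts, file.path(outdir, "quadrant_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stats_list <- list(
    chi_square = result$chi_square[c("statistic", "df", "p_value", "variant")],
    correlation = result$correlation[c("r", "n", "t_statistic", "p_value")]
  )
  if (report_format == "json") {
    jsonlite::write_json(stats_list, file.path(outdir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    df <- data.frame(
      test = c("chi_square_pearson", "pearson_correlation"),
      statistic = sprintf("%.17g", c(result$chi_square$statistic,
                                     result$correlation$r)),
      df = c(result$chi_square$df, result$correlation$n - 2L),
      p_value = sprintf("%.17g", c(result$chi_square$p_value,
                                   result$correlation$p_value))
    )
    utils::write.table(df, file.path(outdir, "stats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(outdir)
}

#' Quadrant demonstration on the packaged 16-cell-line example
#'
#' Applies the strict-positivity quadrant rule directly to the published,
#' already-standardized scores of the packaged worked example (the scoring
#' stage is skipped) and summarises the result.
#'
#' @return A list with `calls`, `quadrant_counts`, and
#'   `predicted_sensitive` (the cell lines called combination-sensitive).
#' @export
table1_demo <- function() {
  fixture <- load_table1_fixture()
  calls <- assign_quadrants(fixture$scores, sig18 = "RAS18", sig13 = "MEKR13")
  counts <- quadrant_summary(calls, fixture$annotations)
  list(calls = calls, quadrant_counts = counts,
       predicted_sensitive = calls$sample_id[calls$combo_sensitive_predicted])
}
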