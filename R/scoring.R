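#' Scoring configuration
#'
#' @param method Scoring method: `"ssgsea"` (rank-weighted single-sample
#'   enrichment) or `"ratio_mean"` (cohort-mean-normalized gene averaging).
#' @param alpha Non-negative exponent applied to rank magnitudes in the
#'   ssGSEA-style scorer; 0.25 by default. Larger values up-weight genes near
#'   the extremes of a sample's expression ranking.
#' @param allow_missing_genes If `FALSE` (default) every signature gene must
#'   be present in the matrix; if `TRUE`, sets are scored on their
#'   intersection with the matrix provided coverage is at least
#'   `min_coverage`, and the coverage fraction is reported via a message.
#' @param min_coverage Minimum fraction of signature genes that must be
#'   present when `allow_missing_genes = TRUE`; in (0, 1].
#' @return A list of class `scoring_config`.
#' @export
scoring_config <- function(method = c("ssgsea", "ratio_mean"), alpha = 0.25,
                           allow_missing_genes = FALSE, min_coverage = 1) {
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  if (!is.numeric(min_coverage) || min_coverage <= 0 || min_coverage > 1) {
    stop("min_coverage must be in (0, 1]", call. = FALSE)
  }
  structure(list(method = method, alpha = alpha,
                 allow_missing_genes = isTRUE(allow_missing_genes),
                 min_coverage = min_coverage),
            class = "scoring_config")
}

# enforce the coverage policy for one membership vector; returns the members
# present in the matrix
check_coverage <- function(members, gene_ids, set_name, config) {
  present <- intersect(members, gene_ids)
  missing <- setdiff(members, gene_ids)
  if (length(missing) == 0L) return(present)
  coverage <- length(present) / length(members)
  if (!config$allow_missing_genes) {
    stop("signature '", set_name, "' gene(s) absent from matrix: ",
         paste(missing, collapse = ", "),
         " (set allow_missing_genes = TRUE to score on the intersection)",
         call. = FALSE)
  }
  if (coverage < config$min_coverage) {
    stop(sprintf("signature '%s' coverage %.2f below min_coverage %.2f; missing: %s",
                 set_name, coverage, config$min_coverage,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  message(sprintf("signature '%s': scoring on %d/%d genes (coverage %.2f)",
                  set_name, length(present), length(members), coverage))
  present
}

# average rows sharing a gene id (probe-level rows collapsed to gene level)
collapse_duplicate_rows <- function(values) {
  if (!anyDuplicated(rownames(values))) return(values)
  groups <- factor(rownames(values), levels = unique(rownames(values)))
  sums <- rowsum(values, group = groups, reorder = FALSE)
  sums / as.vector(table(groups))
}

#' Ratio-mean signature scores
#'
#' Each signature gene's values are first divided by that gene's mean across
#' all samples of the cohort, which puts genes whose absolute expression
#' differs by orders of magnitude on a common footing and prevents a few
#' dominant genes or probes from carrying the score. Rows sharing a gene id
#' (probe rows) are then averaged, and a sample's score for a set is the
#' mean of its normalized up-gene values minus the mean of its normalized
#' down-gene values (zero when the set has no down-members).
#'
#' The score is scale-invariant per gene: rescaling any single gene's row by
#' a positive constant leaves all scores unchanged.
#'
#' @param values Expression matrix (genes x samples); duplicate gene-id rows
#'   are allowed and treated as probes.
#' @param sets List of [gene_set()] objects.
#' @param config A [scoring_config()]; only the coverage policy fields are
#'   used here.
#' @return A [score_table()] with the raw slot filled.
#' @export
ratio_mean_scores <- function(values, sets, config = scoring_config()) {
  validate_expression_matrix(values, allow_duplicate_genes = TRUE)
  sets <- as_gene_set_list(sets)
  row_means <- rowMeans(values)
  member_universe <- unique(unlist(lapply(sets, function(s) c(s$up, s$down))))
  zero_mean <- intersect(member_universe,
                         rownames(values)[abs(row_means) == 0])
  if (length(zero_mean) > 0L) {
    stop("signature gene(s) with zero cohort mean (ratio undefined): ",
         paste(unique(zero_mean), collapse = ", "), call. = FALSE)
  }
  normalized <- collapse_duplicate_rows(values / row_means)

  raw <- matrix(NA_real_, nrow = ncol(values), ncol = length(sets),
                dimnames = list(colnames(values),
                                vapply(sets, `[[`, character(1), "name")))
  for (s in sets) {
    up <- check_coverage(s$up, rownames(normalized), s$name, config)
    score <- colMeans(normalized[up, , drop = FALSE])
    if (length(s$down) > 0L) {
      down <- check_coverage(s$down, rownames(normalized),
                             paste0(s$name, " (down)"), config)
      score <- score - colMeans(normalized[down, , drop = FALSE])
    }
    raw[, s$name] <- score
  }
  score_table(raw)
}

#' Rank-weighted single-sample enrichment scores (ssGSEA family)
#'
#' For each sample, genes are ranked by descending expression (ties take the
#' average rank; the traversal order for the running sums is descending value
#' with ties broken lexicographically by gene id, so the score is fully
#' deterministic). Walking down that ranking, two empirical cumulative
#' distributions are accumulated: the in-set one steps by
#' `rank_magnitude^alpha` at each signature gene (rank magnitudes are the
#' ranks N..1 themselves, normalized so the in-set steps sum to 1) and the
#' out-of-set one steps by `1/(N - m)` at each non-member. The score is the
#' sum over all positions of the difference between the two running sums —
#' the unnormalized, rank-weighted member of the ssGSEA family, which
#' depends on each sample's expression only through its ranking and is
#' therefore invariant to any strictly increasing per-sample transform.
#' Signed sets are scored as up-score minus down-score.
#'
#' @param values Expression matrix (genes x samples); duplicate gene-id rows
#'   are averaged on the raw values before ranking.
#' @param sets List of [gene_set()] objects; each membership component must
#'   cover neither zero nor all of the matrix genes.
#' @param config A [scoring_config()] supplying `alpha` and the coverage
#'   policy.
#' @return A [score_table()] with the raw slot filled.
#' @export
ssgsea_scores <- function(values, sets, config = scoring_config()) {
  validate_expression_matrix(values, allow_duplicate_genes = TRUE)
  sets <- as_gene_set_list(sets)
  values <- collapse_duplicate_rows(values)
  gene_ids <- rownames(values)
  n_genes <- nrow(values)

  component_score <- function(members, sample_values) {
    m <- length(members)
    # descending-value traversal, ties by gene id (C-locale radix order)
    idx <- order(-sample_values, gene_ids, method = "radix")
    magnitude <- rank(sample_values, ties.method = "average")
    in_set <- gene_ids[idx] %in% members
    w <- numeric(n_genes)
    w[in_set] <- magnitude[idx][in_set]^config$alpha
    w[in_set] <- w[in_set] / sum(w[in_set])
    out_step <- numeric(n_genes)
    out_step[!in_set] <- 1 / (n_genes - m)
    sum(cumsum(w) - cumsum(out_step))
  }

  raw <- matrix(NA_real_, nrow = ncol(values), ncol = length(sets),
                dimnames = list(colnames(values),
                                vapply(sets, `[[`, character(1), "name")))
  for (s in sets) {
    up <- check_coverage(s$up, gene_ids, s$name, config)
    down <- if (length(s$down) > 0L) {
      check_coverage(s$down, gene_ids, paste0(s$name, " (down)"), config)
    } else character(0)
    for (members in list(up, down)) {
      if (length(members) == 0L) next
      if (length(members) >= n_genes) {
        stop("signature '", s$name,
             "' covers the whole gene universe; out-of-set distribution undefined",
             call. = FALSE)
      }
    }
    if (length(up) == 0L) {
      stop("signature '", s$name, "' has no genes in the matrix", call. = FALSE)
    }
    for (j in seq_len(ncol(values))) {
      score <- component_score(up, values[, j])
      if (length(down) > 0L) score <- score - component_score(down, values[, j])
      raw[j, s$name] <- score
    }
  }
  score_table(raw)
}

#' Standardize scores by cohort median and IQR
#'
#' Each signature column is centred on its median and divided by its
#' interquartile range across all samples, with quantiles computed by linear
#' interpolation (the type-7 convention, R's default). The standardized
#' scores therefore have median 0 and IQR 1 by construction, the convention
#' under which zero is the natural quadrant boundary; the operation is
#' idempotent.
#'
#' @param table A [score_table()].
#' @return The same table with the standardized slot filled.
#' @export
standardize_scores <- function(table) {
  stopifnot(inherits(table, "score_table"))
  raw <- table$raw
  std <- raw
  for (sig in colnames(raw)) {
    iqr <- stats::IQR(raw[, sig], type = 7)
    if (iqr == 0) {
      stop("signature '", sig,
           "' has zero interquartile range; standardization undefined",
           call. = FALSE)
    }
    std[, sig] <- (raw[, sig] - stats::median(raw[, sig])) / iqr
  }
  score_table(raw, std)
}

# accept a single gene_set, a named list of them, or a bare list
as_gene_set_list <- function(sets) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  if (!is.list(sets) || length(sets) == 0L ||
      !all(vapply(sets, inherits, logical(1), "gene_set"))) {
    stop("sets must be one or more gene_set objects", call. = FALSE)
  }
  names(sets) <- vapply(sets, `[[`, character(1), "name")
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene set names", call. = FALSE)
  }
  sets
}
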