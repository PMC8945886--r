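# Independent brute-force oracles, written as literal transcriptions of the
# defining formulas so they share no code with the package implementation.

# rank-weighted single-sample enrichment score for one sample and one
# membership vector: explicit enumeration of both running sums
oracle_enrichment <- function(sample_values, gene_ids, members, alpha) {
  n <- length(gene_ids)
  m <- length(members)
  # descending expression, ties by gene id
  ord <- order(-sample_values, gene_ids, method = "radix")
  # rank magnitude = ascending average rank, so the top gene carries ~n
  mag <- rank(sample_values, ties.method = "average")
  in_set <- gene_ids[ord] %in% members
  w_raw <- ifelse(in_set, mag[ord]^alpha, 0)
  w <- w_raw / sum(w_raw)
  score <- 0
  cum_in <- 0
  cum_out <- 0
  for (i in seq_len(n)) {
    if (in_set[i]) cum_in <- cum_in + w[i] else cum_out <- cum_out + 1 / (n - m)
    score <- score + (cum_in - cum_out)
  }
  score
}

# cellwise evaluation of the chi-square statistic of independence
oracle_chisq_stat <- function(tab) {
  total <- sum(tab)
  stat <- 0
  for (i in seq_len(nrow(tab))) {
    for (j in seq_len(ncol(tab))) {
      expected <- sum(tab[i, ]) * sum(tab[, j]) / total
      stat <- stat + (tab[i, j] - expected)^2 / expected
    }
  }
  stat
}

# product-moment correlation from its definitional sums
oracle_pearson_r <- function(x, y) {
  xc <- x - mean(x)
  yc <- y - mean(y)
  sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
}

# Cochran-Armitage trend statistic for a 2 x k table with column scores
oracle_trend_stat <- function(tab, s) {
  n <- colSums(tab)
  N <- sum(n)
  p_bar <- sum(tab[1, ]) / N
  num <- sum(s * (tab[1, ] - n * p_bar))^2
  den <- p_bar * (1 - p_bar) * (sum(n * s^2) - sum(n * s)^2 / N)
  num / den
}

# small deterministic expression matrix used across tests
toy_matrix <- function() {
  m <- matrix(c(1, 2, 3,
                2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("geneA", "geneB"), c("s1", "s2", "s3")))
  m
}

random_matrix <- function(n_genes, n_samples, prefix = "G") {
  matrix(stats::rnorm(n_genes * n_samples, mean = 5, sd = 2),
         nrow = n_genes,
         dimnames = list(sprintf("%s%03d", prefix, seq_len(n_genes)),
                         sprintf("S%03d", seq_len(n_samples))))
}
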