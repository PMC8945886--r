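test_that("ratio-mean scores reproduce the hand-derived worked example", {
  m <- toy_matrix() # geneA = (1,2,3), geneB = (2,2,2)
  up_only <- gene_set("SIG", up = c("geneA", "geneB"))
  tab <- ratio_mean_scores(m, list(up_only))
  expect_equal(unname(tab$raw[, "SIG"]), c(0.75, 1.0, 1.25))

  signed <- gene_set("SGN", up = "geneA", down = "geneB")
  tab2 <- ratio_mean_scores(m, list(signed))
  expect_equal(unname(tab2$raw[, "SGN"]), c(-0.5, 0, 0.5))
})

test_that("identical samples all score 1 for an up-only set", {
  m <- matrix(rep(c(3, 7), each = 4), nrow = 2, byrow = TRUE,
              dimnames = list(c("a", "b"), paste0("s", 1:4)))
  tab <- ratio_mean_scores(m, list(gene_set("S", up = c("a", "b"))))
  expect_equal(unname(tab$raw[, "S"]), rep(1, 4))
})

test_that("ratio-mean scores are invariant to per-gene rescaling", {
  set.seed(21)
  for (rep in 1:5) {
    m <- abs(random_matrix(8, 6)) + 1
    sets <- list(gene_set("S", up = rownames(m)[1:4], down = rownames(m)[5:6]))
    base <- ratio_mean_scores(m, sets)
    m2 <- m
    g <- sample(nrow(m), 1)
    m2[g, ] <- m2[g, ] * runif(1, 0.1, 50)
    expect_equal(ratio_mean_scores(m2, sets)$raw, base$raw, tolerance = 1e-12)
  }
})

test_that("probe rows sharing a gene id are averaged after normalization", {
  # two probes for geneA on very different scales; after per-row mean
  # normalization each probe contributes equally
  m <- matrix(c(1, 2, 3,
                100, 200, 300,
                2, 2, 2), nrow = 3, byrow = TRUE,
              dimnames = list(c("geneA", "geneA", "geneB"),
                              c("s1", "s2", "s3")))
  tab <- ratio_mean_scores(m, list(gene_set("S", up = c("geneA", "geneB"))))
  # both probes normalize to (0.5, 1, 1.5), geneB to (1,1,1)
  expect_equal(unname(tab$raw[, "S"]), c(0.75, 1.0, 1.25))
})

test_that("ratio-mean rejects zero-mean signature genes and missing genes", {
  m <- matrix(c(-1, 0, 1,
                2, 2, 2), nrow = 2, byrow = TRUE,
              dimnames = list(c("zmean", "ok"), c("s1", "s2", "s3")))
  expect_error(ratio_mean_scores(m, list(gene_set("S", up = c("zmean", "ok")))),
               "zmean")

  m2 <- toy_matrix()
  expect_error(
    ratio_mean_scores(m2, list(gene_set("S", up = c("geneA", "ghost")))),
    "ghost")
  cfg <- scoring_config(allow_missing_genes = TRUE, min_coverage = 0.5)
  expect_message(
    tab <- ratio_mean_scores(m2, list(gene_set("S", up = c("geneA", "ghost"))),
                             cfg),
    "coverage")
  expect_equal(unname(tab$raw[, "S"]), c(0.5, 1, 1.5))
  cfg_strict <- scoring_config(allow_missing_genes = TRUE, min_coverage = 0.9)
  expect_error(
    ratio_mean_scores(m2, list(gene_set("S", up = c("geneA", "ghost"))),
                      cfg_strict),
    "coverage")
})

test_that("enrichment score matches the hand-enumerated running sums", {
  m <- matrix(c(4, 3, 2, 1), ncol = 1,
              dimnames = list(c("g1", "g2", "g3", "g4"), "s1"))
  cfg <- scoring_config(alpha = 0)
  tab <- ssgsea_scores(m, list(gene_set("TOP", up = "g1")), cfg)
  # (1-0) + (1-1/3) + (1-2/3) + (1-1) = 2
  expect_equal(unname(tab$raw["s1", "TOP"]), 2.0)
})

test_that("enrichment scores agree with the brute-force oracle", {
  set.seed(99)
  for (rep in 1:25) {
    m <- random_matrix(10, 3)
    members <- sample(rownames(m), sample(2:5, 1))
    alpha <- sample(c(0, 0.25, 1), 1)
    cfg <- scoring_config(alpha = alpha)
    tab <- ssgsea_scores(m, list(gene_set("S", up = members)), cfg)
    for (j in 1:3) {
      expect_equal(tab$raw[j, "S"],
                   oracle_enrichment(m[, j], rownames(m), members, alpha),
                   tolerance = 1e-12)
    }
  }
})

test_that("enrichment scores depend only on within-sample ranks", {
  set.seed(7)
  m <- random_matrix(12, 4)
  sets <- list(gene_set("S", up = rownames(m)[c(1, 5, 9)],
                        down = rownames(m)[c(2, 6)]))
  base <- ssgsea_scores(m, sets)
  # strictly increasing transforms per sample: doubling, exp, cube
  m2 <- m
  m2[, 1] <- 2 * m2[, 1]
  m2[, 2] <- exp(m2[, 2] / 4)
  m2[, 3] <- m2[, 3]^3
  expect_equal(ssgsea_scores(m2, sets)$raw, base$raw, tolerance = 1e-12)
})

test_that("enrichment scoring rejects degenerate set/universe combinations", {
  m <- toy_matrix()
  expect_error(ssgsea_scores(m, list(gene_set("ALL", up = rownames(m)))),
               "universe")
  expect_error(ssgsea_scores(m, list(gene_set("NONE", up = "ghost")),
                             scoring_config(allow_missing_genes = TRUE,
                                            min_coverage = 1e-6)),
               "coverage")
})

test_that("median/IQR standardization matches the type-7 hand example", {
  raw <- matrix(c(0.75, 1.0, 1.25), ncol = 1,
                dimnames = list(paste0("s", 1:3), "SIG"))
  tab <- standardize_scores(score_table(raw))
  expect_equal(unname(tab$standardized[, "SIG"]), c(-1, 0, 1))
})

test_that("standardization always yields median 0 / IQR 1 and is idempotent", {
  set.seed(13)
  for (rep in 1:10) {
    raw <- matrix(rnorm(40, sd = runif(1, 0.5, 20)), ncol = 2,
                  dimnames = list(paste0("s", 1:20), c("A", "B")))
    tab <- standardize_scores(score_table(raw))
    for (sig in c("A", "B")) {
      expect_lt(abs(median(tab$standardized[, sig])), 1e-9)
      expect_lt(abs(IQR(tab$standardized[, sig], type = 7) - 1), 1e-9)
    }
    twice <- standardize_scores(score_table(tab$standardized))
    expect_equal(twice$standardized, tab$standardized, tolerance = 1e-12)
  }
})

test_that("standardization errors on a constant score column", {
  raw <- matrix(rep(2, 4), ncol = 1,
                dimnames = list(paste0("s", 1:4), "FLAT"))
  expect_error(standardize_scores(score_table(raw)), "FLAT")
})

test_that("sample order permutation permutes scores identically", {
  set.seed(31)
  m <- abs(random_matrix(10, 6)) + 1
  sets <- list(gene_set("S", up = rownames(m)[1:5]))
  perm <- sample(ncol(m))
  for (scorer in list(ratio_mean_scores, ssgsea_scores)) {
    base <- scorer(m, sets)
    shuffled <- scorer(m[, perm], sets)
    expect_equal(shuffled$raw[colnames(m), ], base$raw[, 1],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("scoring configuration validates its fields", {
  expect_error(scoring_config(alpha = -1), "alpha")
  expect_error(scoring_config(min_coverage = 0), "min_coverage")
  expect_error(scoring_config(min_coverage = 1.5), "min_coverage")
})
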