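test_that("chi-square statistic matches hand-derived tables", {
  r <- chi_square_test(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20.0)
  expect_equal(r$df, 1L)
  expect_equal(r$variant, "pearson")

  expect_equal(chi_square_test(matrix(c(5, 5, 5, 5), 2))$statistic, 0.0)

  tab <- matrix(c(2, 4, 4, 2), 2)
  expect_warning(res3 <- chi_square_test(tab), "expected")
  expect_equal(res3$statistic, oracle_chisq_stat(tab), tolerance = 1e-12)
})

test_that("chi-square agrees with the cellwise oracle on random tables", {
  set.seed(41)
  for (rep in 1:30) {
    nr <- sample(2:5, 1)
    nc <- sample(2:5, 1)
    tab <- matrix(rpois(nr * nc, lambda = 12) + 1, nr, nc)
    res <- suppressWarnings(chi_square_test(tab))
    expect_equal(res$statistic, oracle_chisq_stat(tab), tolerance = 1e-9)
    expect_equal(res$df, (nr - 1L) * (nc - 1L))
    expect_equal(res$p_value,
                 pchisq(oracle_chisq_stat(tab), res$df, lower.tail = FALSE),
                 tolerance = 1e-9)
    # permutation invariance and linear scaling of the statistic
    perm <- suppressWarnings(
      chi_square_test(tab[sample(nr), sample(nc), drop = FALSE]))
    expect_equal(perm$statistic, res$statistic, tolerance = 1e-9)
    tripled <- suppressWarnings(chi_square_test(tab * 3))
    expect_equal(tripled$statistic, res$statistic * 3, tolerance = 1e-9)
  }
})

test_that("trend variant matches the Cochran-Armitage formula", {
  set.seed(43)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    tab <- matrix(rpois(2 * k, lambda = 15) + 1, nrow = 2)
    s <- sort(sample(1:20, k))
    res <- chi_square_test(tab, variant = "trend", trend_scores = s)
    expect_equal(res$statistic, oracle_trend_stat(tab, s), tolerance = 1e-9)
    expect_equal(res$df, 1L)
  }
  expect_error(chi_square_test(matrix(1:9, 3), variant = "trend"), "2 x k")
})

test_that("chi-square rejects degenerate tables and warns on sparse cells", {
  expect_error(chi_square_test(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
  expect_error(chi_square_test(matrix(c(1, 2), ncol = 1)), "2 x 2")
  expect_warning(chi_square_test(matrix(c(1, 2, 2, 1), 2)), "expected")
})

test_that("correlation matches hand-derived cases and the definitional sums", {
  expect_equal(pearson_correlation(1:3, c(2, 4, 6))$r, 1.0)
  expect_equal(pearson_correlation(1:3, c(3, 2, 1))$r, -1.0)
  # centred cross-sum 4, both centred square-sums 5, so r = 4/5
  res <- pearson_correlation(1:4, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8, tolerance = 1e-12)
  expect_equal(res$n, 4L)
  expect_equal(res$t_statistic, res$r * sqrt(2 / (1 - res$r^2)),
               tolerance = 1e-12)

  set.seed(47)
  for (rep in 1:30) {
    n <- sample(5:40, 1)
    x <- rnorm(n)
    y <- rnorm(n) + 0.3 * x
    res <- pearson_correlation(x, y)
    expect_equal(res$r, oracle_pearson_r(x, y), tolerance = 1e-9)
    expect_equal(res$p_value,
                 2 * pt(abs(res$t_statistic), n - 2, lower.tail = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("correlation is affine-invariant and flips sign under negation", {
  set.seed(53)
  x <- rnorm(20)
  y <- rnorm(20) + x
  base <- pearson_correlation(x, y)$r
  expect_equal(pearson_correlation(3 * x + 7, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, 0.1 * y - 2)$r, base, tolerance = 1e-12)
  expect_equal(pearson_correlation(-x, y)$r, -base, tolerance = 1e-12)
})

test_that("correlation rejects constant or mismatched input", {
  expect_error(pearson_correlation(rep(1, 5), rnorm(5)), "constant")
  expect_error(pearson_correlation(1:4, 1:5), "length")
  expect_error(pearson_correlation(1:2, 1:2), "3")
})

test_that("with no latent coupling the correlation p-value is well calibrated", {
  # 13-gene vs SRC scores on null cohorts: the two-sided p should be
  # approximately uniform, so the 0.05 rejection rate over 1000 replicates
  # must sit inside binomial 99% bounds
  rejections <- 0L
  for (i in seq_len(1000)) {
    cfg <- cohort_sim_config(
      n_per_class = c(CMS1 = 10, CMS2 = 10, CMS3 = 10, CMS4 = 10),
      n_background_genes = 0, shared_latent_loading = 0, seed = 20000 + i)
    co <- generate_cohort(cfg)
    tab <- ratio_mean_scores(co$expression,
                             co$gene_sets[c("MEKR13", "SRC61")])
    p <- pearson_correlation(tab$raw[, "MEKR13"], tab$raw[, "SRC61"])$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.05)
  expect_gte(rejections, bounds[1])
  expect_lte(rejections, bounds[2])
})
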