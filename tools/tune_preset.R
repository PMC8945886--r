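#!/usr/bin/env Rscript
# One-time tuning of the quadrant-preset constants frozen in
# quadrant_preset_effects() / generate_quadrant_cohort().
#
# Goal: with n = 50 per CMS class, ratio-mean scoring and median/IQR
# standardization, the preset should robustly (across seeds) give
#   - > 80% of CMS4 samples in the right upper quadrant,
#   - a 13-gene <-> SRC standardized-score Pearson r >= 0.8 (both methods),
#   - a strongly significant CMS x quadrant chi-square.
#
# Candidate effect matrices were screened over 40-60 seeds; the frozen
# choice couples the SRC genes to the class structure at half the 13-gene
# effect size (SRC-driven resistance) with a shared latent loading of 2.5.
# Run time: a few minutes.

library(sigquad)

evaluate <- function(effects, loading, seeds = 1:60) {
  t(sapply(seeds, function(s) {
    cfg <- cohort_sim_config(
      n_per_class = c(CMS1 = 50, CMS2 = 50, CMS3 = 50, CMS4 = 50),
      effects = effects, shared_latent_loading = loading, seed = s)
    co <- generate_cohort(cfg)
    res <- suppressMessages(run_pipeline(
      co$expression, co$gene_sets, co$annotations,
      config = scoring_config("ratio_mean")))
    c(r = res$correlation$r,
      ruq_cms4 = mean(res$calls$quadrant[grepl("^CMS4",
                                               res$calls$sample_id)] == "RUQ"),
      chisq_p = res$chi_square$p_value)
  }))
}

frozen <- evaluate(quadrant_preset_effects(), loading = 2.5)
cat("frozen preset over 60 seeds:\n")
cat(sprintf("  r:        min %.3f mean %.3f\n",
            min(frozen[, "r"]), mean(frozen[, "r"])))
cat(sprintf("  CMS4 RUQ: min %.3f mean %.3f\n",
            min(frozen[, "ruq_cms4"]), mean(frozen[, "ruq_cms4"])))
cat(sprintf("  chisq p:  max %.3g\n", max(frozen[, "chisq_p"])))
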