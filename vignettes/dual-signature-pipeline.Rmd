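---
title: "Dual-signature scoring and quadrant-based sensitivity prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-signature scoring and quadrant-based sensitivity prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigquad)
```

## The model

`sigquad` operationalizes a biomarker strategy for colorectal cancer (CRC):
a tumor or cell line is predicted sensitive to combined MEK + SRC
inhibition when it scores positive on *both* an 18-gene RAS-pathway
activation signature (MEK-pathway dependence) and a 13-gene MEKi-resistance
signature (bypass-pathway priming, strongly coupled to SRC activation,
tracked by a 61-gene SRC signature). The pipeline is: per-sample signature
scoring, cohort-wide median/IQR standardization, quadrant assignment in the
(18-gene, 13-gene) plane, and cohort-level statistics.

The package consumes an already-normalized, log-scale gene × sample matrix
and applies no further transformation; normalization choices belong to the
upstream processing of the platform at hand. Gene identifiers are matched
case-sensitively and exactly. The three signature membership lists are user
input (GMT format): they are published elsewhere and are not redistributed
here, so all packaged sets are synthetic stand-ins.

## Scoring methods

Two scorers are exposed; both handle signed sets as up-component minus
down-component, which degrades gracefully to up-only scoring.

**Ratio-mean.** Signature-gene values are first divided by the gene's mean
across all cohort samples — absolute expression of different genes (or
probes) can differ by orders of magnitude, and without this step a few
dominant genes would carry the score. Probe rows sharing a gene id are then
averaged, and a sample's score is the mean over its normalized up-gene
values. Consequences worth knowing: the score is cohort-relative (adding or
removing samples changes it), per-gene scale-invariant, and undefined when
a signature gene has cohort mean zero (an error, not a silent drop —
mean-zero genes essentially cannot occur on log-intensity scales, and on
centred data the ratio is meaningless anyway).

**Rank-weighted single-sample enrichment (ssGSEA family).** Per sample,
genes are ranked by descending expression. Walking down the ranking, an
in-set cumulative distribution steps by `rank_magnitude^alpha` (normalized
to total 1) at each signature gene and an out-of-set one steps by
`1/(N - m)` elsewhere; the score is the sum of the running differences.
Published single-sample enrichment implementations differ in details
(value- vs rank-weighted steps, final range normalization). This package
fixes one deterministic variant: rank magnitudes are the ranks `N..1`
themselves (average ranks at ties), `alpha = 0.25` by default, and no final
normalization across samples. That variant depends on a sample's expression
only through its within-sample ranking — so it is invariant under any
strictly increasing per-sample transform, which makes it robust to
monotone normalization differences and directly testable against a
brute-force enumeration oracle (the suite checks agreement to 1e-12).
Tie-break for the traversal order is lexicographic gene id, purely for
determinism.

**Missing signature genes.** By default every signature gene must be
present in the matrix; `allow_missing_genes = TRUE` with a `min_coverage`
threshold opts into intersection scoring with the coverage fraction
reported. Silent partial scoring is deliberately not the default: dropped
genes change what the signature measures.

## Standardization and the quadrant rule

Each score column is centred on its cohort median and divided by its
interquartile range, computed with type-7 (linearly interpolated) quantiles
— R's default convention; the exact quantile convention is otherwise
arbitrary and is simply documented and fixed. Standardized columns have
median 0 and IQR 1 by construction, and the operation is idempotent.
Median/IQR is preferred over mean/SD because signature scores in mixed
cohorts are routinely skewed by a high-scoring subclass.

Quadrants use *strict* positivity: a sample sits in the right upper
quadrant (RUQ, predicted combination-sensitive) only if both scores exceed
their thresholds (default 0, i.e. the medians). A score exactly on the
boundary is non-positive. The packaged 16-cell-line example fixes this
choice: the line SW48 carries an 18-gene score of exactly 0.00 and must not
be called sensitive for the published count of 8 RUQ lines to be
reproduced. Thresholds are exposed for users supplying raw scores with
external cutoffs. The prediction is binary by design; the rule defines no
confidence score.

## Cohort statistics

The CMS × quadrant association is tested with the classical chi-square test
of independence (no continuity correction); expected counts under 5 produce
a warning, never a silent method switch. A Cochran–Armitage trend variant
is provided for 2 × k tables with ordered columns and user-supplied scores
— which of the two flavours a given published statistic used is often
unstated, so both are first-class and neither is guessed. Score–score
coupling is measured by the Pearson correlation with the usual two-sided
t-based p-value (n − 2 degrees of freedom). P-values are reported at full
precision; "< 0.0001"-style bounds are a formatting concern.

`run_pipeline()` drops CMS classes with zero samples from the contingency
table before testing — an all-zero row would make the test undefined, and
most cohorts have no UNCLASSIFIED samples — while `chi_square_test()`
itself rejects zero marginals, as a direct call should.

## The synthetic cohort generator

`generate_cohort()` draws log-scale expression from an additive Gaussian
model: baseline + class effect (per CMS class and signature role) + a
shared latent factor loading on the 13-gene and SRC genes + i.i.d. noise.
The scores are ratio and rank statistics, so a location-shift model is the
simplest structure that exercises every pipeline stage; the single latent
factor is the minimal mechanism producing the strong 13-gene ↔ SRC score
coupling the quadrant strategy relies on. Draw order is fixed and
documented — samples outer, genes inner, the sample's latent value before
its noise vector — under R's Mersenne-Twister RNG with inversion normals,
so a config plus seed is bit-reproducible.

Defaults: baseline 6 and noise sd 1 (log2-intensity-like units), signature
sizes 18/13/61 mirroring the real signatures, 200 background genes. The
quadrant preset (`generate_quadrant_cohort()`, 50 samples per class — the
scale of the public cell-line cohorts this emulates) uses effect sizes
frozen after a one-time simulation screen (`tools/tune_preset.R`): CMS4 is
shifted up on both axis signatures (+2 and +3.5), CMS2/CMS3 down on the
13-gene axis, CMS1 up-left-leaning; SRC-gene class effects are half the
13-gene effects — the two signatures share class structure as well as the
latent factor (loading 2.5), encoding the premise that MEKi-resistance
expression is SRC-driven. Under this preset the full pipeline robustly
yields a CMS × quadrant chi-square p far below 0.01, a 13-gene ↔ SRC
correlation around 0.95, and ~90% of CMS4 samples in the RUQ.

What the generator does *not* emulate: count-level noise (no negative
binomial), probe structure, batch effects, or the marginal distributions of
any real platform. Passing tests on synthetic cohorts demonstrate that the
pipeline recovers planted structure of the assumed form — not that the
signatures themselves are valid biomarkers on real data, which is an
external, wet-lab question.

## Numerical and design choices

- Exactly-zero scores are non-positive (see above); ranking ties get
  average ranks, traversal ties lexicographic gene id order.
- Written tables use 17 significant digits, so write → read round-trips
  are bit-exact.
- Duplicate gene-id rows are rejected when *reading* a matrix (silent
  duplicate ids in a file are almost always an upstream bug) but accepted
  by the scorers for in-memory matrices, where they are treated as probes:
  averaged after mean-normalization (ratio-mean) or on raw values before
  ranking (enrichment).
- Unknown CMS labels become `UNCLASSIFIED` with a warning rather than an
  error, so partially classified cohorts load.
- The command-line wrapper takes flags only; a config-file layer was left
  out to keep the wrapper a thin shell over the documented functions.
- Test problem sizes: cohorts of 24–200 samples with 92–292 genes, 200
  null replicates for the test-size check and 1000 for correlation
  calibration — sizes at which every documented property is already
  sharply testable while the suite stays fast.

## Limitations

- Whether a published score table came from the enrichment path or the
  ratio-mean path is often unknowable; both are exposed, and the packaged
  16-line example is consumed as printed scores rather than regenerated.
- The published external-cohort statistics (computed on downloaded
  microarray/RNA-seq cohorts with the real signature gene lists) are not
  reproducible without those inputs; the test suite instead verifies
  formula-level correctness against oracles and structure recovery on
  synthetic cohorts.
- No probe-set annotation mapping, no CMS classification (labels are
  consumed as annotation), no drug-response modelling.
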