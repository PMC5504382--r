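---
title: "Phylogenetic trait estimation and community-weighted mean analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic trait estimation and community-weighted mean analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Amplicon surveys of soil microbial communities deliver taxonomic marker
(16S rRNA gene) composition but say little about ecology. Two traits that
are both ecologically informative and phylogenetically conserved — rRNA
gene operon copy number (a proxy for growth responsiveness) and genome
size (a proxy for metabolic breadth) — can be estimated for uncultured
taxa from their position on a reference phylogeny of sequenced genomes.
`phylotraits` implements that estimation pipeline end to end: signal
screening, hidden-state prediction with uncertainty, copy-number
correction of OTU abundances, community-weighted means (CWMs), and the
treatment-response statistics of a factorial field experiment — plus a
synthetic-data generator with known ground truth, so every stage can be
validated without any sequencing data.

## The trait model

All continuous-trait machinery assumes Brownian motion on a rooted
phylogeny with branch lengths: a trait `x` on tips is multivariate normal
with mean `mu * 1` and covariance `sigma2 * C`, where `C[i, j]` is the
shared root-to-MRCA path length of tips `i` and `j`. Everything follows
from conditioning in this model:

* **Blomberg's K** is the ratio of tip variance around the GLS
  (phylogenetic) mean to the phylogenetically corrected variance, scaled
  by its Brownian expectation on the same tree, so `K = 1` under Brownian
  motion. The permutation test shuffles tip values and compares the
  corrected mean squared error.
* **Pagel's lambda** multiplies the off-diagonal of `C` by `lambda` and
  maximizes the profile likelihood (GLS mean, ML `sigma2 = q/n`) over
  `lambda` in `[0, 1]` by Brent search (tolerance 1e-8) with explicit
  endpoint checks; the test against `lambda = 0` is a 1-df LRT. On a star
  tree the likelihood is flat and the fit is flagged non-identifiable
  rather than reporting an arbitrary optimum.
* **Fritz–Purvis D** scores a binary trait's clumping: summed absolute
  daughter differences in a post-order pass (node value = mean of
  daughters, which reduces to `|v1 - v2|` on bifurcations; at polytomies
  the contribution is the sum of deviations from the node mean), scaled
  between a tip-shuffle null (D = 1) and a thresholded-Brownian null
  (D = 0). Both p-values use the `(b + 1) / (m + 1)` correction so no
  p-value is exactly zero.
* **Tip prediction** is the conditional mean of the query given the known
  tips, `mu_hat + C_qk C_kk^-1 (x_k - mu_hat 1)`, with `mu_hat` the GLS
  mean and `sigma2_hat` the ML Brownian rate on the known tips (divide by
  `n_known`; REML is not used, and this choice is recorded in the
  output metadata by construction — the SEs are conditional-model SEs).
  The 95% CI uses the normal 1.96 multiplier; uncertainty in `mu_hat` is
  deliberately not propagated, so CI widths are comparable across
  queries and usable as the ranking key for the least-certain-20%
  filter. Discrete traits use a 2-state equal-rates Markov model with the
  rate fit by ML and the query's marginal posterior computed by
  Felsenstein pruning under a stationary root.

Trait-unknown tips carry no information about each other, so
`estimate_all()` conditions every query on the reference tips only
(equivalently: all other queries are pruned first). Because pruning does
not change covariances among retained tips, all queries share a single
factorization; the equivalence with per-query pruned prediction is
asserted in the test suite, and the whole predictor is checked to 1e-8
against a brute-force dense conditional-MVN oracle and against
`picante::phyEstimate` point estimates.

## Numerical choices

* Tip order is lexicographic wherever a matrix is built, for determinism.
* Covariance solves go through Cholesky; reference trees may contain
  zero-length branches that make `C` exactly singular, in which case (and
  only then) a `1e-10` ridge is added to the diagonal.
* Polytomies are accepted everywhere and never resolved; the statistics
  operate on `C` directly.
* Ties are broken by taxon/OTU label (uncertainty filter, increaser /
  decreaser grouping) so repeated runs agree exactly.
* LOOCV reuses one factorization of the full precision matrix via Schur
  complements; a test verifies fold-for-fold agreement with the direct
  per-fold computation.

## The synthetic experiment

`simulate_experiment()` emulates the study design the pipeline targets:
three soil types (harsh, lush, non) crossed with nutrient and
precipitation addition, 10 replicate plots per cell (120 plots). Defaults:

* A 200-tip Yule tree (birth rate 1), height-normalized to 1, with a
  50/50 reference/query split. Copy number is `exp(BM)` clamped to
  `[1, 15]` (root `log 2`, rate 0.35 on the unit-height tree), giving
  1–10 copies for most tips; genome size is Brownian around 4.2 Mbp
  (rate 1.2), truncated below at 0.5 Mbp — bracketing values reported
  for soil communities.
* Plot `p` has environment score
  `E_p = beta_N * nutrient + beta_P * precip + soil offset`
  (defaults `beta_N = +1`, `beta_P = -1` per SD of latent trait; soil
  offsets `-0.5, 0.2, 0.3`), and OTU `i`'s expected relative abundance is
  proportional to `exp(b_i + E_p * z_i)` with baseline
  `b_i ~ N(0, 1)` and `z_i` the standardized true copy number. This
  log-linear link is the minimal model that produces CWM shifts with a
  known expected magnitude and direction.
* Counts are multinomial at a negative-binomial depth (mean 30,000,
  size 30), so rarefaction to 26,690 reads drops some plots and the
  retention logic is exercised.
* "Phyla" are the `k = 10` most basal clades (classes and orders from
  cuts at `2k` and `4k`), creating the group-level analysis surface
  without a real taxonomy.
* Soil chemistry is generated with per-soil baselines and treatment
  responses (nutrient addition raises NH4-N, NO3-N, Olsen P and K;
  precipitation leaches NH4-N and raises moisture and pH), so the
  covariate-mediation screen has real structure to find.

The generator records ground truth: true traits for every tip, the
reference/query split, per-plot environment scores, and the
infinite-depth expected CWM per plot (the softmax-weighted mean of true
traits). What it does **not** emulate: PCR/primer bias, chimeras,
spatial autocorrelation among plots, non-Brownian trait evolution, or
relic DNA inertia. Passing tests therefore demonstrate correctness of
the computations under the stated model, not robustness to those
real-data complications.

## Treatment-response statistics

The factorial analysis is ordinary least squares with
`soil * nutrient * precipitation` plus the irrigation line as a fixed
block term, rather than a REML mixed model with a random line effect.
With lines crossed with treatments (as in the generator's design) the
fixed-block OLS tests the same contrasts at this scale while keeping the
inferential machinery transparent; this divergence is deliberate and
documented here. Term tests are Type II F-tests (`car::Anova`) — the
conventional choice for factorials with interactions — and pairwise soil
contrasts are estimated marginal means with Tukey adjustment
(`emmeans`). The covariate screen refits the model with each soil
property in turn and flags a covariate as a candidate mediator when it
renders a significant treatment (p <= 0.05) non-significant (p > 0.10);
covariates collinear with the design are reported as aliased instead.

The increaser/decreaser analysis pools plots across soils, keeps OTUs
with mean abundance above 1 (on the 26,690-read scale) in both control
and treatment groups, sorts by percent change in mean abundance, and
cuts the sorted list into `n` equal sequential groups (default 4;
earlier, more-decreasing groups take the extras when sizes do not
divide). Welch's t compares trait values of the top and bottom groups,
and the robustness sweep repeats this for 3–30 groups. The per-phylum
tests are corrected with the Benjamini–Yekutieli step-up rule, which
controls FDR under arbitrary dependence — appropriate because phylum
CWMs computed from the same compositional table are not independent.
Whether the presence filter should use the rarefied-averaged or raw
table is ambiguous in the field; this package fixes the
rarefied-averaged table. Per-sample (not global) renormalization after
copy-number adjustment is likewise fixed.

## Validation scale and what the checks show

The packaged calibration routines (also run by `scripts/acceptance.R`
and exercised in `tests/testthat/test-acceptance.R`) use sizes chosen to
give stable Monte-Carlo summaries while staying desk-sized: 200
Brownian simulations on 128-tip trees for K/lambda/D calibration (200
null simulations inside each D), 50 replicates of 256-tip LOOCV, 50
replicates of the full 120-plot pipeline at depth ~30,000, 1000
null-response replicates for the type-I error of the factorial model,
and 200 null communities for the sweep calibration. Under these
conditions the pipeline recovers the configured effect directions
essentially always, LOOCV r for strong-signal traits centers near 0.9
(and near 0 without signal), and the null calibrations sit at their
nominal levels; the exact numbers are recomputed, never stored, by the
acceptance script.

## Known limitations

* Branch-length units are absorbed into the estimated `sigma2`; trees
  built under different substitution models are comparable only through
  that rescaling.
* The conditional-model SEs understate total uncertainty because
  `mu_hat` and `sigma2_hat` are plugged in; CI widths are meant for
  ranking, not coverage.
* The discrete predictor assumes equal transition rates; strongly
  asymmetric binary traits would need a 2-parameter model.
* The equivalence of fixed-block OLS and the mixed model holds for
  balanced, crossed designs; with lines nested in treatments the random
  effect would matter and is out of scope here.
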