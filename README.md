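# phylotraits

Estimating ecologically informative microbial traits from phylogeny, and
testing how environmental change shifts them at the community level.

Soil amplicon surveys report *who* is there (16S rRNA OTUs), not *how*
those microbes live. Two traits are both ecologically meaningful and
phylogenetically conserved enough to be predicted from relatedness alone:
**rRNA gene copy number** (more copies → faster ramp-up of growth when
resources arrive) and **genome size** (larger genomes → broader metabolic
and environmental range). `phylotraits` is for microbial ecologists who
want to turn marker-gene community tables plus a reference phylogeny of
sequenced genomes into per-plot community-weighted mean (CWM) traits and
treatment-response statistics — and to validate every step against
synthetic data with known ground truth.

## What is in the box

* **Signal screening** — Blomberg's *K* (permutation test), ML Pagel's
  λ (likelihood-ratio test), and Fritz–Purvis *D* (dual simulation
  nulls) decide which traits are conserved enough to estimate.
* **Hidden-state prediction** — for a trait-unknown tip *q* with known
  tips *k*, the Brownian conditional mean

  x̂_q = μ̂ + C_qk C_kk⁻¹ (x_k − μ̂1),  Var = σ̂² (C_qq − C_qk C_kk⁻¹ C_kq)

  where C is the shared branch-length matrix, μ̂ the GLS mean and σ̂² the
  ML Brownian rate; discrete traits use a 2-state Markov model with
  Felsenstein pruning. Validation by leave-one-out and held-out test
  sets; a least-certain-20% CI-width filter for robustness checks.
* **Community stage** — organelle filtering, rarefaction without
  replacement with replicate averaging (depth 26,690 × 100 by default),
  copy-number correction of relative abundances, CWMs per plot and per
  phylum (Proteobacteria split by class, Actinobacteria by order).
* **Treatment response** — Type II factorial model
  (soil × nutrient × precipitation + block) with Tukey soil contrasts, a
  covariate-mediation screen over soil chemistry (plus derived
  extractable N:P and Ca:Mg ratios), Pearson soil-property correlations,
  increaser/decreaser quartile analysis with a 3–30-group robustness
  sweep, and Benjamini–Yekutieli FDR control for per-phylum tests.
* **Synthetic experiment generator** — Yule trees, Brownian traits, and
  a 3-soil × 2×2 factorial design whose OTU abundances respond to
  treatments through latent trait values, with exact ground truth.

## Worked example

```r
library(phylotraits)

cfg <- simulation_config(n_tips = 200, beta_nutrient = 1, beta_precip = -1,
                         depth_mean = 30000, seed = 42)
sim <- simulate_experiment(cfg)

# 1. screen the trait for signal on the reference tips
ref_tree <- ape::keep.tip(sim$tree, rownames(sim$traits))
x <- setNames(sim$traits$copy_number, rownames(sim$traits))
blomberg_k(ref_tree, x, n_perm = 999, seed = 1)
#> K = 0.8079
#>   p_vs_no_signal = 0.001
pagel_lambda(ref_tree, x)
#> lambda = 0.8801
#>   p_vs_no_signal = 1.753e-21

# 2. predict copy number for the 100 trait-unknown OTUs
est <- estimate_all(sim$tree, sim$traits, sim$ground_truth$query,
                    trait = "copy_number")
head(est, 3)
#>   taxon       trait estimate        se    ci_low  ci_high  ci_width
#> 1  t002 copy_number 1.002326 0.2968837 0.4204342 1.584218 1.1637841
#> 2  t005 copy_number 1.812861 0.1251566 1.5675542 2.058168 0.4906138
#> 3  t007 copy_number 3.382171 0.5877176 2.2302442 4.534097 2.3038532
cor(sim$ground_truth$traits[est$taxon, "copy_number"], est$estimate)
#> [1] 0.8794519

# 3. copy-number-correct abundances, compute CWMs, test the treatments
adj <- copy_number_adjust(sim$otu_table, est)
cwm <- community_weighted_mean(adj, est, trait = "copy_number")
fm <- factorial_model(cwm, sim$metadata)
fm$terms[fm$terms$term %in% c("soil", "nutrient", "precipitation"), ]
#>            term        F df df_resid             p
#> 1          soil 111089.3  2       99 1.296027e-166
#> 2      nutrient 562402.0  1       99 1.137375e-187
#> 3 precipitation 561872.8  1       99 1.191613e-187

# 4. do nutrient increasers carry more rRNA copies than decreasers?
rel <- sim$otu_table / rowSums(sim$otu_table)
increaser_decreaser(rel * 26690, sim$metadata, "nutrient", est)
#> nutrient: increasers 4.077 +/- 0.196 (n=25) vs decreasers 1.466 +/- 0.102 (n=25)
#>   Welch t(36.2) = 11.787, p = 6.024e-14 (4 groups, presence > 1)
```

Reading the output: K near 1 with p ≤ 0.001 and λ near 1 say the
simulated copy number is strongly conserved, so neighbors are
informative; r = 0.88 between estimated and true values confirms it.
The factorial model recovers the built-in effects — nutrient addition
(β_N = +1) raises CWM copy number, precipitation (β_P = −1) lowers it —
and OTUs that increase under nutrient addition carry significantly more
rRNA gene copies than those that decrease, matching the generator's
ground truth in both direction and significance.

## The analysis workflow

The `analysis/` scripts run the whole study on synthetic data, each a
thin narrative driver over the package functions, writing tables under
`results/` (bulky regenerable inputs go to `scratch/`):

```sh
Rscript analysis/01_simulate.R         # generate the factorial experiment
Rscript analysis/02_signal_screen.R    # K / lambda / D per candidate trait
Rscript analysis/03_estimate_traits.R  # tip prediction + LOOCV/holdout + 20% filter
Rscript analysis/04_community.R        # rarefy, adjust, CWMs per plot & phylum
Rscript analysis/05_response.R         # factorial models, screens, inc/dec, FDR
```

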