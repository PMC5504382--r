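#' Signal-statistic calibration under their own generating models
#'
#' Simulates Brownian traits on fresh Yule trees and computes the mean
#' Blomberg K and ML lambda (both should center near 1 under Brownian
#' motion with full signal), plus the mean Fritz-Purvis D under each of
#' its construction nulls (random labels: D near 1; thresholded Brownian:
#' D near 0).
#'
#' @param n_sims Replicates per statistic.
#' @param n_tips Tips per simulated tree.
#' @param n_null Null simulations inside each D evaluation.
#' @param prevalence Prevalence of the binary traits.
#' @param seed Integer seed.
#' @return List: mean_k, mean_lambda, mean_d_random, mean_d_brownian, and
#'   the per-replicate vectors.
#' @export
calibrate_signal <- function(n_sims = 200, n_tips = 128, n_null = 200,
                             prevalence = 0.3, seed = 1) {
  k <- lam <- d_r <- d_b <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    tr <- simulate_yule_tree(n_tips, 1, seed = seed + 7L * i)
    x <- simulate_bm_trait(tr, 0, 1, 1, seed = seed + 7L * i + 1L)
    k[i] <- blomberg_k(tr, x, n_perm = 0)$value
    lam[i] <- pagel_lambda(tr, x)$value
    br <- simulate_binary_trait(tr, prevalence, "random", seed = seed + 7L * i + 2L)
    bb <- simulate_binary_trait(tr, prevalence, "brownian_threshold",
                                seed = seed + 7L * i + 3L)
    d_r[i] <- fritz_purvis_d(tr, br, n_sim = n_null, seed = seed + 7L * i + 4L)$value
    d_b[i] <- fritz_purvis_d(tr, bb, n_sim = n_null, seed = seed + 7L * i + 5L)$value
  }
  list(mean_k = mean(k), mean_lambda = mean(lam),
       mean_d_random = mean(d_r), mean_d_brownian = mean(d_b),
       k = k, lambda = lam, d_random = d_r, d_brownian = d_b)
}

#' LOOCV accuracy under strong and absent phylogenetic signal
#'
#' For each replicate, simulates a Brownian trait on a fresh Yule tree and
#' records the leave-one-out Pearson r, once with full signal (lambda = 1)
#' and once with none (lambda = 0).
#'
#' @param n_reps Replicates.
#' @param n_tips Tips per tree.
#' @param seed Integer seed.
#' @return List: r_strong, r_none (vectors), frac_strong_ge_0.8,
#'   mean_r_strong, mean_r_none.
#' @export
calibrate_loocv <- function(n_reps = 50, n_tips = 256, seed = 1) {
  r_strong <- r_none <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    tr <- simulate_yule_tree(n_tips, 1, seed = seed + 3L * i)
    r_strong[i] <- loocv(tr, simulate_bm_trait(tr, 0, 1, 1, seed = seed + 3L * i + 1L))$r
    r_none[i] <- loocv(tr, simulate_bm_trait(tr, 0, 1, 0, seed = seed + 3L * i + 2L))$r
  }
  list(r_strong = r_strong, r_none = r_none,
       frac_strong_ge_0.8 = mean(r_strong >= 0.8),
       mean_r_strong = mean(r_strong), mean_r_none = mean(r_none))
}

#' End-to-end parameter recovery of the treatment effects
#'
#' Runs the full pipeline on replicate synthetic experiments — estimate
#' copy number for the trait-unknown OTUs, adjust abundances, compute
#' per-plot CWMs, fit the factorial model, and run the
#' increaser/decreaser comparison — and records whether each replicate
#' recovers the configured effect directions.
#'
#' @param n_reps Replicates.
#' @param config_args Named list of overrides passed to
#'   \code{\link{simulation_config}} (seed is set per replicate).
#' @param depth_scale Rarefaction-depth scale used for the presence filter
#'   in the increaser/decreaser analysis.
#' @param seed Integer seed.
#' @return Data.frame with one row per replicate: nutrient/precipitation
#'   coefficient signs and Type II p-values, increaser/decreaser t and p,
#'   and indicator columns \code{signs_ok} (both coefficient signs match
#'   the configured betas, both terms significant) and \code{incdec_ok}
#'   (increasers have higher copy number, p < 0.05).
#' @export
calibrate_recovery <- function(n_reps = 50, config_args = list(),
                               depth_scale = 26690, seed = 1) {
  out <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    args <- utils::modifyList(list(n_tips = 200, seed = seed + i), config_args)
    cfg <- do.call(simulation_config, args)
    sim <- simulate_experiment(cfg)
    est <- estimate_all(sim$tree, sim$traits, sim$ground_truth$query,
                        trait = "copy_number")
    adj <- copy_number_adjust(sim$otu_table, est)
    cwm <- community_weighted_mean(adj, est, trait = "copy_number")
    fm <- factorial_model(cwm, sim$metadata, soil_contrasts = FALSE)
    p <- stats::setNames(fm$terms$p, fm$terms$term)
    cf <- stats::coef(fm$fit)
    rel <- sim$otu_table / rowSums(sim$otu_table)
    idr <- increaser_decreaser(rel * depth_scale, sim$metadata, "nutrient", est)
    sign_n <- sign(cf[["nutrient1"]])
    sign_p <- sign(cf[["precipitation1"]])
    out[[i]] <- data.frame(
      sign_nutrient = sign_n, p_nutrient = p[["nutrient"]],
      sign_precip = sign_p, p_precip = p[["precipitation"]],
      incdec_t = idr$t, incdec_p = idr$p,
      incdec_direction = sign(idr$mean_increasers - idr$mean_decreasers),
      signs_ok = sign_n == sign(cfg$beta_nutrient) &
        sign_p == sign(cfg$beta_precip) &
        p[["nutrient"]] < 0.05 & p[["precipitation"]] < 0.05,
      incdec_ok = idr$mean_increasers > idr$mean_decreasers & idr$p < 0.05)
  }
  do.call(rbind, out)
}

#' Type-I error of the factorial model under a null response
#'
#' Draws pure-noise responses on the factorial design and records the
#' fraction of replicates in which each focal term is significant at
#' \code{alpha} — which should match \code{alpha}.
#'
#' @param n_reps Replicates.
#' @param reps_per_cell Plots per soil x treatment cell.
#' @param alpha Nominal level.
#' @param seed Integer seed.
#' @return List: rate_nutrient, rate_precipitation, p-value matrix.
#' @export
calibrate_type1 <- function(n_reps = 1000, reps_per_cell = 10, alpha = 0.05,
                            seed = 1) {
  design <- expand.grid(rep = seq_len(reps_per_cell), nutrient = 0:1,
                        precipitation = 0:1, soil = c("harsh", "lush", "non"),
                        stringsAsFactors = FALSE)
  ids <- sprintf("p%03d", seq_len(nrow(design)))
  md <- data.frame(soil = design$soil, nutrient = design$nutrient,
                   precipitation = design$precipitation,
                   line = sprintf("l%02d", design$rep), row.names = ids)
  pmat <- withr::with_seed(seed, {
    t(vapply(seq_len(n_reps), function(i) {
      y <- stats::setNames(stats::rnorm(nrow(md)), ids)
      fm <- factorial_model(y, md, soil_contrasts = FALSE)
      stats::setNames(fm$terms$p, fm$terms$term)[c("nutrient", "precipitation")]
    }, numeric(2)))
  })
  list(rate_nutrient = mean(pmat[, 1L] < alpha),
       rate_precipitation = mean(pmat[, 2L] < alpha),
       pvalues = pmat)
}

#' Null calibration of the increaser/decreaser robustness sweep
#'
#' Simulates null communities (no treatment effect, no soil offsets) and
#' measures, across the 3-30 group sweep, the overall fraction of Welch
#' p-values below 0.10 — which should be near 0.10 under the null.
#'
#' @param n_reps Replicates.
#' @param group_range Group counts to sweep.
#' @param depth_scale Presence-filter scale.
#' @param seed Integer seed.
#' @return List: p10_rate (overall fraction of p < 0.10), per_rep vector.
#' @export
calibrate_sweep_null <- function(n_reps = 200, group_range = 3:30,
                                 depth_scale = 26690, seed = 1) {
  per_rep <- numeric(n_reps)
  for (i in seq_len(n_reps)) {
    cfg <- simulation_config(n_tips = 200, reps_per_cell = 5,
                             beta_nutrient = 0, beta_precip = 0,
                             soil_offsets = c(0, 0, 0),
                             depth_mean = 5000, seed = seed + i)
    sim <- simulate_experiment(cfg)
    gt <- sim$ground_truth
    tq <- stats::setNames(gt$traits[gt$query, "copy_number"], gt$query)
    rel <- sim$otu_table / rowSums(sim$otu_table)
    sw <- robustness_sweep(rel * depth_scale, sim$metadata, "nutrient", tq,
                           group_range = group_range)
    per_rep[i] <- mean(sw$p < 0.10)
  }
  list(p10_rate = mean(per_rep), per_rep = per_rep)
}
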