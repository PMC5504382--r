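# Generate a CWM response directly from the factorial design, bypassing the
# community stage, for model-level tests.
sim_cwm <- function(beta_n = 0, beta_p = 0, soil_eff = c(0, 0, 0),
                    reps = 10, sd = 1, seed = 1) {
  withr::with_seed(seed, {
    design <- expand.grid(rep = seq_len(reps), nutrient = 0:1,
                          precipitation = 0:1,
                          soil = c("harsh", "lush", "non"),
                          stringsAsFactors = FALSE)
    ids <- sprintf("p%03d", seq_len(nrow(design)))
    md <- data.frame(soil = design$soil, nutrient = design$nutrient,
                     precipitation = design$precipitation,
                     line = sprintf("l%02d", design$rep), row.names = ids)
    y <- beta_n * design$nutrient + beta_p * design$precipitation +
      soil_eff[match(design$soil, c("harsh", "lush", "non"))] +
      rnorm(nrow(design), 0, sd)
    list(cwm = stats::setNames(y, ids), metadata = md)
  })
}

test_that("factorial model recovers known effects with Type II F-tests", {
  d <- sim_cwm(beta_n = 2, beta_p = -2, soil_eff = c(-1, 0, 1), sd = 0.5, seed = 3)
  fm <- factorial_model(d$cwm, d$metadata)
  terms <- stats::setNames(fm$terms$p, fm$terms$term)
  expect_lt(terms[["nutrient"]], 1e-6)
  expect_lt(terms[["precipitation"]], 1e-6)
  expect_lt(terms[["soil"]], 1e-6)
  expect_equal(unname(coef(fm$fit)["nutrient1"]), 2, tolerance = 0.5)
  expect_equal(nrow(fm$soil_contrasts), 3)
  expect_lt(fm$soil_contrasts$p[fm$soil_contrasts$contrast == "harsh - non"], 0.01)

  expect_error(factorial_model(stats::setNames(rep(1, nrow(d$metadata)),
                                               rownames(d$metadata)),
                               d$metadata), "constant")
  md_bad <- d$metadata[d$metadata$soil != "harsh" | d$metadata$nutrient != 1, ]
  expect_error(factorial_model(d$cwm[rownames(md_bad)], md_bad), "empty design cell")
})

test_that("Type II main-effect F equals classical balanced ANOVA", {
  for (s in 1:20) {
    d <- sim_cwm(beta_n = runif(1, -1, 1), beta_p = runif(1, -1, 1),
                 soil_eff = rnorm(3), reps = 4, seed = 100 + s)
    fm <- factorial_model(d$cwm, d$metadata, include_block = FALSE)
    av <- summary(stats::aov(response ~ soil * nutrient * precipitation,
                             data = phylotraits:::response_frame(d$cwm, d$metadata)))[[1]]
    for (term in c("soil", "nutrient", "precipitation")) {
      f_aov <- av[trimws(rownames(av)) == term, "F value"]
      f_mine <- fm$terms$F[fm$terms$term == term]
      expect_equal(f_mine, f_aov, tolerance = 1e-8)
    }
  }
})

test_that("nutrient effect estimate recovers the simulated shift", {
  hits <- 0
  for (s in 1:50) {
    d <- sim_cwm(beta_n = 0.1, reps = 10, sd = 0.02, seed = 200 + s)
    fm <- factorial_model(d$cwm, d$metadata)
    eff <- unname(coef(fm$fit)["nutrient1"])
    if (abs(eff - 0.1) <= 0.02) hits <- hits + 1
  }
  expect_gte(hits, 45)
})

test_that("covariate screen flags mediators and spares irrelevant covariates", {
  flag_med <- flag_null <- logical(25)
  for (s in 1:25) {
    d <- sim_cwm(reps = 10, sd = 1, seed = 300 + s)
    md <- d$metadata
    withr::with_seed(400 + s, {
      # full mediation: treatment -> covariate -> response
      med <- 2 * md$nutrient + rnorm(nrow(md), 0, 0.3)
      y <- stats::setNames(1.0 * med + rnorm(nrow(md), 0, 0.8), rownames(md))
      noise_cov <- rnorm(nrow(md))
    })
    md$mediator <- med
    md$noise <- noise_cov
    scr <- covariate_screen(y, md, c("mediator", "noise"))
    flag_med[s] <- scr$flagged[scr$covariate == "mediator" & scr$treatment == "nutrient"]
    flag_null[s] <- scr$flagged[scr$covariate == "noise" & scr$treatment == "nutrient"]
  }
  expect_gte(mean(flag_med), 0.8)
  expect_lte(mean(flag_null), 0.1)

  # a copy of the treatment indicator is reported aliased, with no p
  d <- sim_cwm(beta_n = 1, reps = 6, sd = 0.5, seed = 12)
  md <- d$metadata; md$copy_trt <- md$nutrient
  scr <- covariate_screen(d$cwm, md, "copy_trt")
  expect_true(all(scr$aliased))
  expect_true(all(is.na(scr$p_with)))
})

test_that("soil correlations match hand computation and handle degenerate input", {
  md <- data.frame(soil = "harsh", nutrient = 0, precipitation = 0, line = "l1",
                   prop = c(1, 2, 3), flat = c(1, 1, 1),
                   row.names = c("a", "b", "c"))
  y <- stats::setNames(c(2, 4, 5), c("a", "b", "c"))
  res <- suppressWarnings(soil_correlations(y, md, c("prop", "flat")))
  # r for pairs (1,2),(2,4),(3,5): 3 / sqrt(2 * 14/3) = 0.98198
  expect_equal(res$r[res$property == "prop"], 3 / sqrt(2 * 14 / 3),
               tolerance = 1e-8)
  expect_true(is.na(res$r[res$property == "flat"]))
  # perfect correlation
  res2 <- soil_correlations(y, transform(md, prop = c(2, 4, 5)), "prop")
  expect_equal(res2$r, 1, tolerance = 1e-12)
})

test_that("derived ratios follow the defining formulas and guard division", {
  md <- data.frame(soil = "x", nutrient = 0, precipitation = 0, line = "l",
                   NH4_N = c(2, 1), NO3_N = c(1, 1), olsen_P = c(3, 0),
                   Ca = c(10, 4), Mg = c(5, 2), row.names = c("a", "b"))
  out <- suppressWarnings(derive_ratios(md))
  expect_equal(out$ext_NP, c(1, NA_real_))
  expect_equal(out$ca_mg, c(2, 2))
  expect_error(derive_ratios(md[, -5]), "missing column")
})

test_that("increaser/decreaser grouping matches hand-sorted quantiles", {
  # 8 OTUs with hand-set changes: ctrl means 10, trt means chosen
  ctrl <- matrix(10, 4, 8, dimnames = list(sprintf("c%d", 1:4), sprintf("o%d", 1:8)))
  pct <- c(-80, -60, -40, -20, 20, 40, 60, 80)
  trt <- matrix(rep(10 * (1 + pct / 100), each = 4), 4, 8,
                dimnames = list(sprintf("t%d", 1:4), sprintf("o%d", 1:8)))
  tab <- rbind(ctrl, trt)
  md <- data.frame(soil = "x", nutrient = rep(c(0, 1), each = 4),
                   precipitation = 0, line = "l",
                   row.names = rownames(tab))
  traits <- stats::setNames(1:8, sprintf("o%d", 1:8))
  res <- increaser_decreaser(tab, md, "nutrient", traits, n_groups = 4)
  expect_equal(sort(res$classification$otu[res$classification$group == 1]),
               c("o1", "o2"))
  expect_equal(sort(res$classification$otu[res$classification$group == 4]),
               c("o7", "o8"))
  expect_equal(res$mean_increasers, 7.5)
  expect_equal(res$mean_decreasers, 1.5)
  # invariance to common rescaling of all abundances
  res2 <- increaser_decreaser(tab * 3, md, "nutrient", traits, n_groups = 4,
                              presence_threshold = 3)
  expect_equal(res2$classification, res$classification)

  # uneven split: earlier groups take the extra OTUs
  res3 <- increaser_decreaser(tab, md, "nutrient", traits, n_groups = 3)
  expect_equal(as.integer(table(res3$classification$group)), c(3L, 3L, 2L))
})

test_that("presence filter removes OTUs absent from either pooled group", {
  ctrl <- matrix(c(10, 10, 0.5, 10), 2, 2, byrow = TRUE,
                 dimnames = list(c("c1", "c2"), c("o1", "o2")))
  ctrl <- rbind(ctrl, matrix(c(10, 10, 10, 10), 2, 2,
                             dimnames = list(c("t1", "t2"), c("o1", "o2"))))
  md <- data.frame(soil = "x", nutrient = c(0, 0, 1, 1), precipitation = 0,
                   line = "l", row.names = rownames(ctrl))
  # o1 mean in control = 5.25 > 1, o2 = 10 > 1; with threshold 6, o1 fails
  expect_error(increaser_decreaser(ctrl, md, "nutrient",
                                   c(o1 = 1, o2 = 2), n_groups = 1,
                                   presence_threshold = 6), "too few")
})

test_that("Welch t matches hand values and separates distant groups", {
  wt <- welch_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(wt$t, -1.224745, tolerance = 1e-6)
  expect_equal(wt$df, 4, tolerance = 1e-6)
  expect_equal(wt$p, 0.2879, tolerance = 1e-3)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1, tolerance = 1e-12)
  far <- welch_t(c(1, 1.001, 0.999), c(1001, 1001.001, 1000.999))
  expect_lt(far$p, 1e-6)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
})

test_that("Benjamini-Yekutieli step-up matches hand thresholds", {
  res <- by_fdr(c(0.001, 0.02, 0.04), q = 0.05)
  expect_equal(res$reject, c(TRUE, FALSE, FALSE))
  expect_equal(res$threshold, c(1, 2, 3) * 0.05 / (3 * (11 / 6)), tolerance = 1e-12)
  expect_equal(res$p_adjusted[1], 0.001 * 3 * (11 / 6), tolerance = 1e-12)

  expect_equal(by_fdr(0.04, 0.05)$reject, TRUE)   # m = 1 reduces to p <= q
  expect_equal(by_fdr(0.06, 0.05)$reject, FALSE)
  all1 <- by_fdr(rep(1, 5), 0.05)
  expect_false(any(all1$reject))
  expect_equal(all1$p_adjusted, rep(1, 5))
})

test_that("BY rejections are a subset of BH rejections", {
  withr::with_seed(9, {
    for (i in 1:20) {
      p <- c(runif(15), runif(5, 0, 0.01))
      by <- by_fdr(p, 0.05)$reject
      bh <- stats::p.adjust(p, "BH") <= 0.05
      expect_true(all(!by | bh))
    }
  })
})

test_that("monotone adjusted p-values stay within [0, 1]", {
  p <- c(0.5, 0.001, 0.2, 0.9, 0.03)
  res <- by_fdr(p, 0.05)
  ord <- order(p)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  expect_true(all(res$p_adjusted >= 0 & res$p_adjusted <= 1))
})
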