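test_that("continuous prediction matches hand cases", {
  # query shares no history with A, B: estimate = phylogenetic mean
  tr <- toy_tree("((A:1,B:1):1,Q:2);")
  p <- predict_tip_continuous(tr, c(A = 0, B = 2), "Q")
  expect_equal(p$estimate, 1)
  expect_equal(p$ci_high - p$estimate, p$estimate - p$ci_low, tolerance = 1e-12)

  # query nested next to A: conditional mean 0.75 A + 0.25 B
  tr2 <- toy_tree("((A:1,Q:1):1,B:2);")
  expect_equal(predict_tip_continuous(tr2, c(A = 4, B = 0), "Q")$estimate, 3)

  # zero-length pendant at A's position copies A with zero SE
  tr3 <- toy_tree("(((A:0,Q:0):1,B:1):1,C:2);")
  p3 <- predict_tip_continuous(tr3, c(A = 1.7, B = 0, C = 5), "Q")
  expect_equal(p3$estimate, 1.7, tolerance = 1e-6)
  expect_lt(p3$se, 1e-4)

  expect_error(predict_tip_continuous(tr, c(A = 0, B = 2), "Z"), "not in tree")
})

test_that("continuous prediction equals the conditional-MVN oracle", {
  for (s in 1:100) {
    tr <- simulate_yule_tree(10, 1, seed = 2000 + s)
    x <- simulate_bm_trait(tr, 1, 1, 1, seed = 3000 + s)
    q <- sort(tr$tip.label)[1 + (s %% 10)]
    known <- x[setdiff(names(x), q)]
    mine <- predict_tip_continuous(tr, known, q)
    orac <- oracle_conditional(tr, known, q)
    expect_equal(mine$estimate, orac$mean, tolerance = 1e-8)
    expect_equal(mine$se^2, orac$var, tolerance = 1e-8)
  }
})

test_that("prediction respects affine equivariance and information bounds", {
  tr <- simulate_yule_tree(30, 1, seed = 71)
  x <- simulate_bm_trait(tr, 0, 2, 1, seed = 72)
  q <- sort(tr$tip.label)[5]
  known <- x[setdiff(names(x), q)]
  p1 <- predict_tip_continuous(tr, known, q)
  p2 <- predict_tip_continuous(tr, 3 * known - 2, q)
  expect_equal(p2$estimate, 3 * p1$estimate - 2, tolerance = 1e-8)
  expect_equal(p2$se, 3 * p1$se, tolerance = 1e-8)
  # conditional variance never exceeds the marginal variance
  res <- phylotraits:::conditional_predict(tr, known, q)
  C <- vcv_from_tree(tr)
  expect_lte(res$se[[q]]^2, res$sigma2 * C[q, q] + 1e-10)
})

test_that("estimate_all equals sequential single-query predictions", {
  tr <- simulate_yule_tree(60, 1, seed = 81)
  x <- simulate_bm_trait(tr, 0, 1, 1, seed = 82)
  queries <- sort(sample(names(x), 15))
  known <- x[setdiff(names(x), queries)]
  batch <- estimate_all(tr, known, queries)
  for (q in queries) {
    pruned <- ape::drop.tip(tr, setdiff(queries, q))
    single <- predict_tip_continuous(pruned, known, q)
    i <- match(q, batch$taxon)
    expect_equal(batch$estimate[i], single$estimate, tolerance = 1e-8)
    expect_equal(batch$se[i], single$se, tolerance = 1e-8)
  }
  expect_equal(batch$taxon, sort(batch$taxon))
  expect_equal(nrow(estimate_all(tr, known, character(0))), 0L)
  expect_error(estimate_all(tr, known, names(known)[1]), "overlap")
})

test_that("discrete prediction follows the pruning model", {
  # query on a near-zero pendant next to a known state-1 tip, long
  # branches elsewhere
  tr <- toy_tree("(((A:0.001,Q:0.001):2,B:2):2,(C:2,D:2):4);")
  known <- c(A = 1, B = 0, C = 0, D = 0)
  res <- predict_tip_discrete(tr, known, "Q")
  expect_equal(sum(res$prob), 1, tolerance = 1e-9)
  expect_gt(res$prob[["1"]], 0.9)
  expect_equal(res$state, "1")

  # symmetric cherry, one tip of each state equidistant from the query
  tr2 <- toy_tree("((A:1,B:1):1,Q:2);")
  res2 <- predict_tip_discrete(tr2, c(A = 0, B = 1), "Q")
  expect_equal(unname(res2$prob), c(0.5, 0.5), tolerance = 1e-9)

  # constant known states: non-identifiable, majority with probability 1
  res3 <- predict_tip_discrete(tr2, c(A = 1, B = 1), "Q")
  expect_true(res3$non_identifiable)
  expect_equal(res3$prob[["1"]], 1)
})

test_that("LOOCV agrees with per-fold prediction and tracks signal strength", {
  tr <- simulate_yule_tree(40, 1, seed = 91)
  x <- simulate_bm_trait(tr, 0, 1, 1, seed = 92)
  rep <- loocv(tr, x)
  expect_equal(rep$n, 40)
  # spot-check folds against the single-query path
  for (tx in rep$details$taxon[c(1, 17, 40)]) {
    single <- predict_tip_continuous(tr, x[setdiff(names(x), tx)], tx)
    i <- match(tx, rep$details$taxon)
    expect_equal(rep$details$estimate[i], single$estimate, tolerance = 1e-8)
    expect_equal(rep$details$se[i], single$se, tolerance = 1e-8)
  }
  expect_error(loocv(toy_tree("(A:1,B:1);"), c(A = 1, B = 2)), ">= 4")

  # mean LOOCV r increases with simulated lambda
  r_by_lambda <- vapply(c(0, 0.5, 1), function(l) {
    mean(vapply(1:10, function(s) {
      tree <- simulate_yule_tree(64, 1, seed = 4000 + s)
      loocv(tree, simulate_bm_trait(tree, 0, 1, l, seed = 5000 + 1000 * l + s))$r
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(r_by_lambda) > 0))
})

test_that("holdout validation reduces to LOOCV for one taxon and errors cleanly", {
  tr <- simulate_yule_tree(30, 1, seed = 101)
  x <- simulate_bm_trait(tr, 0, 1, 1, seed = 102)
  tx <- sort(names(x))[4]
  hv <- holdout_validation(tr, x, tx)
  lv <- loocv(tr, x)
  i <- match(tx, lv$details$taxon)
  expect_equal(hv$details$estimate, lv$details$estimate[i], tolerance = 1e-10)
  expect_error(holdout_validation(tr, x, character(0)), "empty")
  expect_error(holdout_validation(tr, x, "nope"), "subset")
})

test_that("clustered holdout is more conservative than LOOCV on average", {
  # joint holdout of a clade gives its members identical conditional means
  # (they share all paths to the training tips), so the test set mixes a
  # clade with scattered tips to keep r well defined
  diffs <- vapply(1:15, function(s) {
    tr <- simulate_yule_tree(80, 1, seed = 6000 + s)
    x <- simulate_bm_trait(tr, 0, 1, 1, seed = 7000 + s)
    sizes <- vapply((81:159), function(n) length(ape::extract.clade(tr, n)$tip.label),
                    numeric(1))
    node <- (81:159)[which.min(abs(sizes - 8))]
    clade <- ape::extract.clade(tr, node)$tip.label
    scattered <- withr::with_seed(8000 + s,
      sample(setdiff(tr$tip.label, clade), 10))
    loocv(tr, x)$r - holdout_validation(tr, x, c(clade, scattered))$r
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})

test_that("uncertainty filter drops the widest CIs with deterministic ties", {
  est <- data.frame(taxon = sprintf("t%02d", 1:10), trait = "x",
                    estimate = 1:10, se = (10:1) / 10,
                    ci_low = 0, ci_high = 0,
                    ci_width = 2 * 1.96 * (10:1) / 10,
                    stringsAsFactors = FALSE)
  kept <- filter_least_certain(est, 0.2)
  expect_equal(nrow(kept), 8)
  expect_false(any(c("t01", "t02") %in% kept$taxon))
  expect_identical(filter_least_certain(est, 0), est)

  ties <- est; ties$ci_width <- 1
  kept2 <- filter_least_certain(ties, 0.2)
  expect_equal(setdiff(ties$taxon, kept2$taxon), c("t01", "t02"))
  expect_error(filter_least_certain(est, 1), "fraction")
})

test_that("point estimates agree with picante's phyEstimate", {
  skip_if_not_installed("picante")
  tr <- simulate_yule_tree(25, 1, seed = 111)
  x <- simulate_bm_trait(tr, 5, 1, 1, seed = 112)
  queries <- sort(sample(names(x), 5))
  known <- x[setdiff(names(x), queries)]
  mine <- estimate_all(tr, known, queries)
  ref <- picante::phyEstimate(tr, data.frame(trait = known,
                                             row.names = names(known)))
  # SEs are not compared: picante propagates root-state uncertainty,
  # ours is the documented conditional-model SE
  expect_equal(mine$estimate, unname(ref[mine$taxon, "estimate"]),
               tolerance = 1e-6)
})
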