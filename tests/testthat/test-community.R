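make_table <- function(counts, samples = NULL, otus = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- otus %||% sprintf("otu%d", seq_len(ncol(m)))
  m
}

test_that("taxonomy filter removes organelle lineages case-insensitively", {
  tab <- make_table(rbind(c(5, 3, 2), c(1, 1, 1)))
  tax <- data.frame(domain = "Bacteria",
                    phylum = c("Cyanobacteria", "Proteobacteria", "Firmicutes"),
                    class = c("Chloroplast", "Alpha", "Bacilli"),
                    row.names = colnames(tab), stringsAsFactors = FALSE)
  out <- filter_taxa(tab, tax)
  expect_equal(colnames(out), c("otu2", "otu3"))
  expect_identical(filter_taxa(tab, tax, exclude = character(0)), tab)
  expect_error(filter_taxa(tab, tax, exclude = c("bacteria")), "all OTUs")
})

test_that("rarefaction replicates sum exactly to depth and average correctly", {
  tab <- make_table(rbind(c(500, 300, 200), c(50, 30, 20), c(10, 5, 5)))
  res <- rarefy_average(tab, depth = 100, n_reps = 20, seed = 1)
  expect_setequal(res$retained, c("s1", "s2"))
  expect_equal(res$dropped, "s3")
  expect_equal(unname(rowSums(res$table)), c(100, 100), tolerance = 1e-9)

  # exhaustive draw returns the sample unchanged
  res2 <- rarefy_average(make_table(rbind(c(5, 5))), depth = 10, n_reps = 5, seed = 1)
  expect_equal(unname(res2$table[1, ]), c(5, 5))

  # hypergeometric expectation: depth * p_i
  res3 <- rarefy_average(make_table(rbind(c(5, 5))), depth = 2, n_reps = 2000, seed = 2)
  expect_equal(unname(res3$table[1, ]), c(1, 1), tolerance = 0.05)

  expect_error(rarefy_average(make_table(rbind(c(1.5, 2))), 2), "integral")
  expect_error(rarefy_average(tab, depth = 1e6), "no sample")
})

test_that("copy-number adjustment renormalizes per sample", {
  tab <- make_table(rbind(c(10, 10), c(20, 80)))
  adj <- copy_number_adjust(tab, c(otu1 = 1, otu2 = 2))
  expect_equal(unname(adj[1, ]), c(2 / 3, 1 / 3), tolerance = 1e-12)
  adj2 <- copy_number_adjust(tab, c(otu1 = 1, otu2 = 4))
  expect_equal(unname(adj2[2, ]), c(0.5, 0.5), tolerance = 1e-12)
  # equal copies leave relative abundances unchanged
  adj3 <- copy_number_adjust(tab, c(otu1 = 3, otu2 = 3))
  expect_equal(adj3, tab / rowSums(tab), tolerance = 1e-12)
  expect_error(copy_number_adjust(tab, c(otu1 = 1)), "missing copy-number")
})

test_that("adjusting for copy number down-weights high-copy OTUs in CWM", {
  withr::with_seed(5, {
    for (i in 1:100) {
      n_otu <- sample(3:12, 1)
      tab <- make_table(matrix(rpois(3 * n_otu, 50) + 1, nrow = 3))
      cn <- stats::setNames(runif(n_otu, 1, 10), colnames(tab))
      raw_cwm <- community_weighted_mean(tab / rowSums(tab), cn)$cwm
      adj_cwm <- community_weighted_mean(copy_number_adjust(tab, cn), cn)$cwm
      expect_true(all(adj_cwm <= raw_cwm + 1e-9))
    }
  })
})

test_that("community-weighted mean matches hand arithmetic", {
  tab <- make_table(rbind(c(0.5, 0.5), c(0.9, 0.1), c(1, 0)))
  tr <- c(otu1 = 2, otu2 = 4)
  cwm <- community_weighted_mean(tab, tr)
  expect_equal(cwm$cwm, c(3, 2.2, 2))
  cwm2 <- community_weighted_mean(make_table(rbind(c(0.9, 0.1))), c(otu1 = 1, otu2 = 10))
  expect_equal(cwm2$cwm, 1.9)
  expect_error(community_weighted_mean(make_table(rbind(c(0, 0))), tr), "zero total")
  expect_error(community_weighted_mean(tab, c(otu1 = 2)), "missing trait")
})

test_that("group CWMs renormalize within groups and flag absent groups", {
  tab <- make_table(rbind(c(3, 1, 0), c(0, 0, 4)))
  tax <- data.frame(phylum = c("P1", "P1", "P2"),
                    class = "c", order = "o",
                    row.names = colnames(tab), stringsAsFactors = FALSE)
  tr <- c(otu1 = 1, otu2 = 5, otu3 = 9)
  g <- phylum_cwm(tab, tr, tax, split_rules = c())
  p1s1 <- g$cwm[g$group == "P1" & g$sample == "s1"]
  expect_equal(p1s1, (3 * 1 + 1 * 5) / 4)
  expect_true(is.na(g$cwm[g$group == "P1" & g$sample == "s2"]))
  # single group holding all abundance equals whole-community CWM
  whole <- community_weighted_mean(tab[1, , drop = FALSE], tr)$cwm
  both <- g[g$sample == "s1" & g$total_weight > 0, ]
  wts <- both$total_weight / sum(both$total_weight)
  expect_equal(sum(wts * both$cwm), whole, tolerance = 1e-9)
})

test_that("split rules regroup designated phyla at finer ranks", {
  tab <- make_table(rbind(c(2, 2, 4, 8)))
  tax <- data.frame(
    phylum = c("Proteobacteria", "Proteobacteria", "Actinobacteria", "Firmicutes"),
    class = c("Alphaproteobacteria", "Gammaproteobacteria", "Actinomycetia", "Bacilli"),
    order = c("Rhizobiales", "Pseudomonadales", "Actinomycetales", "Bacillales"),
    row.names = colnames(tab), stringsAsFactors = FALSE)
  rel <- phylum_relative_abundance(tab, tax)
  expect_setequal(rel$group,
                  c("Proteobacteria: Alphaproteobacteria",
                    "Proteobacteria: Gammaproteobacteria",
                    "Actinobacteria: Actinomycetales", "Firmicutes"))
  expect_equal(sum(rel$rel_abundance), 1, tolerance = 1e-9)
  expect_equal(rel$rel_abundance[rel$group == "Firmicutes"], 0.5)
})

test_that("group abundances sum to 1 per sample on simulated data", {
  sim <- simulate_experiment(simulation_config(n_tips = 80, reps_per_cell = 2,
                                               depth_mean = 2000, seed = 13))
  rel <- phylum_relative_abundance(sim$otu_table, sim$taxonomy, split_rules = c())
  sums <- tapply(rel$rel_abundance, rel$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("whole-community CWM is the abundance-weighted mean of group CWMs", {
  sim <- simulate_experiment(simulation_config(n_tips = 60, reps_per_cell = 2,
                                               depth_mean = 3000, seed = 19))
  gt <- sim$ground_truth
  tq <- stats::setNames(gt$traits[gt$query, "copy_number"], gt$query)
  rel <- sim$otu_table / rowSums(sim$otu_table)
  whole <- community_weighted_mean(rel, tq)
  grp <- phylum_cwm(rel, tq, sim$taxonomy, split_rules = c())
  for (s in rownames(rel)[c(1, 10, 24)]) {
    gs <- grp[grp$sample == s & !is.na(grp$cwm), ]
    expect_equal(sum(gs$total_weight / sum(gs$total_weight) * gs$cwm),
                 whole$cwm[whole$sample == s], tolerance = 1e-9)
  }
})
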