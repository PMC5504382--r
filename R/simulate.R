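#' Simulation configuration for the factorial community experiment
#'
#' Bundles and validates every knob of the synthetic experiment: a Yule
#' reference phylogeny, Brownian traits on it, a reference/query tip split,
#' and a 3-soil x 2x2 factorial plot design in which OTU abundances respond
#' to treatments through their latent trait values.
#'
#' Defaults emulate the study conditions the pipeline is built for: three
#' soil types (harsh, lush, non) x nutrient x precipitation with 10
#' replicate plots per cell (120 plots), sequencing depths drawn from a
#' negative binomial with mean 30,000 reads so that rarefaction to 26,690
#' drops some plots, and selection gradients acting on standardized
#' log-scale rRNA copy number.
#'
#' @param n_tips Number of tips on the reference tree (>= 2).
#' @param birth_rate Yule birth rate (> 0).
#' @param mu_log_copy,sigma2_log_copy Brownian root value and rate for
#'   log rRNA copy number (copy number = exp(BM) clamped to [1, 15]).
#' @param mu_genome,sigma2_genome Brownian root value (Mbp) and rate for
#'   genome size (truncated below at 0.5 Mbp).
#' @param lambda Phylogenetic signal of the simulated traits, in [0, 1].
#' @param query_fraction Fraction of tips marked trait-unknown (in (0, 1));
#'   must leave at least 2 reference tips.
#' @param n_soils Number of soil types (default 3: harsh, lush, non).
#' @param reps_per_cell Replicate plots per soil x treatment cell.
#' @param beta_nutrient,beta_precip Selection gradients (per SD of the
#'   latent trait) linking treatments to OTU fitness.
#' @param soil_offsets Numeric vector of per-soil environment offsets.
#' @param depth_mean,depth_size Negative-binomial mean and size for
#'   per-plot sequencing depth.
#' @param n_phyla Number of basal clades used as synthetic "phyla".
#' @param seed Integer seed (mandatory; the generator is fully reproducible).
#' @return A list of class \code{sim_config}.
#' @export
simulation_config <- function(n_tips = 200, birth_rate = 1,
                              mu_log_copy = log(2), sigma2_log_copy = 0.35,
                              mu_genome = 4.2, sigma2_genome = 1.2,
                              lambda = 1, query_fraction = 0.5,
                              n_soils = 3, reps_per_cell = 10,
                              beta_nutrient = 1, beta_precip = -1,
                              soil_offsets = c(harsh = -0.5, lush = 0.2, non = 0.3),
                              depth_mean = 30000, depth_size = 30,
                              n_phyla = 10, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  if (sigma2_log_copy <= 0 || sigma2_genome <= 0) stop("trait rates must be > 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  if (query_fraction <= 0 || query_fraction >= 1) stop("query_fraction must be in (0, 1)")
  if (n_tips - floor(query_fraction * n_tips) < 2)
    stop("query_fraction leaves fewer than 2 reference tips")
  if (depth_mean <= 0) stop("depth_mean must be > 0")
  if (reps_per_cell < 1) stop("empty design cell: reps_per_cell must be >= 1")
  if (length(soil_offsets) != n_soils) stop("soil_offsets must have one entry per soil")
  cfg <- list(n_tips = as.integer(n_tips), birth_rate = birth_rate,
              mu_log_copy = mu_log_copy, sigma2_log_copy = sigma2_log_copy,
              mu_genome = mu_genome, sigma2_genome = sigma2_genome,
              lambda = lambda, query_fraction = query_fraction,
              n_soils = as.integer(n_soils), reps_per_cell = as.integer(reps_per_cell),
              beta_nutrient = beta_nutrient, beta_precip = beta_precip,
              soil_offsets = soil_offsets, depth_mean = depth_mean,
              depth_size = depth_size, n_phyla = as.integer(n_phyla),
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a Yule (pure-birth) phylogeny
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Speciation rate (> 0).
#' @param seed Integer seed.
#' @return An ultrametric \code{phylo} with tips \code{t1..tn}.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  tree <- withr::with_seed(seed, ape::rphylo(n_tips, birth = birth_rate, death = 0))
  tree$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tree
}

#' Simulate a continuous trait under Brownian motion
#'
#' Draws tip values from a multivariate normal with mean \code{mu} and
#' covariance \code{sigma2 * C(lambda)}, where \code{C} is the shared
#' branch-length matrix of the tree and the lambda transform scales its
#' off-diagonal entries. \code{lambda = 1} is plain Brownian motion;
#' \code{lambda = 0} gives phylogenetically independent values.
#'
#' @param tree A \code{phylo} object.
#' @param mu Root (mean) value.
#' @param sigma2 Brownian rate (> 0), trait-units^2 per branch-length unit.
#' @param lambda Signal parameter in [0, 1].
#' @param seed Integer seed.
#' @param n Number of independent replicate traits to draw.
#' @return If \code{n = 1}, a named numeric vector (lexicographic tip
#'   order); otherwise a tips x n matrix.
#' @export
simulate_bm_trait <- function(tree, mu = 0, sigma2 = 1, lambda = 1, seed, n = 1) {
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  C <- lambda_transform(vcv_from_tree(tree), lambda)
  R <- chol_safe(sigma2 * C)
  z <- withr::with_seed(seed, matrix(stats::rnorm(nrow(C) * n), nrow(C), n))
  x <- mu + crossprod(R, z)
  rownames(x) <- rownames(C)
  if (n == 1L) stats::setNames(x[, 1L], rownames(C)) else x
}

#' Simulate a binary trait
#'
#' Two generators matching the two nulls of the Fritz-Purvis D statistic:
#' \code{brownian_threshold} simulates a Brownian trait and thresholds it at
#' the empirical quantile matching \code{prevalence} (maximal clumping
#' consistent with BM, the D = 0 null); \code{random} assigns exactly
#' \code{round(prevalence * n)} ones uniformly at random (the D = 1 null).
#'
#' @param tree A \code{phylo} object.
#' @param prevalence Target fraction of ones, in (0, 1).
#' @param mode \code{"brownian_threshold"} or \code{"random"}.
#' @param seed Integer seed.
#' @return Named 0/1 vector in lexicographic tip order.
#' @export
simulate_binary_trait <- function(tree, prevalence,
                                  mode = c("brownian_threshold", "random"), seed) {
  mode <- match.arg(mode)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  n <- length(tree$tip.label)
  n_ones <- max(1L, min(n - 1L, as.integer(round(prevalence * n))))
  if (mode == "random") {
    labs <- sort(tree$tip.label)
    ones <- withr::with_seed(seed, sample.int(n, n_ones))
    x <- stats::setNames(integer(n), labs)
    x[ones] <- 1L
    x
  } else {
    z <- simulate_bm_trait(tree, mu = 0, sigma2 = 1, lambda = 1, seed = seed)
    thr <- sort(z, decreasing = TRUE)[n_ones]
    stats::setNames(as.integer(z >= thr), names(z))
  }
}

# Assign each tip to one of the k most basal clades: cut the rooted tree
# just below its (k-1) earliest internal splits; the subtrees hanging from
# the cut edges are the groups.
cut_basal_clades <- function(tree, k) {
  n_tip <- length(tree$tip.label)
  if (k <= 1L || n_tip <= k) {
    if (k <= 1L) return(stats::setNames(rep(1L, n_tip), tree$tip.label))
  }
  k <- min(k, n_tip)
  nd <- ape::node.depth.edgelength(tree)        # distance from root, all nodes
  internal <- (n_tip + 1L):(n_tip + tree$Nnode)
  times <- sort(nd[internal])
  # slice between the (k-1)-th and k-th branching times
  t_lo <- times[k - 1L]
  t_hi <- if (k <= length(times)) times[k] else Inf
  slice <- if (is.finite(t_hi)) (t_lo + t_hi) / 2 else t_lo + 1e-9
  # edges crossing the slice define the groups
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  crossing <- which(nd[parent] <= slice & nd[child] > slice)
  # tips exactly at/below the slice with no crossing edge (short pendant): own group
  grp <- integer(n_tip)
  g <- 0L
  desc_tips <- function(node) {
    if (node <= n_tip) return(node)
    out <- integer(0); stack <- node
    while (length(stack)) {
      nodecur <- stack[[1L]]; stack <- stack[-1L]
      ch <- child[parent == nodecur]
      tipch <- ch[ch <= n_tip]
      out <- c(out, tipch)
      stack <- c(stack, ch[ch > n_tip])
    }
    out
  }
  for (e in crossing) {
    g <- g + 1L
    grp[desc_tips(child[e])] <- g
  }
  if (any(grp == 0L)) for (i in which(grp == 0L)) { g <- g + 1L; grp[i] <- g }
  stats::setNames(grp, tree$tip.label)
}

# Build a synthetic ranked taxonomy by cutting the tree at three depths:
# k phyla, 2k classes, 4k orders. Lineages are nested by construction.
synthetic_taxonomy <- function(tree, n_phyla) {
  phy <- cut_basal_clades(tree, n_phyla)
  cls <- cut_basal_clades(tree, 2L * n_phyla)
  ord <- cut_basal_clades(tree, 4L * n_phyla)
  data.frame(
    domain = "Bacteria",
    phylum = sprintf("Phylum%02d", phy),
    class  = sprintf("Class%02d", cls),
    order  = sprintf("Order%02d", ord),
    family = "unclassified",
    genus  = "unclassified",
    row.names = tree$tip.label, stringsAsFactors = FALSE)
}

#' Simulate the full factorial community experiment
#'
#' Generates every input of the downstream pipeline with known ground
#' truth. Per plot p the latent environment score is
#' \code{E_p = beta_N * nutrient_p + beta_P * precip_p + soil_offset}, and
#' OTU i's expected relative abundance is proportional to
#' \code{exp(b_i + E_p * z_i)}, where \code{b_i ~ Normal(0, 1)} is a
#' baseline log-abundance and \code{z_i} is the standardized true
#' (clamped) rRNA copy number. Counts are multinomial at the plot's
#' sequencing depth. A fraction of tips is marked trait-unknown (the
#' "experimental OTUs"); only those appear in the OTU table. Soil
#' chemistry covariates are generated with soil-type baselines plus
#' treatment responses (nutrient raises NH4-N, NO3-N, Olsen P and K;
#' precipitation leaches NH4-N and raises moisture and pH), giving the
#' covariate-mediation screen realistic structure.
#'
#' @param config A \code{\link{simulation_config}} object.
#' @return A list with elements \code{tree}, \code{traits} (reference
#'   tips only), \code{otu_table} (plots x OTUs counts), \code{metadata},
#'   \code{taxonomy}, and \code{ground_truth} (true traits for all tips,
#'   the reference/query split, per-plot environment scores and expected
#'   infinite-depth CWMs).
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  tree <- simulate_yule_tree(cfg$n_tips, cfg$birth_rate, seed = cfg$seed)
  # normalize tree height to 1 so trait rates are per total depth
  H <- max(ape::node.depth.edgelength(tree)[seq_len(cfg$n_tips)])
  tree$edge.length <- tree$edge.length / H

  log_copy <- simulate_bm_trait(tree, cfg$mu_log_copy, cfg$sigma2_log_copy,
                                cfg$lambda, seed = cfg$seed + 1L)
  copy_number <- pmin(pmax(exp(log_copy), 1), 15)
  genome_size <- pmax(simulate_bm_trait(tree, cfg$mu_genome, cfg$sigma2_genome,
                                        cfg$lambda, seed = cfg$seed + 2L), 0.5)
  tips <- sort(tree$tip.label)

  soils <- c("harsh", "lush", "non")[seq_len(cfg$n_soils)]
  design <- expand.grid(rep = seq_len(cfg$reps_per_cell),
                        nutrient = 0:1, precipitation = 0:1,
                        soil = soils, stringsAsFactors = FALSE)
  design <- design[order(design$soil, design$nutrient, design$precipitation, design$rep), ]
  n_plot <- nrow(design)
  plot_ids <- sprintf("plot%03d", seq_len(n_plot))

  offsets <- cfg$soil_offsets
  names(offsets) <- soils
  env <- cfg$beta_nutrient * design$nutrient +
    cfg$beta_precip * design$precipitation + offsets[design$soil]

  out <- withr::with_seed(cfg$seed + 3L, {
    n_query <- as.integer(floor(cfg$query_fraction * cfg$n_tips))
    query <- sort(sample(tips, n_query))
    reference <- setdiff(tips, query)
    b <- stats::rnorm(n_query)                       # baseline log-abundance
    zt <- copy_number[query]                         # standardized latent trait
    z <- if (stats::sd(zt) > 0) as.vector((zt - mean(zt)) / stats::sd(zt)) else rep(0, n_query)
    eta <- outer(env, z) + matrix(b, n_plot, n_query, byrow = TRUE)
    prob <- exp(eta - apply(eta, 1L, max))
    prob <- prob / rowSums(prob)
    depth <- stats::rnbinom(n_plot, mu = cfg$depth_mean, size = cfg$depth_size)
    depth <- pmax(depth, 1L)
    counts <- t(vapply(seq_len(n_plot),
                       function(p) as.numeric(stats::rmultinom(1L, depth[p], prob[p, ])),
                       numeric(n_query)))
    dimnames(counts) <- list(plot_ids, query)
    chem <- simulate_soil_chemistry(design)
    list(query = query, reference = reference, prob = prob,
         depth = depth, counts = counts, chem = chem)
  })

  metadata <- data.frame(soil = design$soil, nutrient = design$nutrient,
                         precipitation = design$precipitation,
                         line = sprintf("line%02d", design$rep),
                         out$chem, row.names = plot_ids, stringsAsFactors = FALSE)

  expected_cwm <- data.frame(
    copy_number = as.vector(out$prob %*% copy_number[out$query]),
    genome_size = as.vector(out$prob %*% genome_size[out$query]),
    row.names = plot_ids)

  traits_all <- data.frame(copy_number = copy_number[tips],
                           genome_size = genome_size[tips],
                           row.names = tips)
  list(
    tree = tree,
    traits = traits_all[out$reference, , drop = FALSE],
    otu_table = out$counts,
    metadata = metadata,
    taxonomy = synthetic_taxonomy(tree, cfg$n_phyla)[out$query, , drop = FALSE],
    ground_truth = list(traits = traits_all,
                        reference = out$reference, query = out$query,
                        environment = stats::setNames(as.vector(env), plot_ids),
                        expected_rel_abundance = out$prob,
                        depth = stats::setNames(out$depth, plot_ids),
                        expected_cwm = expected_cwm))
}

# Soil chemistry with per-soil baselines and treatment responses, log-normal
# noise. Units follow routine soil reports (mg/kg for extractables, % for
# organic matter and moisture, meq/100g for CEC).
simulate_soil_chemistry <- function(design) {
  n <- nrow(design)
  base <- list(
    harsh = c(pH = 6.9, organic_matter = 2.0, NH4_N = 2.5, NO3_N = 1.5,
              olsen_P = 4, K = 90, Mg = 900, Ca = 450, Na = 15,
              CEC = 18, DOC = 40, moisture = 8),
    lush = c(pH = 6.5, organic_matter = 4.5, NH4_N = 4.0, NO3_N = 3.0,
             olsen_P = 8, K = 160, Mg = 850, Ca = 500, Na = 18,
             CEC = 25, DOC = 70, moisture = 14),
    non = c(pH = 6.2, organic_matter = 5.0, NH4_N = 4.5, NO3_N = 3.5,
            olsen_P = 12, K = 200, Mg = 300, Ca = 1400, Na = 20,
            CEC = 27, DOC = 80, moisture = 13))
  vars <- names(base[[1L]])
  chem <- t(vapply(design$soil, function(s) base[[s]], numeric(length(vars))))
  colnames(chem) <- vars
  # treatment effects: nutrient addition raises extractable nutrients,
  # precipitation leaches NH4-N and wets/limes the soil slightly
  mult <- matrix(1, n, length(vars), dimnames = list(NULL, vars))
  mult[, "NH4_N"] <- (1 + 1.2 * design$nutrient) * (1 - 0.35 * design$precipitation)
  mult[, "NO3_N"] <- (1 + 1.0 * design$nutrient) * (1 - 0.20 * design$precipitation)
  mult[, "olsen_P"] <- 1 + 0.8 * design$nutrient
  mult[, "K"] <- 1 + 0.4 * design$nutrient
  mult[, "moisture"] <- 1 + 0.5 * design$precipitation
  chem <- chem * mult
  chem[, "pH"] <- chem[, "pH"] + 0.15 * design$precipitation
  noise <- matrix(stats::rnorm(n * length(vars), 0, 0.08), n, length(vars))
  noise[, colnames(chem) == "pH"] <- stats::rnorm(n, 0, 0.05)
  out <- chem * exp(noise)
  out[, "pH"] <- chem[, "pH"] + noise[, which(vars == "pH")]
  as.data.frame(out)
}

#' Write simulated experiment inputs to a directory
#'
#' Serializes a \code{\link{simulate_experiment}} result in the formats the
#' readers consume: newick tree plus TSV trait, OTU, metadata and taxonomy
#' tables.
#'
#' @param sim Result of \code{\link{simulate_experiment}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_table(sim$traits, file.path(dir, "traits.tsv"), id_name = "taxon")
  write_table(sim$otu_table, file.path(dir, "otu_table.tsv"), id_name = "sample")
  write_table(sim$metadata, file.path(dir, "metadata.tsv"), id_name = "sample")
  write_table(sim$taxonomy, file.path(dir, "taxonomy.tsv"), id_name = "otu")
  invisible(dir)
}
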