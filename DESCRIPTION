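Package: phylotraits
Title: Phylogenetic Trait Estimation and Community-Weighted Mean Analysis
    for Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates phylogenetically conserved microbial traits (rRNA
    gene copy number, genome size) for trait-unknown taxa from their
    position on a reference phylogeny under a Brownian-motion model,
    screens candidate traits for phylogenetic signal (Blomberg's K,
    Pagel's lambda, Fritz-Purvis D), corrects OTU relative abundances
    for rRNA gene copy number, computes community-weighted mean traits
    per plot and per phylum, and quantifies responses to factorial
    nutrient and precipitation treatments (Type II factorial models,
    covariate mediation screen, soil-property correlations,
    increaser/decreaser quantile analysis, Benjamini-Yekutieli FDR).
    Includes a synthetic-data generator that simulates Yule phylogenies,
    Brownian traits, and factorial-design communities with known ground
    truth so the full pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    vegan,
    car,
    emmeans,
    withr
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
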