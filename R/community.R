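#' Remove OTUs by taxonomy label
#'
#' Drops every OTU whose lineage contains (case-insensitively) any of the
#' excluded labels at any rank. The default exclusion set removes organelle
#' sequences (chloroplasts, mitochondria) that amplify with 16S primers
#' but are not community members.
#'
#' @param table Samples x OTUs numeric matrix.
#' @param taxonomy Data.frame of ranked lineages with OTU rownames.
#' @param exclude Character vector of labels to exclude.
#' @return Filtered table.
#' @export
filter_taxa <- function(table, taxonomy,
                        exclude = c("chloroplast", "mitochondria")) {
  if (!length(exclude)) return(table)
  otus <- colnames(table)
  miss <- setdiff(otus, rownames(taxonomy))
  if (length(miss)) stop("OTUs missing from taxonomy: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  lin <- apply(taxonomy[otus, , drop = FALSE], 1L,
               function(r) paste(tolower(r), collapse = ";"))
  hit <- Reduce(`|`, lapply(tolower(exclude), function(e) grepl(e, lin, fixed = TRUE)))
  keep <- otus[!hit]
  if (!length(keep)) stop("filtering removed all OTUs")
  table[, keep, drop = FALSE]
}

#' Rarefy an OTU count table with replicate averaging
#'
#' Each retained sample is subsampled to \code{depth} reads without
#' replacement (multivariate hypergeometric draw) \code{n_reps} times and
#' the replicate tables are averaged, so the output is real-valued with
#' row sums equal to \code{depth}. Samples whose total is below
#' \code{depth} are dropped and reported. Defaults follow the pipeline's
#' standard configuration: depth 26,690, 100 replicates.
#'
#' @param table Samples x OTUs matrix of integral counts.
#' @param depth Target depth (>= 1).
#' @param n_reps Number of rarefaction replicates to average.
#' @param seed Integer seed.
#' @return List with \code{table} (averaged, real-valued), \code{retained}
#'   and \code{dropped} sample IDs.
#' @export
rarefy_average <- function(table, depth = 26690, n_reps = 100, seed = 1) {
  if (depth < 1) stop("depth must be >= 1")
  if (max(abs(table - round(table))) > 1e-9)
    stop("counts must be integral for rarefaction")
  totals <- rowSums(table)
  retained <- rownames(table)[totals >= depth]
  dropped <- setdiff(rownames(table), retained)
  if (!length(retained)) stop("no sample reaches the rarefaction depth")
  sub <- round(table[retained, , drop = FALSE])
  acc <- matrix(0, nrow(sub), ncol(sub), dimnames = dimnames(sub))
  withr::with_seed(seed, {
    for (r in seq_len(n_reps)) {
      # preconditions (integral counts, totals >= depth) are validated
      # above; rrarefy's count-heuristic warning is spurious here
      rep_tab <- suppressWarnings(vegan::rrarefy(sub, depth))
      stopifnot(all(rowSums(rep_tab) == depth))
      acc <- acc + rep_tab
    }
  })
  list(table = acc / n_reps, retained = retained, dropped = dropped)
}

#' Adjust OTU relative abundances for rRNA gene copy number
#'
#' Read counts over-represent taxa with many rRNA operon copies. Dividing
#' each OTU's abundance by its (estimated) copy number and renormalizing
#' per sample converts read proportions into approximate cell proportions:
#' a'_ij = (a_ij / c_i) / sum_k (a_kj / c_k).
#'
#' @param table Samples x OTUs matrix (counts or relative abundances).
#' @param copies Copy-number estimates: named numeric vector, or a
#'   data.frame from \code{\link{estimate_all}} (taxon/estimate columns).
#' @return Samples x OTUs matrix of adjusted relative abundances (rows sum
#'   to 1).
#' @export
copy_number_adjust <- function(table, copies) {
  if (is.data.frame(copies)) copies <- stats::setNames(copies$estimate, copies$taxon)
  miss <- setdiff(colnames(table), names(copies))
  if (length(miss)) stop("missing copy-number estimate for OTU(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  cn <- copies[colnames(table)]
  if (any(cn < 1)) stop("copy-number estimates must be >= 1")
  rel <- table / rowSums(table)
  adj <- sweep(rel, 2L, cn, `/`)
  adj / rowSums(adj)
}

#' Community-weighted mean trait per sample
#'
#' CWM_j = sum_i p_ij t_i / sum_i p_ij over the OTUs of sample j. Every
#' OTU with non-zero abundance must have a trait value.
#'
#' @param table Samples x OTUs abundance matrix (relative or counts).
#' @param traits Per-OTU trait values: named vector or estimate data.frame.
#' @param trait Trait name recorded in the output.
#' @return Data.frame: sample, trait, cwm, total_weight.
#' @export
community_weighted_mean <- function(table, traits, trait = "trait") {
  if (is.data.frame(traits)) traits <- stats::setNames(traits$estimate, traits$taxon)
  active <- colnames(table)[colSums(table) > 0]
  miss <- setdiff(active, names(traits))
  if (length(miss)) stop("missing trait value for OTU(s) with non-zero abundance: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tv <- traits[colnames(table)]
  tv[is.na(tv)] <- 0      # zero-abundance OTUs only; they get zero weight
  w <- rowSums(table)
  if (any(w <= 0)) stop("sample(s) with zero total abundance: ",
                        paste(utils::head(rownames(table)[w <= 0], 5), collapse = ", "))
  data.frame(sample = rownames(table), trait = trait,
             cwm = as.vector(table %*% tv) / w, total_weight = w,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Resolve each OTU to its analysis group: phylum by default, with rank
# overrides for named phyla (e.g. Proteobacteria by class, Actinobacteria
# by order). Unclassified lineages keep an explicit label so abundance is
# conserved.
taxon_groups <- function(taxonomy, otus,
                         split_rules = c(Proteobacteria = "class",
                                         Actinobacteria = "order")) {
  miss <- setdiff(otus, rownames(taxonomy))
  if (length(miss)) stop("OTUs missing from taxonomy: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  tx <- taxonomy[otus, , drop = FALSE]
  phylum <- as.character(tx[["phylum"]])
  phylum[is.na(phylum) | phylum == ""] <- "unclassified_phylum"
  grp <- phylum
  for (ph in names(split_rules)) {
    rank <- split_rules[[ph]]
    if (!rank %in% colnames(tx)) stop("rank not in taxonomy: ", rank)
    sel <- phylum == ph
    if (!any(sel)) next
    sub <- as.character(tx[[rank]])[sel]
    sub[is.na(sub) | sub == "" | sub == "unclassified"] <-
      paste0("unclassified_", rank)
    grp[sel] <- paste(ph, sub, sep = ": ")
  }
  stats::setNames(grp, otus)
}

#' Community-weighted mean trait per taxonomic group per sample
#'
#' CWMs computed within each phylum (or finer group for phyla named in
#' \code{split_rules}) using abundances renormalized within the group.
#' Groups absent from a sample yield an NA record rather than zero.
#'
#' @param table Samples x OTUs abundance matrix.
#' @param traits Per-OTU trait values (named vector or estimate data.frame).
#' @param taxonomy Lineage data.frame with OTU rownames.
#' @param split_rules Named character vector: phylum -> rank override.
#' @param trait Trait name recorded in the output.
#' @return Data.frame: sample, group, trait, cwm (NA if absent),
#'   total_weight.
#' @export
phylum_cwm <- function(table, traits, taxonomy,
                       split_rules = c(Proteobacteria = "class",
                                       Actinobacteria = "order"),
                       trait = "trait") {
  if (is.data.frame(traits)) traits <- stats::setNames(traits$estimate, traits$taxon)
  grp <- taxon_groups(taxonomy, colnames(table), split_rules)
  out <- lapply(sort(unique(grp)), function(g) {
    sub <- table[, grp == g, drop = FALSE]
    w <- rowSums(sub)
    present <- w > 0
    cwm <- rep(NA_real_, nrow(table))
    if (any(present)) {
      subp <- sub[present, , drop = FALSE]
      cwm[present] <- community_weighted_mean(subp, traits, trait)$cwm
    }
    data.frame(sample = rownames(table), group = g, trait = trait,
               cwm = cwm, total_weight = w,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Per-sample relative abundance of each taxonomic group
#'
#' @inheritParams phylum_cwm
#' @return Data.frame: sample, group, rel_abundance (sums to 1 per sample).
#' @export
phylum_relative_abundance <- function(table, taxonomy,
                                      split_rules = c(Proteobacteria = "class",
                                                      Actinobacteria = "order")) {
  grp <- taxon_groups(taxonomy, colnames(table), split_rules)
  rel <- table / rowSums(table)
  groups <- sort(unique(grp))
  agg <- vapply(groups, function(g) rowSums(rel[, grp == g, drop = FALSE]),
                numeric(nrow(table)))
  if (nrow(table) == 1L) agg <- matrix(agg, nrow = 1L, dimnames = list(rownames(table), groups))
  data.frame(sample = rep(rownames(table), times = length(groups)),
             group = rep(groups, each = nrow(table)),
             rel_abundance = as.vector(agg),
             stringsAsFactors = FALSE, row.names = NULL)
}
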