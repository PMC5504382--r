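#' Read a rooted phylogeny from a newick file
#'
#' Parses a single newick tree and validates it for downstream use: every
#' tip label must be unique, every edge must carry a non-negative branch
#' length. Branch lengths are required because they define the Brownian
#' covariance structure; a tree without them is rejected rather than
#' defaulted.
#'
#' @param path Path to a file containing one newick tree.
#' @return An object of class \code{phylo} (see \pkg{ape}).
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("newick file not found: ", path)
  tree <- tryCatch(ape::read.tree(path),
                   error = function(e) stop("malformed newick: ", conditionMessage(e)))
  if (is.null(tree)) stop("malformed newick: no tree could be parsed from ", path)
  if (inherits(tree, "multiPhylo")) {
    if (length(tree) != 1L) stop("expected exactly one tree, found ", length(tree))
    tree <- tree[[1L]]
  }
  validate_phylogeny(tree)
  tree
}

#' Write a phylogeny to a newick file
#'
#' @param tree A \code{phylo} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_phylogeny(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Validate a phylogeny for trait analysis
#'
#' Checks the invariants every downstream computation relies on: unique tip
#' labels, branch lengths present and non-negative. Polytomies are allowed.
#'
#' @param tree A \code{phylo} object.
#' @return \code{tree}, invisibly.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths (required, not defaulted)")
  if (anyNA(tree$edge.length)) stop("tree has missing branch lengths")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) stop("duplicate tip label(s): ", paste(unique(dup), collapse = ", "))
  invisible(tree)
}

#' Phylogenetic variance-covariance matrix
#'
#' Builds the matrix C with C[i, j] equal to the shared root-to-MRCA path
#' length of tips i and j (the Brownian trait covariance up to the rate
#' sigma^2). Rows and columns are ordered lexicographically by tip label so
#' that every matrix built from the same tree is identical regardless of the
#' tree's internal edge ordering.
#'
#' @param tree A \code{phylo} object with non-negative branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
vcv_from_tree <- function(tree) {
  validate_phylogeny(tree)
  C <- ape::vcv.phylo(tree)
  ord <- order(rownames(C))
  C[ord, ord, drop = FALSE]
}

#' Pagel's lambda transform of a covariance matrix
#'
#' Multiplies the off-diagonal entries of C by lambda, leaving the diagonal
#' (tip variances) untouched.
#'
#' @param C Phylogenetic covariance matrix.
#' @param lambda Scalar in [0, 1].
#' @return Transformed matrix.
#' @export
lambda_transform <- function(C, lambda) {
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

# Cholesky with a ridge fallback: reference trees contain zero-length
# branches that make C exactly singular; a tiny diagonal ridge is added
# only when plain factorization fails.
chol_safe <- function(C, ridge = 1e-10) {
  R <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(R)) R <- chol(C + diag(ridge, nrow(C)))
  R
}

# Solve C x = b through the (possibly ridge-regularized) Cholesky factor.
solve_c <- function(C, b, ridge = 1e-10) {
  R <- chol_safe(C, ridge)
  backsolve(R, forwardsolve(t(R), b))
}

#' Read a tab-delimited data table
#'
#' Reads one of the four pipeline tables from TSV (tab-delimited, header
#' row, first column = ID, "NA" for missing) and validates it:
#' \describe{
#'   \item{otu}{samples x OTUs, non-negative numeric counts or relative
#'     abundances; returned as a numeric matrix with sample rownames.}
#'   \item{trait}{taxon x trait values; continuous traits finite,
#'     \code{copy_number} (if present) >= 1; returned as a data.frame with
#'     taxon rownames.}
#'   \item{metadata}{sample metadata; must contain \code{soil},
#'     \code{nutrient}, \code{precipitation}, and \code{line} columns;
#'     returned as a data.frame with sample rownames.}
#'   \item{taxonomy}{OTU lineage table; returned as a character data.frame
#'     with OTU rownames.}
#' }
#'
#' @param path Path to a TSV file.
#' @param kind One of \code{"otu"}, \code{"trait"}, \code{"metadata"},
#'   \code{"taxonomy"}.
#' @return See Details.
#' @export
read_table <- function(path, kind = c("otu", "trait", "metadata", "taxonomy")) {
  kind <- match.arg(kind)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = "NA")
  if (ncol(df) < 2L) stop("table needs an ID column plus at least one data column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate IDs in first column of ", path)
  body <- df[, -1L, drop = FALSE]
  rownames(body) <- ids
  switch(kind,
    otu = {
      m <- as.matrix(body)
      if (!is.numeric(m)) stop("non-numeric entries in OTU table")
      if (anyNA(m)) stop("missing values in OTU table")
      if (any(m < 0)) stop("negative entries in OTU table")
      m
    },
    trait = {
      for (cn in colnames(body)) {
        v <- body[[cn]]
        if (is.numeric(v) && any(!is.finite(v[!is.na(v)])))
          stop("non-finite values in trait column ", cn)
      }
      if ("copy_number" %in% colnames(body)) {
        cnv <- body$copy_number
        if (any(cnv[!is.na(cnv)] < 1)) stop("copy_number must be >= 1")
      }
      body
    },
    metadata = {
      required <- c("soil", "nutrient", "precipitation", "line")
      missing_cols <- setdiff(required, colnames(body))
      if (length(missing_cols))
        stop("metadata missing required column(s): ",
             paste(missing_cols, collapse = ", "))
      num <- vapply(body, is.numeric, logical(1))
      for (cn in colnames(body)[num]) {
        v <- body[[cn]]
        if (any(!is.finite(v[!is.na(v)]))) stop("non-finite values in metadata column ", cn)
      }
      body
    },
    taxonomy = {
      body[] <- lapply(body, as.character)
      body
    })
}

#' Write a data table as TSV
#'
#' Inverse of \code{\link{read_table}}: writes rownames as the first column.
#'
#' @param x Matrix or data.frame with IDs as rownames.
#' @param path Output path.
#' @param id_name Header for the ID column.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(x, path, id_name = "id") {
  df <- data.frame(rownames(x), as.data.frame(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_name
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
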