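#' Predict a continuous trait for one trait-unknown tip
#'
#' Brownian-motion hidden-state prediction: with tips partitioned into
#' known (k) and the query (q), the trait is multivariate normal with GLS
#' mean \eqn{\hat\mu = 1'C_{kk}^{-1} x_k / 1'C_{kk}^{-1} 1} and rate
#' \eqn{\hat\sigma^2} estimated by ML on the known tips. The estimate is
#' the conditional mean
#' \deqn{\hat x_q = \hat\mu + C_{qk} C_{kk}^{-1} (x_k - \hat\mu 1)}
#' with conditional variance
#' \eqn{\hat\sigma^2 (C_{qq} - C_{qk} C_{kk}^{-1} C_{kq})} and a
#' normal-theory 95\% CI (1.96 multiplier). Uncertainty in \eqn{\hat\mu}
#' is not propagated; CI widths are interpretable as conditional-model
#' uncertainty only.
#'
#' @param tree A \code{phylo} containing the query and all known tips.
#'   Tips other than the query and the known set must not be present (prune
#'   other queries first; \code{\link{estimate_all}} does this for you).
#' @param known Data.frame of trait values with taxon rownames, or a named
#'   numeric vector.
#' @param query Tip label to predict.
#' @param trait Trait (column) name when \code{known} is a data.frame.
#' @return A one-row data.frame: taxon, trait, estimate, se, ci_low,
#'   ci_high, ci_width.
#' @export
predict_tip_continuous <- function(tree, known, query, trait = NULL) {
  xk <- trait_vector(known, trait)
  if (!query %in% tree$tip.label) stop("query tip not in tree: ", query)
  known_tips <- setdiff(tree$tip.label, query)
  miss <- setdiff(known_tips, names(xk))
  if (length(miss)) stop("non-query tips lack trait values: ",
                         paste(utils::head(miss, 5), collapse = ", "))
  if (length(known_tips) < 2) stop("need >= 2 known tips")
  res <- conditional_predict(tree, xk[known_tips], query)
  data.frame(taxon = query, trait = if (is.null(trait)) NA_character_ else trait,
             estimate = res$mean, se = res$se,
             ci_low = res$mean - 1.96 * res$se,
             ci_high = res$mean + 1.96 * res$se,
             ci_width = 2 * 1.96 * res$se,
             stringsAsFactors = FALSE, row.names = NULL)
}

# Shared conditional-MVN machinery: predict one or more query tips jointly
# conditioned on the known tips only. Because covariances between retained
# tips are unchanged by pruning, predicting each query with all other
# queries pruned is identical to reading the relevant blocks off the full
# covariance matrix; this lets all queries share one factorization.
conditional_predict <- function(tree, xk, queries) {
  C <- vcv_from_tree(tree)
  k <- intersect(rownames(C), names(xk))
  stopifnot(all(queries %in% rownames(C)))
  Ckk <- C[k, k, drop = FALSE]
  Cqk <- C[queries, k, drop = FALSE]
  x <- xk[k]
  nk <- length(k)
  one <- rep(1, nk)
  Kinv1 <- solve_c(Ckk, one)
  mu <- sum(Kinv1 * x) / sum(Kinv1)
  r <- x - mu
  Kinvr <- solve_c(Ckk, r)
  sigma2 <- sum(r * Kinvr) / nk                 # ML Brownian rate on known tips
  est <- mu + as.vector(Cqk %*% Kinvr)
  KinvCkq <- solve_c(Ckk, t(Cqk))
  cond_var <- diag(C)[queries] - rowSums(Cqk * t(KinvCkq))
  cond_var <- pmax(cond_var, 0)
  list(mean = stats::setNames(est, queries),
       se = stats::setNames(sqrt(sigma2 * cond_var), queries),
       mu = mu, sigma2 = sigma2)
}

#' Predict a binary trait for one trait-unknown tip
#'
#' Marginal posterior of the query's state under a 2-state equal-rates
#' (ER) Markov model. The transition rate is fit by maximum likelihood on
#' the known tips (query treated as missing data) and the posterior is
#' computed by Felsenstein pruning with a stationary (1/2, 1/2) root. If
#' all known states are identical the rate is non-identifiable; the
#' majority state is returned with probability 1 and a flag.
#'
#' @param tree A \code{phylo} containing the query and known tips only.
#' @param known Binary (0/1) trait values: named vector or data.frame.
#' @param query Tip label to predict.
#' @param trait Column name when \code{known} is a data.frame.
#' @return List with \code{prob} (named vector over states "0" and "1"),
#'   \code{state} (argmax), \code{rate}, \code{non_identifiable}.
#' @export
predict_tip_discrete <- function(tree, known, query, trait = NULL) {
  xk <- trait_vector(known, trait)
  if (!query %in% tree$tip.label) stop("query tip not in tree: ", query)
  known_tips <- setdiff(tree$tip.label, query)
  xk <- xk[known_tips]
  if (anyNA(xk)) stop("non-query tips lack trait values")
  if (!all(xk %in% c(0, 1))) stop("trait must be binary 0/1")
  if (length(unique(xk)) == 1L) {
    st <- as.character(xk[[1L]])
    prob <- stats::setNames(c(0, 0), c("0", "1")); prob[st] <- 1
    return(list(prob = prob, state = st, rate = NA_real_, non_identifiable = TRUE))
  }
  H <- max(ape::node.depth.edgelength(tree))
  nll <- function(lr) -er_pruning_loglik(tree, xk, exp(lr))
  opt <- stats::optim(log(1 / H), nll, method = "Brent",
                      lower = log(1e-8 / H), upper = log(100 / H))
  rate <- exp(opt$par)
  # posterior: likelihood with the query clamped to each state
  l0 <- er_pruning_loglik(tree, c(xk, stats::setNames(0, query)), rate)
  l1 <- er_pruning_loglik(tree, c(xk, stats::setNames(1, query)), rate)
  m <- max(l0, l1)
  w <- exp(c(l0, l1) - m)
  prob <- stats::setNames(w / sum(w), c("0", "1"))
  list(prob = prob, state = names(prob)[which.max(prob)], rate = rate,
       non_identifiable = FALSE)
}

# Log-likelihood of 0/1 tip states under the ER 2-state model by
# Felsenstein pruning; tips absent from `states` are missing data (1,1).
er_pruning_loglik <- function(tree, states, rate) {
  n_tip <- length(tree$tip.label)
  L <- matrix(1, n_tip + tree$Nnode, 2L)
  idx <- match(names(states), tree$tip.label)
  L[idx[!is.na(idx)], ] <- 0
  L[cbind(idx[!is.na(idx)], states[!is.na(idx)] + 1L)] <- 1
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]; blen <- tree$edge.length
  scale_log <- 0
  po <- ape::postorder(tree)
  for (nodecur in unique(parent[po])) {
    e <- which(parent == nodecur)
    for (j in e) {
      ch <- child[j]
      p_same <- 0.5 + 0.5 * exp(-2 * rate * blen[j])
      P <- matrix(c(p_same, 1 - p_same, 1 - p_same, p_same), 2L, 2L)
      L[nodecur, ] <- L[nodecur, ] * as.vector(P %*% L[ch, ])
    }
    m <- max(L[nodecur, ])
    if (m > 0 && m < 1e-100) { L[nodecur, ] <- L[nodecur, ] / m; scale_log <- scale_log + log(m) }
  }
  root <- n_tip + 1L
  log(sum(0.5 * L[root, ])) + scale_log
}

#' Predict a continuous trait for a set of trait-unknown tips
#'
#' Each query is predicted conditional on the known (reference) tips only,
#' with all other query tips pruned from the tree — trait-unknown
#' neighbors carry no information and must not influence each other.
#'
#' @param tree A \code{phylo} containing reference and query tips.
#' @param known Trait values for the reference tips (data.frame or named
#'   vector); must be disjoint from \code{queries}.
#' @param queries Character vector of query tip labels (may be empty).
#' @param trait Column name when \code{known} is a data.frame.
#' @return Data.frame ordered by taxon label: taxon, trait, estimate, se,
#'   ci_low, ci_high, ci_width.
#' @export
estimate_all <- function(tree, known, queries, trait = NULL) {
  xk <- trait_vector(known, trait)
  if (length(intersect(queries, names(xk))))
    stop("queries overlap known taxa")
  cols <- c("taxon", "trait", "estimate", "se", "ci_low", "ci_high", "ci_width")
  if (!length(queries))
    return(stats::setNames(data.frame(character(), character(), numeric(), numeric(),
                                      numeric(), numeric(), numeric(),
                                      stringsAsFactors = FALSE), cols))
  miss <- setdiff(queries, tree$tip.label)
  if (length(miss)) stop("query tip(s) not in tree: ", paste(miss, collapse = ", "))
  queries <- sort(queries)
  known_tips <- intersect(tree$tip.label, names(xk))
  extra <- setdiff(tree$tip.label, c(known_tips, queries))
  if (length(extra)) stop("tips with neither trait value nor query status: ",
                          paste(utils::head(extra, 5), collapse = ", "))
  if (length(known_tips) < 2) stop("need >= 2 known tips")
  res <- conditional_predict(tree, xk[known_tips], queries)
  data.frame(taxon = queries,
             trait = if (is.null(trait)) NA_character_ else trait,
             estimate = unname(res$mean), se = unname(res$se),
             ci_low = unname(res$mean - 1.96 * res$se),
             ci_high = unname(res$mean + 1.96 * res$se),
             ci_width = unname(2 * 1.96 * res$se),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Leave-one-out cross-validation of continuous tip prediction
#'
#' Hides each reference tip in turn, predicts it from the remaining tips
#' (GLS mean and ML rate re-estimated without it), and reports the Pearson
#' correlation between predictions and true values.
#'
#' @param tree A \code{phylo} whose tips all have known trait values.
#' @param known Trait values (data.frame or named vector).
#' @param trait Column name when \code{known} is a data.frame.
#' @return List of class \code{validation_report}: \code{method} ("loocv"),
#'   \code{n}, \code{r}, and a per-taxon data.frame \code{details}
#'   (taxon, true, estimate, se).
#' @export
loocv <- function(tree, known, trait = NULL) {
  x <- trait_vector(known, trait)
  C <- vcv_from_tree(tree)
  tips <- rownames(C)
  miss <- setdiff(tips, names(x))
  if (length(miss)) stop("trait values missing for tip(s): ",
                         paste(utils::head(miss, 5), collapse = ", "))
  n <- length(tips)
  if (n < 4) stop("need >= 4 known tips for LOOCV")
  x <- x[tips]
  if (stats::var(x) == 0) stop("degenerate trait: constant values, r undefined")
  # One factorization serves all folds: the inverse of C with row/col i
  # removed is the Schur complement P[-i,-i] - P[-i,i] P[i,-i] / P[ii]
  # of the full precision matrix P. Validated against the per-fold
  # conditional-MVN computation in the test suite.
  R <- chol_safe(C)
  P <- chol2inv(R)
  est <- se <- numeric(n)
  for (i in seq_len(n)) {
    pi_col <- P[-i, i]
    Aib <- function(b) P[-i, -i] %*% b - pi_col * (sum(pi_col * b) / P[i, i])
    onek <- rep(1, n - 1L)
    xkv <- x[-i]
    Kinv1 <- Aib(onek)
    mu <- sum(Kinv1 * xkv) / sum(Kinv1)
    r <- xkv - mu
    Kinvr <- Aib(r)
    sigma2 <- sum(r * Kinvr) / (n - 1L)
    cqk <- C[i, -i]
    est[i] <- mu + sum(cqk * Kinvr)
    cv <- max(0, C[i, i] - sum(cqk * as.vector(Aib(cqk))))
    se[i] <- sqrt(sigma2 * cv)
  }
  structure(list(method = "loocv", n = n,
                 r = stats::cor(x, est),
                 details = data.frame(taxon = tips, true = unname(x),
                                      estimate = est, se = se,
                                      stringsAsFactors = FALSE)),
            class = "validation_report")
}

#' Held-out test-set validation of continuous tip prediction
#'
#' Predicts every taxon in \code{test_set} using only the taxa outside it
#' (the whole test set is treated as trait-unknown simultaneously), then
#' reports the Pearson correlation with the true values. With a clustered
#' test set this is deliberately more conservative than LOOCV.
#'
#' @param tree A \code{phylo} whose tips all have known trait values.
#' @param known Trait values (data.frame or named vector).
#' @param test_set Character vector of taxa to hold out (subset of known).
#' @param trait Column name when \code{known} is a data.frame.
#' @return A \code{validation_report} with method "test_species".
#' @export
holdout_validation <- function(tree, known, test_set, trait = NULL) {
  x <- trait_vector(known, trait)
  if (!length(test_set)) stop("empty test set")
  if (!all(test_set %in% names(x))) stop("test_set is not a subset of known taxa")
  train <- setdiff(intersect(tree$tip.label, names(x)), test_set)
  if (length(train) < 2) stop("fewer than 2 training taxa remain")
  est <- estimate_all(tree, x[train], queries = test_set)
  truth <- x[est$taxon]
  structure(list(method = "test_species", n = length(test_set),
                 r = stats::cor(truth, est$estimate),
                 details = data.frame(taxon = est$taxon, true = unname(truth),
                                      estimate = est$estimate, se = est$se,
                                      stringsAsFactors = FALSE)),
            class = "validation_report")
}

#' Drop the least certain fraction of trait estimates
#'
#' Removes the \code{ceiling(fraction * n)} estimates with the widest
#' confidence intervals (the robustness filter applied before recomputing
#' community-weighted means). Ties in CI width are broken by taxon label.
#'
#' @param estimates Data.frame as returned by \code{\link{estimate_all}}.
#' @param fraction Fraction to drop, in [0, 1); default 0.2.
#' @return The retained rows, original order preserved.
#' @export
filter_least_certain <- function(estimates, fraction = 0.2) {
  if (fraction < 0 || fraction >= 1) stop("fraction must be in [0, 1)")
  n <- nrow(estimates)
  m <- ceiling(fraction * n)
  if (m == 0) return(estimates)
  ord <- order(-estimates$ci_width, estimates$taxon)
  drop_idx <- ord[seq_len(m)]
  estimates[-drop_idx, , drop = FALSE]
}

# Accept trait input as a named vector or a data.frame column.
trait_vector <- function(known, trait = NULL) {
  if (is.data.frame(known)) {
    if (is.null(trait)) {
      if (ncol(known) != 1L) stop("specify which trait column to use")
      trait <- colnames(known)[1L]
    }
    if (!trait %in% colnames(known)) stop("trait column not found: ", trait)
    stats::setNames(known[[trait]], rownames(known))
  } else {
    if (is.null(names(known))) stop("trait vector must be named by taxon")
    known
  }
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("%s validation: n = %d, Pearson r = %.3f\n", x$method, x$n, x$r))
  invisible(x)
}
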