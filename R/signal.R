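#' Blomberg's K with permutation test
#'
#' K compares the observed ratio of tip variance (around the phylogenetic
#' mean) to phylogenetically corrected variance against its Brownian
#' expectation on the same tree:
#' \deqn{K = (MSE0/MSE) / [(tr(C) - n / 1'C^{-1}1) / (n - 1)]}
#' with phylogenetic (GLS) mean \eqn{\hat a = 1'C^{-1}x / 1'C^{-1}1},
#' \eqn{MSE0 = (x-\hat a)'(x-\hat a)/(n-1)} and
#' \eqn{MSE = (x-\hat a)'C^{-1}(x-\hat a)/(n-1)}. K = 1 is the Brownian
#' expectation; K > 1 more signal, K < 1 less. The permutation p-value
#' shuffles tip values: low observed MSE (relative to permutations)
#' indicates signal. Uses the (b+1)/(m+1) correction.
#'
#' @param tree A \code{phylo} object (>= 3 tips).
#' @param x Named numeric trait vector covering all tips.
#' @param n_perm Number of permutations for the p-value (0 to skip).
#' @param seed Integer seed for the permutations.
#' @return A list of class \code{signal_result} with elements
#'   \code{statistic} ("K"), \code{value}, \code{p_vs_no_signal},
#'   \code{n_null}, \code{seed}.
#' @export
blomberg_k <- function(tree, x, n_perm = 1000, seed = 1) {
  C <- vcv_from_tree(tree)
  x <- align_trait(x, rownames(C))
  n <- length(x)
  if (n < 3) stop("need >= 3 tips")
  if (stats::var(x) == 0) stop("degenerate trait: constant values (MSE0 = 0)")
  Cinv1 <- solve_c(C, rep(1, n))
  s1 <- sum(Cinv1)
  expected_ratio <- (sum(diag(C)) - n / s1) / (n - 1)

  k_parts <- function(v) {
    a_hat <- sum(Cinv1 * v) / s1
    r <- v - a_hat
    mse0 <- sum(r * r) / (n - 1)
    mse <- sum(r * solve_c(C, r)) / (n - 1)
    c(k = (mse0 / mse) / expected_ratio, mse = mse)
  }
  obs <- k_parts(x)
  p <- NA_real_
  if (n_perm > 0) {
    null_mse <- withr::with_seed(seed, vapply(seq_len(n_perm), function(i) {
      k_parts(sample(x))[["mse"]]
    }, numeric(1)))
    p <- (sum(null_mse <= obs[["mse"]]) + 1) / (n_perm + 1)
  }
  structure(list(statistic = "K", value = obs[["k"]],
                 p_vs_no_signal = p, n_null = n_perm, seed = seed),
            class = "signal_result")
}

#' Maximum-likelihood Pagel's lambda with likelihood-ratio test
#'
#' Fits the multivariate-normal model x ~ N(mu 1, sigma^2 C(lambda)) where
#' C(lambda) scales the off-diagonal of the phylogenetic covariance matrix,
#' with mu the GLS mean and sigma^2 profiled out by ML (divide by n).
#' lambda is optimized on [0, 1] by Brent's method with endpoint checks; a
#' 1-df likelihood-ratio test against lambda = 0 gives the p-value. On a
#' star tree the likelihood is flat in lambda and the result is flagged
#' non-identifiable.
#'
#' @param tree A \code{phylo} object (>= 3 tips).
#' @param x Named numeric trait vector covering all tips.
#' @return A \code{signal_result} list with \code{value} (lambda-hat),
#'   \code{loglik}, \code{loglik_lambda0}, \code{p_vs_no_signal},
#'   \code{non_identifiable}.
#' @export
pagel_lambda <- function(tree, x) {
  C <- vcv_from_tree(tree)
  x <- align_trait(x, rownames(C))
  n <- length(x)
  if (n < 3) stop("need >= 3 tips")
  if (stats::var(x) == 0) stop("degenerate trait: constant values")
  off <- C; diag(off) <- 0
  if (max(abs(off)) < 1e-12) {
    ll <- bm_profile_loglik(C, x)
    return(structure(list(statistic = "lambda", value = NA_real_,
                          loglik = ll, loglik_lambda0 = ll,
                          p_vs_no_signal = NA_real_, non_identifiable = TRUE),
                     class = "signal_result"))
  }
  f <- function(l) bm_profile_loglik(lambda_transform(C, l), x)
  opt <- stats::optimize(f, interval = c(0, 1), maximum = TRUE, tol = 1e-8)
  cand <- rbind(c(opt$maximum, opt$objective), c(0, f(0)), c(1, f(1)))
  best <- cand[which.max(cand[, 2L]), ]
  ll0 <- cand[2L, 2L]
  lrt <- max(0, 2 * (best[2L] - ll0))
  structure(list(statistic = "lambda", value = best[1L], loglik = best[2L],
                 loglik_lambda0 = ll0,
                 p_vs_no_signal = stats::pchisq(lrt, df = 1, lower.tail = FALSE),
                 non_identifiable = FALSE),
            class = "signal_result")
}

# Profile log-likelihood of x ~ N(mu 1, sigma^2 V) with mu by GLS and
# sigma^2 by ML (divide by n).
bm_profile_loglik <- function(V, x) {
  n <- length(x)
  R <- chol_safe(V)
  logdet <- 2 * sum(log(diag(R)))
  Vinv1 <- backsolve(R, forwardsolve(t(R), rep(1, n)))
  mu <- sum(Vinv1 * x) / sum(Vinv1)
  r <- x - mu
  q <- sum(r * backsolve(R, forwardsolve(t(R), r)))
  s2 <- q / n
  -n / 2 * (log(2 * pi) + log(s2) + 1) - logdet / 2
}

#' Fritz-Purvis D for binary traits
#'
#' Measures phylogenetic clumping of a 0/1 trait. The raw score d is the
#' sum over internal nodes of the absolute differences between daughter
#' subtree values, where node values are computed by a post-order pass
#' (each internal node = mean of its daughters; at polytomies the
#' contribution is the sum of |daughter - node mean|, which reduces to
#' |v1 - v2| on bifurcations). D scales d_obs between two simulated nulls:
#' \deqn{D = (d_{obs} - mean(d_B)) / (mean(d_R) - mean(d_B))}
#' with d_R from tip-label shuffles (D = 1: random) and d_B from Brownian
#' simulations thresholded at the observed prevalence (D = 0: Brownian
#' clumping). p_vs_random is the fraction of shuffle d's <= d_obs (+1
#' corrected); p_vs_brownian the fraction of Brownian d's >= d_obs.
#'
#' @param tree A \code{phylo} object.
#' @param x Named 0/1 trait vector covering all tips; both states present.
#' @param n_sim Simulations per null.
#' @param seed Integer seed.
#' @return A \code{signal_result} list with \code{value} (D), \code{d_obs},
#'   \code{d_random_mean}, \code{d_brownian_mean}, \code{p_vs_random},
#'   \code{p_vs_brownian}.
#' @export
fritz_purvis_d <- function(tree, x, n_sim = 1000, seed = 1) {
  tips <- sort(tree$tip.label)
  x <- align_trait(x, tips)
  if (!all(x %in% c(0, 1))) stop("trait must be binary 0/1")
  n <- length(x)
  m1 <- sum(x == 1)
  if (m1 == 0 || m1 == n) stop("constant state vector")
  if (n < 10) warning("D is unreliable below 10 tips")
  d_obs <- d_score(tree, matrix(x[tree$tip.label], ncol = 1))

  nulls <- withr::with_seed(seed, {
    shuf <- vapply(seq_len(n_sim), function(i) sample(unname(x)), numeric(n))
    rownames(shuf) <- tips
    C <- vcv_from_tree(tree)
    R <- chol_safe(C)
    z <- crossprod(R, matrix(stats::rnorm(n * n_sim), n, n_sim))
    rownames(z) <- rownames(C)
    bm_bin <- apply(z, 2L, function(col) {
      thr <- sort(col, decreasing = TRUE)[m1]
      as.numeric(col >= thr)
    })
    rownames(bm_bin) <- rownames(C)
    list(shuf = shuf, bm = bm_bin)
  })
  d_r <- d_score(tree, nulls$shuf[tree$tip.label, , drop = FALSE])
  d_b <- d_score(tree, nulls$bm[tree$tip.label, , drop = FALSE])
  denom <- mean(d_r) - mean(d_b)
  D <- if (abs(denom) < 1e-12) NA_real_ else (d_obs - mean(d_b)) / denom
  structure(list(statistic = "D", value = D, d_obs = d_obs,
                 d_random_mean = mean(d_r), d_brownian_mean = mean(d_b),
                 p_vs_random = (sum(d_r <= d_obs) + 1) / (n_sim + 1),
                 p_vs_brownian = (sum(d_b >= d_obs) + 1) / (n_sim + 1),
                 n_null = n_sim, seed = seed),
            class = "signal_result")
}

# Raw Fritz-Purvis d for each column of a tips x m matrix X (rows in
# tree$tip.label order). Vectorized over columns: one post-order pass.
d_score <- function(tree, X) {
  n_tip <- length(tree$tip.label)
  n_node <- tree$Nnode
  vals <- matrix(0, n_tip + n_node, ncol(X))
  vals[seq_len(n_tip), ] <- X
  d <- numeric(ncol(X))
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  # postorder edge traversal visits each internal node children-first
  ord <- unique(parent[ape::postorder(tree)])
  for (nodecur in ord) {
    ch <- child[parent == nodecur]
    chv <- vals[ch, , drop = FALSE]
    nv <- colMeans(chv)
    vals[nodecur, ] <- nv
    d <- d + colSums(abs(sweep(chv, 2L, nv)))
  }
  d
}

# Align a named trait vector to an ordered label set, with checks.
align_trait <- function(x, labels) {
  if (is.null(names(x))) {
    if (length(x) != length(labels)) stop("unnamed trait vector of wrong length")
    names(x) <- labels
  }
  missing_tips <- setdiff(labels, names(x))
  if (length(missing_tips))
    stop("trait values missing for tip(s): ", paste(utils::head(missing_tips, 5), collapse = ", "))
  x <- x[labels]
  if (anyNA(x)) stop("NA trait values")
  x
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f\n", x$statistic, x$value))
  for (f in grep("^p_", names(x), value = TRUE))
    if (!is.na(x[[f]])) cat(sprintf("  %s = %.4g\n", f, x[[f]]))
  invisible(x)
}
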