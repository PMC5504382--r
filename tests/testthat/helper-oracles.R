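# Independent brute-force oracles used to validate the package's
# linear-algebra paths. These deliberately share no code with R/: paths are
# walked explicitly, systems solved with dense solve(), recursions written
# directly from the definitions.

# Shared-path covariance by explicit root-to-tip path walking.
oracle_vcv <- function(tree) {
  tips <- sort(tree$tip.label)
  n <- length(tips)
  # edge path from root to each tip
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  root <- length(tree$tip.label) + 1L
  path_edges <- function(tip_idx) {
    edges <- integer(0)
    node <- tip_idx
    while (node != root) {
      e <- which(child == node)
      edges <- c(edges, e)
      node <- parent[e]
    }
    edges
  }
  paths <- lapply(match(tips, tree$tip.label), path_edges)
  C <- matrix(0, n, n, dimnames = list(tips, tips))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(tree$edge.length[shared])
  }
  C
}

# Conditional multivariate-normal mean/variance by dense matrix algebra.
oracle_conditional <- function(tree, xk, query) {
  C <- oracle_vcv(tree)
  k <- setdiff(rownames(C), query)
  k <- k[k %in% names(xk)]
  Ckk <- C[k, k, drop = FALSE]
  Ckk_inv <- solve(Ckk)
  one <- rep(1, length(k))
  mu <- as.numeric(t(one) %*% Ckk_inv %*% xk[k]) /
    as.numeric(t(one) %*% Ckk_inv %*% one)
  r <- xk[k] - mu
  sigma2 <- as.numeric(t(r) %*% Ckk_inv %*% r) / length(k)
  cqk <- C[query, k, drop = FALSE]
  est <- mu + as.numeric(cqk %*% Ckk_inv %*% r)
  cv <- C[query, query] - as.numeric(cqk %*% Ckk_inv %*% t(cqk))
  list(mean = est, var = sigma2 * max(cv, 0), mu = mu, sigma2 = sigma2)
}

# Blomberg's K straight from the defining formula with solve().
oracle_k <- function(tree, x) {
  C <- oracle_vcv(tree)
  x <- x[rownames(C)]
  n <- length(x)
  Cinv <- solve(C)
  one <- rep(1, n)
  a_hat <- as.numeric(t(one) %*% Cinv %*% x) / as.numeric(t(one) %*% Cinv %*% one)
  r <- x - a_hat
  mse0 <- sum(r^2) / (n - 1)
  mse <- as.numeric(t(r) %*% Cinv %*% r) / (n - 1)
  (mse0 / mse) / ((sum(diag(C)) - n / sum(Cinv)) / (n - 1))
}

# Fritz-Purvis raw d by direct recursion on a single state vector.
oracle_d <- function(tree, x) {
  n_tip <- length(tree$tip.label)
  parent <- tree$edge[, 1L]; child <- tree$edge[, 2L]
  node_value <- function(node) {
    if (node <= n_tip) return(x[[tree$tip.label[node]]])
    vapply(child[parent == node], node_value, numeric(1))
  }
  total <- 0
  for (node in (n_tip + 1L):(n_tip + tree$Nnode)) {
    ch <- child[parent == node]
    vals <- vapply(ch, function(c_) mean_value(c_, tree, x), numeric(1))
    total <- total + sum(abs(vals - mean(vals)))
  }
  total
}

# Post-order mean value of a node's daughters, recursively.
mean_value <- function(node, tree, x) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(x[[tree$tip.label[node]]])
  ch <- tree$edge[tree$edge[, 1L] == node, 2L]
  mean(vapply(ch, function(c_) mean_value(c_, tree, x), numeric(1)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Small fixed tree used across files.
toy_tree <- function(newick = "((A:1,B:1):1,(C:1,D:1):1);") {
  tf <- tempfile(fileext = ".nwk")
  writeLines(newick, tf)
  read_newick(tf)
}
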