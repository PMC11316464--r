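# Independent brute-force oracles, deliberately written along different
# computational routes than the package internals.

# shared root-to-MRCA path length by explicit path enumeration
brute_shared_path <- function(phy) {
  n <- ape::Ntip(phy)
  root <- n + 1L
  parent <- integer(max(phy$edge))
  elen <- numeric(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  path_nodes <- function(tip) {
    nodes <- integer(0); v <- tip
    while (v != root) { nodes <- c(nodes, v); v <- parent[v] }
    nodes
  }
  paths <- lapply(seq_len(n), path_nodes)
  C <- matrix(0, n, n, dimnames = list(phy$tip.label, phy$tip.label))
  # the edges above the common ancestors of i and j form the shared path
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- sum(elen[intersect(paths[[i]], paths[[j]])])
  C
}

# GLS coefficients via explicit matrix inversion and the normal equations
brute_gls <- function(X, y, V) {
  Vi <- solve(V)
  solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi %*% y
}

# multivariate normal log-density via eigendecomposition
dmvnorm_eigen <- function(x, mu, V) {
  e <- eigen((V + t(V)) / 2, symmetric = TRUE)
  stopifnot(all(e$values > 0))
  z <- t(e$vectors) %*% (x - mu)
  -length(x) / 2 * log(2 * pi) - sum(log(e$values)) / 2 -
    sum(z^2 / e$values) / 2
}

# conditional MVN mean/variance via explicit solve()
brute_conditional <- function(mu, V, obs_idx, y_obs, want_idx) {
  Voo <- V[obs_idx, obs_idx]
  Vwo <- V[want_idx, obs_idx, drop = FALSE]
  K <- Vwo %*% solve(Voo)
  mean_w <- mu[want_idx] + drop(K %*% (y_obs - mu[obs_idx]))
  var_w <- diag(V)[want_idx] - rowSums(K * Vwo)
  list(mean = mean_w, sd = sqrt(pmax(0, var_w)))
}

# MVN draw used by tests (route independent of the package generator)
rmvn_test <- function(mu, V) {
  L <- t(chol(V + diag(1e-12, nrow(V))))
  drop(mu + L %*% rnorm(length(mu)))
}

# small fixed trees
tree_cherry <- function() read_phylo("(A:1,B:1);")
tree_three <- function() read_phylo("((A:1,B:1):1,C:2):0;")
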