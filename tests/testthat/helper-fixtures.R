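# Shared fixtures and independent oracles used across the suite.

# dense multivariate-normal BM log density built from the full phylogenetic
# covariance matrix -- independent of the pruning implementation
bm_dense_oracle <- function(tree, x, sigma2, root_mean, lambda = 1,
                            use_scalars = TRUE) {
  phy <- tree
  if (use_scalars) phy$edge.length <- phy$edge.length * branch_scalars(tree)
  C <- ape::vcv(phy)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  V <- sigma2 * Cl
  n <- length(x)
  d <- x[colnames(C)] - root_mean
  -0.5 * (n * log(2 * pi) + as.numeric(determinant(V)$modulus) +
            drop(t(d) %*% solve(V, d)))
}

# brute-force likelihood of a k-state CTMC by enumerating all internal-node
# state assignments with matrix-exponential transition probabilities
ctmc_enum_oracle <- function(tree, tip_states, Q, rootp) {
  states <- colnames(Q)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  edge <- tree$edge
  Pm <- lapply(seq_len(nrow(edge)), function(e) {
    P <- as.matrix(Matrix::expm(unclass(Q) * tree$edge.length[e]))
    dimnames(P) <- list(states, states)
    P
  })
  tipidx <- match(tip_states[tree$tip.label], states)
  grids <- do.call(expand.grid, rep(list(seq_along(states)), nnode))
  tot <- 0
  for (g in seq_len(nrow(grids))) {
    ass <- c(tipidx, as.integer(grids[g, ]))
    p <- rootp[ass[ntip + 1]]
    for (e in seq_len(nrow(edge))) {
      p <- p * Pm[[e]][ass[edge[e, 1]], ass[edge[e, 2]]]
      if (p == 0) break
    }
    tot <- tot + p
  }
  unname(log(tot))
}

# tip values drawn under a lambda-transformed BM covariance
simulate_lambda_tips <- function(tree, lambda, sigma2, root_mean = 0,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  C <- ape::vcv(tree)
  Cl <- lambda * C
  diag(Cl) <- diag(C)
  x <- root_mean + drop(crossprod(chol(sigma2 * Cl),
                                  stats::rnorm(ape::Ntip(tree))))
  stats::setNames(x, colnames(C))
}

random_Q <- function(scale = 0.5) {
  correlated_Q(stats::runif(8, 0.05, 1) * scale)
}

# a species range table whose zooxanthellate boxes stay inside the photic
# zone, so clean uniform draws can never trip the gap rule
demo_range_table <- function(n_az = 4, n_z = 4) {
  data.frame(
    species = c(paste0("az", seq_len(n_az)), paste0("z", seq_len(n_z))),
    min_depth = c(rep(200, n_az), rep(2, n_z)),
    max_depth = c(rep(3000, n_az), rep(120, n_z)),
    min_lat = -20, max_lat = 20,
    symbiotic = rep(c(FALSE, TRUE), c(n_az, n_z)),
    stringsAsFactors = FALSE)
}
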