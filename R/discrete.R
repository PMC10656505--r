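# Correlated evolution of symbiosis and coloniality: 4-state CTMC with
# dual transitions disallowed, Bayesian rate fitting, node state posteriors.

#' Tip partial-likelihood (ambiguity) matrix from combined trait states
#'
#' Ordinary tips get a point mass on their combined state; facultative tips
#' spread mass 0.5/0.5 over the two states compatible with the trait they
#' are facultative for.
#'
#' @param states character vector of states (`lineage_states()`), named by
#'   tip label.
#' @param facultative_for `NA`, `"symbiosis"` or `"coloniality"` per tip.
#' @return numeric matrix (tips x 4), columns AS, AC, ZS, ZC.
#' @export
tip_state_liks <- function(states, facultative_for = NA) {
  sts <- lineage_states()
  if (any(!states %in% sts)) stop("unknown state")
  fac <- rep_len(facultative_for, length(states))
  M <- matrix(0, length(states), 4, dimnames = list(names(states), sts))
  flip_symb <- c(AS = "ZS", AC = "ZC", ZS = "AS", ZC = "AC")
  flip_col <- c(AS = "AC", AC = "AS", ZS = "ZC", ZC = "ZS")
  for (i in seq_along(states)) {
    if (is.na(fac[i])) M[i, states[i]] <- 1
    else {
      other <- if (fac[i] == "symbiosis") flip_symb[[states[i]]] else flip_col[[states[i]]]
      M[i, c(states[i], other)] <- 0.5
    }
  }
  M
}

.tiplik_from_input <- function(tree, tip_states) {
  if (is.matrix(tip_states)) {
    M <- tip_states
    if (!is.null(rownames(M))) M <- M[tree$tip.label, , drop = FALSE]
    if (nrow(M) != ape::Ntip(tree) || ncol(M) != 4) stop("tip state matrix must be tips x 4")
    return(M)
  }
  if (!is.null(names(tip_states))) tip_states <- tip_states[tree$tip.label]
  if (length(tip_states) != ape::Ntip(tree)) stop("one state per tip required")
  tip_state_liks(tip_states)
}

.root_probs <- function(Q, root) {
  if (is.numeric(root)) {
    if (length(root) != 4 || abs(sum(root) - 1) > 1e-8) stop("invalid root distribution")
    return(root)
  }
  switch(match.arg(root, c("stationary", "uniform")),
         stationary = unname(stationary_distribution(Q)),
         uniform = rep(0.25, 4))
}

#' Pruning log likelihood of correlated binary traits
#'
#' Likelihood of tip states of the combined 4-state symbiosis/coloniality
#' chain, computed by Felsenstein pruning with matrix-exponential transition
#' probabilities on each branch.  The root state distribution is the
#' stationary distribution of `Q` by default (`"uniform"` and explicit
#' vectors are accepted).
#'
#' @param tree a [timetree()].
#' @param tip_states character states named by tip, or a tips x 4 ambiguity
#'   matrix (see [tip_state_liks()]).
#' @param Q a [correlated_Q()] matrix.
#' @param root `"stationary"`, `"uniform"`, or a probability 4-vector.
#' @return log likelihood (nats; `-Inf` for impossible data).
#' @export
correlated_loglik <- function(tree, tip_states, Q, root = "stationary") {
  tree <- as_timetree(tree)
  .validate_Q(Q)
  M <- .tiplik_from_input(tree, tip_states)
  po <- .postorder_parts(tree)
  rootp <- .root_probs(Q, root)
  ctmc_prune_cpp(po$edge, tree$edge.length[po$order], ape::Ntip(tree),
                 unname(M), unclass(Q), rootp)
}

#' Bayesian MCMC over the eight correlated-trait transition rates
#'
#' Metropolis-within-Gibbs sampling of the 8 single-trait transition rates
#' under iid exponential priors whose mean is itself a Uniform(0, `hyper_max`)
#' hyperparameter (an "exponential (0, 10) hyperprior").  With `rj = TRUE`
#' a reversible-jump move may switch individual rates off (exactly zero).
#' `prior_only = TRUE` disables the likelihood so prior recovery can be
#' checked.
#'
#' @param tree a [timetree()].
#' @param tip_states states per tip (character or ambiguity matrix).
#' @param n_iter,burnin,thin chain settings.
#' @param hyper_max upper bound of the uniform hyperprior on the prior mean.
#' @param rj allow reversible-jump zeroing of rates?
#' @param prior_only sample from the prior (likelihood off)?
#' @param root root state distribution passed to [correlated_loglik()].
#' @param seed optional integer seed.
#' @return object of class `"discrete_chain"`: `rates` (draws x 8),
#'   `samples` (`prior_mean`, `loglik`), tree and inputs.
#' @export
fit_discrete_mcmc <- function(tree, tip_states, n_iter = 10000,
                              burnin = floor(n_iter / 4), thin = 5,
                              hyper_max = 10, rj = FALSE, prior_only = FALSE,
                              root = "stationary", seed = NULL) {
  tree <- as_timetree(tree)
  M <- .tiplik_from_input(tree, tip_states)
  hard <- apply(M, 1, function(p) if (max(p) == 1) which.max(p) else NA_integer_)
  if (all(!is.na(hard)) && length(unique(hard)) == 1)
    warning("all tips share one state: rates are weakly identified")
  if (!is.null(seed)) set.seed(seed)
  po <- .postorder_parts(tree)
  lens <- tree$edge.length[po$order]
  ntip <- ape::Ntip(tree)
  rate_names <- c("qAS.AC", "qAC.AS", "qAS.ZS", "qZS.AS",
                  "qAC.ZC", "qZC.AC", "qZS.ZC", "qZC.ZS")
  ll_for <- function(r) {
    if (prior_only) return(0)
    Q <- correlated_Q(stats::setNames(r, rate_names))
    ctmc_prune_cpp(po$edge, lens, ntip, unname(M), unclass(Q),
                   .root_probs(Q, root))
  }
  lprior_rates <- function(r, m) sum(stats::dexp(r[r > 0], 1 / m, log = TRUE))
  m <- hyper_max / 2
  r <- stats::rexp(8, 1 / m)
  ll <- ll_for(r)
  while (!is.finite(ll)) { r <- stats::rexp(8, 1 / m); ll <- ll_for(r) }
  keep <- (n_iter - burnin) %/% thin
  rates <- matrix(NA_real_, keep, 8, dimnames = list(NULL, rate_names))
  samp <- matrix(NA_real_, keep, 2, dimnames = list(NULL, c("prior_mean", "loglik")))
  ki <- 0
  for (it in seq_len(n_iter)) {
    for (j in sample.int(8)) {
      if (r[j] == 0) next
      rp <- r; rp[j] <- r[j] * exp(stats::rnorm(1, 0, 0.5))
      llp <- ll_for(rp)
      # log-scale random walk: Jacobian log(rp/r) added to the prior ratio
      la <- llp - ll + stats::dexp(rp[j], 1 / m, log = TRUE) -
        stats::dexp(r[j], 1 / m, log = TRUE) + log(rp[j]) - log(r[j])
      if (is.finite(la) && log(stats::runif(1)) < la) { r <- rp; ll <- llp }
    }
    if (rj) {
      j <- sample.int(8, 1)
      rp <- r
      # indicator prior 0.5/0.5; the reverse on-move draws from the value
      # prior, so prior and proposal densities cancel and only the
      # likelihood ratio remains
      if (r[j] > 0) rp[j] <- 0 else rp[j] <- stats::rexp(1, 1 / m)
      llp <- ll_for(rp)
      la <- llp - ll
      if (is.finite(la) && log(stats::runif(1)) < la) { r <- rp; ll <- llp }
    }
    mp <- m + stats::rnorm(1, 0, hyper_max / 10)
    if (mp > 0 && mp < hyper_max) {
      la <- lprior_rates(r, mp) - lprior_rates(r, m)
      if (log(stats::runif(1)) < la) m <- mp
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      ki <- ki + 1
      rates[ki, ] <- r
      samp[ki, ] <- c(m, ll)
    }
  }
  structure(list(rates = rates, samples = samp, tree = tree,
                 tip_liks = M, root = root, seed = seed),
            class = "discrete_chain")
}

#' @export
print.discrete_chain <- function(x, ...) {
  cat("Correlated-traits chain:", nrow(x$rates), "draws\n")
  print(round(apply(x$rates, 2, stats::median), 4))
  invisible(x)
}

#' Marginal ancestral state posteriors per node
#'
#' For a thinned subset of posterior rate draws, computes exact marginal
#' node state probabilities by the pruning up-down pass, then summarizes
#' each node/state cell by its across-draw median and renormalizes so every
#' node's four probabilities sum to one (medians alone do not).
#'
#' @param tree a [timetree()].
#' @param tip_states states per tip (character or ambiguity matrix).
#' @param chain a `"discrete_chain"`, or a draws x 8 rate matrix.
#' @param n_samples number of posterior draws to use (evenly thinned).
#' @param root root distribution rule (per draw).
#' @return matrix (nodes x 4, ape node indices incl. tips), columns
#'   AS, AC, ZS, ZC; rows sum to 1.
#' @export
node_state_posteriors <- function(tree, tip_states, chain, n_samples = 100,
                                  root = "stationary") {
  tree <- as_timetree(tree)
  M <- .tiplik_from_input(tree, tip_states)
  R <- if (inherits(chain, "discrete_chain")) chain$rates else as.matrix(chain)
  if (!nrow(R)) stop("empty chain")
  take <- unique(round(seq(1, nrow(R), length.out = min(n_samples, nrow(R)))))
  po <- .postorder_parts(tree)
  lens <- tree$edge.length[po$order]
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  acc <- array(NA_real_, c(ntot, 4, length(take)))
  rate_names <- colnames(R)
  for (s in seq_along(take)) {
    Q <- correlated_Q(stats::setNames(R[take[s], ], rate_names))
    acc[, , s] <- ctmc_marginals_cpp(po$edge, lens, ntip, unname(M),
                                     unclass(Q), .root_probs(Q, root))
  }
  med <- apply(acc, c(1, 2), stats::median)
  med <- med / rowSums(med)
  dimnames(med) <- list(NULL, lineage_states())
  med
}
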