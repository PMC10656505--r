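# Stepping-stone marginal likelihoods, Bayes factors, posterior significance.

#' Stepping-stone estimate of the log marginal likelihood
#'
#' Path sampling through the power posteriors `prior * likelihood^beta`
#' along a ladder of "stones" with `beta` values at quantiles of a
#' Beta(`alpha`, 1) distribution (which concentrates stones near the prior,
#' where the integrand changes fastest).  Each stone runs a short random-walk
#' Metropolis chain at the lower power and the log ratio to the next power is
#' estimated by importance sampling; the sum over stones is the log marginal
#' likelihood in nats.
#'
#' @param model a list with functions `sample_prior()` (returns a parameter
#'   vector), `log_prior(theta)`, `log_lik(theta)` and optionally
#'   `propose(theta)` (symmetric proposal; default Gaussian random walk with
#'   `model$step` scale).
#' @param n_stones number of stones.
#' @param iters_per_stone Metropolis iterations per stone.
#' @param alpha Beta-distribution shape for the stone schedule.
#' @param seed optional integer seed.
#' @return list of class `"marginal_likelihood"`: `logml`, `n_stones`,
#'   `iters_per_stone`, per-stone `log_ratios`.
#' @export
stepping_stone_logml <- function(model, n_stones = 30, iters_per_stone = 400,
                                 alpha = 0.4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  propose <- model$propose
  if (is.null(propose)) {
    step <- if (is.null(model$step)) 0.5 else model$step
    # coordinate-wise random walk mixes far better than joint updates when
    # the posterior is anisotropic
    propose <- function(theta) {
      j <- sample.int(length(theta), 1)
      theta[j] <- theta[j] + stats::rnorm(1, 0, step)
      theta
    }
  }
  betas <- stats::qbeta(seq(0, 1, length.out = n_stones + 1), alpha, 1)
  theta <- model$sample_prior()
  lp <- model$log_prior(theta)
  llik <- model$log_lik(theta)
  if (!is.finite(lp)) stop("prior sample has zero prior density")
  log_ratios <- numeric(n_stones)
  logmeanexp <- function(v) {
    m <- max(v)
    if (!is.finite(m)) return(m)
    m + log(mean(exp(v - m)))
  }
  for (k in seq_len(n_stones)) {
    b_lo <- betas[k]; b_hi <- betas[k + 1]
    ll_store <- numeric(iters_per_stone)
    for (it in seq_len(iters_per_stone)) {
      thp <- propose(theta)
      lpp <- model$log_prior(thp)
      if (is.finite(lpp)) {
        llp <- model$log_lik(thp)
        la <- (lpp + b_lo * llp) - (lp + b_lo * llik)
        if (is.finite(la) && log(stats::runif(1)) < la) {
          theta <- thp; lp <- lpp; llik <- llp
        }
      }
      ll_store[it] <- llik
    }
    log_ratios[k] <- logmeanexp((b_hi - b_lo) * ll_store)
    if (!is.finite(log_ratios[k]))
      stop("stepping-stone stone ", k, " degenerate (zero likelihood everywhere?)")
  }
  structure(list(logml = sum(log_ratios), n_stones = n_stones,
                 iters_per_stone = iters_per_stone, log_ratios = log_ratios,
                 betas = betas),
            class = "marginal_likelihood")
}

#' @export
print.marginal_likelihood <- function(x, ...) {
  cat("Stepping-stone log marginal likelihood:", round(x$logml, 4),
      "(", x$n_stones, "stones x", x$iters_per_stone, "iters )\n")
  invisible(x)
}

#' Stepping-stone model specifications for depth evolution
#'
#' `ss_model_bm` is single-rate Brownian motion with parameters
#' `(root_mean, log sigma2)`; `ss_model_partitioned` additionally carries one
#' log rate scalar per branch category.  Priors are proper and weakly
#' informative: `root_mean ~ N(mean(y), (3 sd(y))^2)`,
#' `log sigma2 ~ N(log s2_hat, 2^2)` and each
#' `log r ~ Uniform(-log 100, log 100)`.
#'
#' @param tree a [timetree()].
#' @param response numeric tip values, named by tip label.
#' @param partition for the partitioned model, one category per branch.
#' @return a model list for [stepping_stone_logml()].
#' @export
ss_model_bm <- function(tree, response) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, response)
  ctx <- .bm_context(tree)
  lens <- tree$edge.length[ctx$order] * branch_scalars(tree)[ctx$order]
  m0 <- mean(y); s0 <- 3 * stats::sd(y)
  ls2_0 <- log(stats::var(y) / max(node_ages(tree)))
  list(
    sample_prior = function() c(stats::rnorm(1, m0, s0), stats::rnorm(1, ls2_0, 2)),
    log_prior = function(th)
      stats::dnorm(th[1], m0, s0, log = TRUE) + stats::dnorm(th[2], ls2_0, 2, log = TRUE),
    log_lik = function(th)
      bm_prune_cpp(ctx$edge, lens * exp(th[2]), ctx$ntip, y, th[1], TRUE),
    step = 0.3
  )
}

#' @rdname ss_model_bm
#' @export
ss_model_partitioned <- function(tree, response, partition) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, response)
  ctx <- .bm_context(tree)
  base_len <- tree$edge.length[ctx$order]
  partition <- as.character(partition)
  if (length(partition) != nrow(tree$edge)) stop("need one category per branch")
  cats <- sort(unique(partition))
  idx <- lapply(cats, function(cc) which(partition[ctx$order] == cc))
  m0 <- mean(y); s0 <- 3 * stats::sd(y)
  ls2_0 <- log(stats::var(y) / max(node_ages(tree)))
  bound <- log(100)
  nc <- length(cats)
  list(
    sample_prior = function() c(stats::rnorm(1, m0, s0), stats::rnorm(1, ls2_0, 2),
                                stats::runif(nc, -bound, bound)),
    log_prior = function(th) {
      if (any(abs(th[-(1:2)]) > bound)) return(-Inf)
      stats::dnorm(th[1], m0, s0, log = TRUE) +
        stats::dnorm(th[2], ls2_0, 2, log = TRUE) - nc * log(2 * bound)
    },
    log_lik = function(th) {
      l <- base_len
      for (j in seq_len(nc)) l[idx[[j]]] <- l[idx[[j]]] * exp(th[2 + j])
      bm_prune_cpp(ctx$edge, l * exp(th[2]), ctx$ntip, y, th[1], TRUE)
    },
    step = 0.25,
    categories = cats
  )
}

#' Log Bayes factor between two marginal likelihoods
#'
#' `log BF = 2 * (log ML complex - log ML simple)`; values above 2 count as
#' positive evidence for the complex model and above 10 as very strong
#' evidence (Raftery's scale).
#'
#' @param logml_complex,logml_simple log marginal likelihoods (nats), or
#'   `"marginal_likelihood"` objects.
#' @return list with `log_bf` and `evidence` label.
#' @export
log_bayes_factor <- function(logml_complex, logml_simple) {
  g <- function(x) if (inherits(x, "marginal_likelihood")) x$logml else x
  lc <- g(logml_complex); ls <- g(logml_simple)
  if (!is.finite(lc) || !is.finite(ls)) stop("log marginal likelihoods must be finite")
  lbf <- 2 * (lc - ls)
  evidence <- if (lbf > 10) "very strong" else if (lbf > 2) "positive"
    else if (lbf >= -2) "none" else "favors simple"
  list(log_bf = lbf, evidence = evidence,
       logml_complex = lc, logml_simple = ls)
}

#' Posterior crossing-zero significance
#'
#' The proportion of a posterior sample (of a coefficient or a difference of
#' coefficients) on the minority side of zero: `min(P(x < 0), P(x > 0))`.
#' The quantity is significant when that proportion is below `alpha`.
#'
#' @param samples numeric vector of at least 100 posterior draws.
#' @param alpha significance threshold.
#' @return list with `p_cross` and logical `significant`.
#' @export
posterior_crossing_significance <- function(samples, alpha = 0.05) {
  if (length(samples) < 100) stop("need at least 100 posterior samples")
  p <- min(mean(samples < 0), mean(samples > 0))
  list(p_cross = p, significant = p < alpha)
}
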