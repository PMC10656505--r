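# Variable-rates model: reversible-jump MCMC over branch/clade rate scalars.

# descendant edge indices (rows of tree$edge) of the clade rooted at each
# internal node, including the stem edge of that node
.clade_edges <- function(tree) {
  ntip <- ape::Ntip(tree)
  po <- ape::reorder.phylo(tree, "postorder", index.only = TRUE)
  edge <- tree$edge
  below <- vector("list", ntip + tree$Nnode)   # edges strictly below node
  for (e in po) {
    p <- edge[e, 1]; c <- edge[e, 2]
    below[[p]] <- c(below[[p]], e, below[[c]])
  }
  out <- vector("list", tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    node <- ntip + k
    stem <- which(edge[, 2] == node)
    out[[k]] <- sort(c(stem, below[[node]]))
  }
  out
}

#' Reversible-jump MCMC for the variable-rates (VR) model
#'
#' Brownian evolution of a continuous character in which individual branches
#' or whole clades may be stretched (`r > 1`, accelerated change) or
#' compressed (`0 < r < 1`, decelerated) by a rate scalar; `r = 1` leaves
#' the branch at the background rate.  The chain jumps between numbers of
#' scalars (geometric prior on the count; log-uniform prior on each value
#' over `[1/100, 100]`) and each posterior draw is a scaled tree.  With a
#' design matrix the model is a variable-rates regression: coefficients get
#' Gibbs updates from their conditional normal and the scalars act on the
#' residual covariance.
#'
#' @param tree a [timetree()] (its own scalars are ignored; the chain owns them).
#' @param response numeric tip values, named by tip label.
#' @param design optional design matrix (rows in tip order).
#' @param n_iter,burnin,thin chain settings.
#' @param geom_p geometric prior parameter on the number of scalars.
#' @param log_r_bound scalars have log-uniform prior on
#'   `[-log_r_bound, log_r_bound]` (natural log).
#' @param seed optional integer seed.
#' @return object of class `"vr_chain"`: `scalars` (draws x branches matrix
#'   of effective per-branch scalars), `samples` (sigma2, root/beta, k,
#'   loglik), the tree and settings.
#' @export
vr_rjmcmc <- function(tree, response, design = NULL, n_iter = 20000,
                      burnin = floor(n_iter / 4), thin = 10,
                      geom_p = 0.1, log_r_bound = log(100), seed = NULL) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, response)
  if (stats::sd(y) == 0) stop("constant response: zero variance")
  if (!is.null(seed)) set.seed(seed)
  n <- length(y)
  ctx <- .bm_context(tree)
  base_len <- tree$edge.length[ctx$order]
  ne <- nrow(tree$edge)
  clades <- .clade_edges(tree)                  # per internal node, edge rows
  # scalar "locations": branches 1..ne, then clades ne+1..ne+Nnode
  n_loc <- ne + tree$Nnode
  loc_edges <- c(lapply(seq_len(ne), identity), clades)
  # map edge rows -> postorder position once
  po_pos <- match(seq_len(ne), ctx$order)

  has_design <- !is.null(design)
  if (has_design) {
    X <- as.matrix(design)
    if (nrow(X) != n) stop("design rows must align with tips")
    if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  } else X <- NULL

  log_eff <- rep(0, ne)                          # effective log r per edge row
  active <- integer(0)                           # active locations
  vals <- numeric(0)                             # log r at active locations
  sigma2 <- stats::var(y) / max(node_ages(tree))
  beta <- if (has_design) rep(0, ncol(X)) else mean(y)

  resid <- function(beta) if (has_design) y - drop(X %*% beta) else y
  loglik <- function(log_eff, sigma2, beta) {
    lens <- base_len * exp(log_eff[ctx$order])
    bm_prune_cpp(ctx$edge, lens * sigma2, ctx$ntip, resid(beta),
                 if (has_design) 0 else beta, TRUE)
  }
  gibbs_beta <- function(log_eff, sigma2) {
    phy <- tree
    phy$edge.length <- tree$edge.length * exp(log_eff)
    C <- ape::vcv(phy)
    R <- chol(C)
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    XtX <- crossprod(Xw)
    bhat <- solve(XtX, crossprod(Xw, yw))
    L <- chol(solve(XtX))
    drop(bhat + sqrt(sigma2) * crossprod(L, stats::rnorm(ncol(X))))
  }

  ll <- loglik(log_eff, sigma2, beta)
  lp_k <- function(k) k * log(1 - geom_p)        # geometric prior, unnormalized
  keep <- (n_iter - burnin) %/% thin
  sc_out <- matrix(NA_real_, keep, ne)
  par_names <- c("sigma2", if (has_design) colnames(X) else "root_mean",
                 "k", "loglik")
  samp_out <- matrix(NA_real_, keep, length(par_names),
                     dimnames = list(NULL, par_names))
  ki <- 0
  apply_loc <- function(log_eff, loc, delta) {
    e <- loc_edges[[loc]]
    log_eff[e] <- log_eff[e] + delta
    log_eff
  }
  for (it in seq_len(n_iter)) {
    move <- sample.int(5, 1)                     # 1 sigma2, 2 beta, 3 value, 4 birth, 5 death
    if (move == 1) {
      s2p <- sigma2 * exp(stats::rnorm(1, 0, 0.3))
      llp <- loglik(log_eff, s2p, beta)
      # Jeffreys prior 1/sigma2; log-scale proposal Jacobian cancels it to log s2p' - log s2p... keep explicit:
      if (log(stats::runif(1)) < llp - ll) { sigma2 <- s2p; ll <- llp }
    } else if (move == 2) {
      if (has_design) {
        beta <- gibbs_beta(log_eff, sigma2)
        ll <- loglik(log_eff, sigma2, beta)
      } else {
        bp <- beta + stats::rnorm(1, 0, 0.2 * stats::sd(y))
        llp <- loglik(log_eff, sigma2, bp)
        if (log(stats::runif(1)) < llp - ll) { beta <- bp; ll <- llp }
      }
    } else if (move == 3 && length(active)) {
      i <- sample.int(length(active), 1)
      old <- vals[i]
      new <- old + stats::rnorm(1, 0, 0.4)
      if (abs(new) <= log_r_bound) {
        le_p <- apply_loc(apply_loc(log_eff, active[i], -old), active[i], new)
        llp <- loglik(le_p, sigma2, beta)
        if (log(stats::runif(1)) < llp - ll) {
          vals[i] <- new; log_eff <- le_p; ll <- llp
        }
      }
    } else if (move == 4) {                      # birth
      free <- setdiff(seq_len(n_loc), active)
      if (length(free)) {
        loc <- free[sample.int(length(free), 1)]
        v <- stats::runif(1, -log_r_bound, log_r_bound)
        le_p <- apply_loc(log_eff, loc, v)
        llp <- loglik(le_p, sigma2, beta)
        k <- length(active)
        # location-set prior uniform over k-subsets: the subset-count ratio
        # cancels the pick probabilities, leaving the geometric count prior
        lacc <- (llp - ll) + (lp_k(k + 1) - lp_k(k))
        if (log(stats::runif(1)) < lacc) {
          active <- c(active, loc); vals <- c(vals, v)
          log_eff <- le_p; ll <- llp
        }
      }
    } else if (move == 5 && length(active)) {    # death
      i <- sample.int(length(active), 1)
      le_p <- apply_loc(log_eff, active[i], -vals[i])
      llp <- loglik(le_p, sigma2, beta)
      k <- length(active)
      lacc <- (llp - ll) + (lp_k(k - 1) - lp_k(k))
      if (log(stats::runif(1)) < lacc) {
        active <- active[-i]; vals <- vals[-i]
        log_eff <- le_p; ll <- llp
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      ki <- ki + 1
      sc_out[ki, ] <- exp(log_eff)
      samp_out[ki, ] <- c(sigma2, beta, length(active), ll)
    }
  }
  structure(list(scalars = sc_out, samples = samp_out, tree = tree,
                 has_design = has_design, seed = seed),
            class = "vr_chain")
}

#' @export
print.vr_chain <- function(x, ...) {
  cat("VR reversible-jump chain:", nrow(x$scalars), "draws,",
      ncol(x$scalars), "branches\n")
  cat("  mean number of scalars:", round(mean(x$samples[, "k"]), 2), "\n")
  invisible(x)
}

#' Median scaled tree from a VR posterior
#'
#' A branch receives its posterior-median scalar when it is stretched or
#' compressed in more than `presence_threshold` of the posterior sample and
#' the median scalar magnitude exceeds `magnitude_threshold` (symmetrically:
#' median > threshold for stretches, median < 1/threshold for compressions);
#' otherwise the branch keeps `r = 1`.  Branches are also classified as
#' accelerated (`r > 1`), constant (`r = 1`) or decelerated (`r < 1`).
#'
#' @param chain a `"vr_chain"` from [vr_rjmcmc()].
#' @param presence_threshold fraction of draws in which the branch is scaled.
#' @param magnitude_threshold significance threshold on the median scalar.
#' @return the chain's tree as a [timetree()] with significant median
#'   scalars; attributes `"rate_class"` (factor per branch) and `"summary"`
#'   (data.frame: `branch_id`, `scaled_fraction`, `median_scalar`,
#'   `significant`, `r`, `rate_class`).
#' @export
summarize_scaled_tree <- function(chain, presence_threshold = 0.5,
                                  magnitude_threshold = 2) {
  if (!inherits(chain, "vr_chain")) stop("'chain' must be a vr_chain")
  S <- chain$scalars
  if (!nrow(S)) stop("empty chain")
  frac <- colMeans(S != 1)
  med <- apply(S, 2, stats::median)
  sig <- frac > presence_threshold &
    (med > magnitude_threshold | med < 1 / magnitude_threshold)
  r <- ifelse(sig, med, 1)
  cls <- factor(ifelse(r > 1, "accelerated", ifelse(r < 1, "decelerated", "constant")),
                levels = c("accelerated", "constant", "decelerated"))
  out <- timetree(chain$tree, scalar = r)
  attr(out, "rate_class") <- cls
  attr(out, "summary") <- data.frame(branch_id = seq_along(r),
                                     scaled_fraction = frac,
                                     median_scalar = med, significant = sig,
                                     r = r, rate_class = cls)
  out
}

#' Posterior rates for an a-priori branch partition (local transformation)
#'
#' Variable-rates model in which every branch belongs to one of a fixed set
#' of categories (e.g. the eight trait-defined lineage classes) and all
#' branches of a category share one rate scalar; the scalars are sampled
#' jointly with `sigma2` and the root state.  Only rate *ratios* between
#' categories are strongly identified, which is why downstream comparison
#' standardizes by each tree's minimum rate.
#'
#' @param tree a [timetree()].
#' @param response numeric tip values, named by tip label.
#' @param partition factor/character vector, one category per branch
#'   (rows of `tree$edge`).  Empty categories are dropped with a warning.
#' @param n_iter,burnin,thin chain settings.
#' @param log_r_bound log-uniform prior bound on each category scalar.
#' @param seed optional integer seed.
#' @return object of class `"partition_chain"`: `rates` (draws x categories
#'   matrix of scalars), `samples` (sigma2, root_mean, loglik),
#'   `category_medians`.
#' @export
partitioned_rates <- function(tree, response, partition, n_iter = 6000,
                              burnin = floor(n_iter / 4), thin = 5,
                              log_r_bound = log(100), seed = NULL) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, response)
  ne <- nrow(tree$edge)
  if (is.factor(partition)) {
    unused <- setdiff(levels(partition), as.character(unique(partition)))
    if (length(unused))
      warning("empty categories dropped: ", paste(unused, collapse = ", "))
  }
  partition <- as.character(partition)
  if (length(partition) != ne) stop("need one category per branch")
  cats <- sort(unique(partition))
  if (!is.null(seed)) set.seed(seed)
  ctx <- .bm_context(tree)
  base_len <- tree$edge.length[ctx$order]
  part_po <- partition[ctx$order]
  idx <- lapply(cats, function(cc) which(part_po == cc))
  logr <- stats::setNames(rep(0, length(cats)), cats)
  sigma2 <- stats::var(y) / max(node_ages(tree))
  root <- mean(y)
  lens_for <- function(logr) {
    l <- base_len
    for (j in seq_along(cats)) l[idx[[j]]] <- l[idx[[j]]] * exp(logr[j])
    l
  }
  ll_for <- function(logr, sigma2, root)
    bm_prune_cpp(ctx$edge, lens_for(logr) * sigma2, ctx$ntip, y, root, TRUE)
  ll <- ll_for(logr, sigma2, root)
  keep <- (n_iter - burnin) %/% thin
  rates <- matrix(NA_real_, keep, length(cats), dimnames = list(NULL, cats))
  samp <- matrix(NA_real_, keep, 3, dimnames = list(NULL, c("sigma2", "root_mean", "loglik")))
  ki <- 0
  for (it in seq_len(n_iter)) {
    for (j in seq_along(cats)) {
      prop <- logr
      prop[j] <- logr[j] + stats::rnorm(1, 0, 0.3)
      if (abs(prop[j]) > log_r_bound) next
      llp <- ll_for(prop, sigma2, root)
      if (log(stats::runif(1)) < llp - ll) { logr <- prop; ll <- llp }
    }
    s2p <- sigma2 * exp(stats::rnorm(1, 0, 0.3))
    llp <- ll_for(logr, s2p, root)
    if (log(stats::runif(1)) < llp - ll) { sigma2 <- s2p; ll <- llp }
    rp <- root + stats::rnorm(1, 0, 0.2 * stats::sd(y))
    llp <- ll_for(logr, sigma2, rp)
    if (log(stats::runif(1)) < llp - ll) { root <- rp; ll <- llp }
    # recenter: move the common log-scalar scale into sigma2 (likelihood
    # invariant; keeps the scalars identified up to ratios away from the
    # prior bounds)
    shift <- mean(logr)
    if (all(abs(logr - shift) <= log_r_bound)) {
      logr <- logr - shift
      sigma2 <- sigma2 * exp(shift)
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      ki <- ki + 1
      rates[ki, ] <- exp(logr)
      samp[ki, ] <- c(sigma2, root, ll)
    }
  }
  structure(list(rates = rates, samples = samp, categories = cats,
                 category_medians = apply(rates, 2, stats::median),
                 tree = tree, seed = seed),
            class = "partition_chain")
}

#' @export
print.partition_chain <- function(x, ...) {
  cat("Partitioned-rates chain:", nrow(x$rates), "draws\n")
  print(round(x$category_medians, 3))
  invisible(x)
}
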