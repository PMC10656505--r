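# Brownian-motion phylogenetic likelihood (pruning), with Pagel's lambda
# and branch rate scalars.

# Postorder context reused across many likelihood evaluations.
.bm_context <- function(tree) {
  tree <- as_timetree(tree)
  po <- .postorder_parts(tree)
  ntip <- ape::Ntip(tree)
  # pendant flag and root-to-node distances on the *unscaled* tree are not
  # enough for the lambda transform once scalars change, so keep raw parts.
  list(tree = tree, edge = po$edge, order = po$order, ntip = ntip,
       is_pendant = po$edge[, 2] <= ntip)
}

# lambda transform of (already scalar-scaled) edge lengths:
# C_lambda = lambda * C + (1 - lambda) * diag(C); as a tree transform this
# multiplies internal edges by lambda and stretches each pendant edge so the
# tip's root-to-tip distance is preserved.
.lambda_lengths <- function(ctx, lens, lambda) {
  if (lambda == 1) return(lens)
  # root-to-node distances under `lens` (postorder edge order)
  ntot <- ctx$ntip + ctx$tree$Nnode
  depth <- numeric(ntot)
  ne <- nrow(ctx$edge)
  for (e in ne:1) depth[ctx$edge[e, 2]] <- depth[ctx$edge[e, 1]] + lens[e]
  out <- lens * lambda
  pend <- ctx$is_pendant
  tipd <- depth[ctx$edge[pend, 2]]
  out[pend] <- lens[pend] + (1 - lambda) * (tipd - lens[pend])
  out
}

# core evaluator: x in ape tip order, lens in postorder edge order
.bm_ll <- function(ctx, lens, sigma2, x, root_mean, lambda = 1) {
  lens <- .lambda_lengths(ctx, lens, lambda)
  bm_prune_cpp(ctx$edge, lens * sigma2, ctx$ntip, x,
               if (is.null(root_mean)) 0 else root_mean, !is.null(root_mean))
}

.match_tip_values <- function(tree, tip_values) {
  if (!is.null(names(tip_values))) {
    if (anyDuplicated(names(tip_values))) stop("duplicate tip names in values")
    miss <- setdiff(tree$tip.label, names(tip_values))
    if (length(miss)) stop("missing tip values: ", paste(miss, collapse = ", "))
    tip_values <- tip_values[tree$tip.label]
  } else if (length(tip_values) != ape::Ntip(tree)) {
    stop("tip_values must be named or have one value per tip")
  }
  if (any(!is.finite(tip_values))) stop("non-finite tip values")
  unname(tip_values)
}

#' Brownian-motion log likelihood of tip values on a time tree
#'
#' Log density of continuous tip values under Brownian motion with variance
#' `sigma2` per Ma, a fixed root state `root_mean`, per-branch rate scalars
#' (taken from the tree unless `use_scalars = FALSE`) and Pagel's lambda
#' transform.  Lambda multiplies the shared (off-diagonal) phylogenetic
#' covariance, leaving tip variances unchanged: `lambda = 1` is plain BM and
#' `lambda = 0` makes tips mutually independent.  Computed by Felsenstein
#' pruning in linear time; equals the dense multivariate-normal density.
#'
#' @param tree a [timetree()].
#' @param tip_values numeric, named by tip label (or in tip order).
#' @param sigma2 Brownian variance per Ma (> 0).
#' @param root_mean value at the root.
#' @param lambda phylogenetic signal in `[0, 1]`.
#' @param use_scalars multiply branch lengths by the tree's scalars?
#' @return log likelihood (nats).
#' @export
bm_loglik <- function(tree, tip_values, sigma2, root_mean, lambda = 1,
                      use_scalars = TRUE) {
  tree <- as_timetree(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (lambda < 0 || lambda > 1) stop("lambda must be in [0, 1]")
  x <- .match_tip_values(tree, tip_values)
  ctx <- .bm_context(tree)
  sc <- if (use_scalars) branch_scalars(tree)[ctx$order] else 1
  lens <- tree$edge.length[ctx$order] * sc
  .bm_ll(ctx, lens, sigma2, x, root_mean, lambda)
}

# dense phylogenetic covariance of the scalar-scaled tree (tips only)
.scaled_vcv <- function(tree, use_scalars = TRUE) {
  phy <- as_timetree(tree)
  if (use_scalars) phy$edge.length <- phy$edge.length * branch_scalars(phy)
  ape::vcv(phy)
}
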