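# Ancestral depth reconstruction: predictive modeling on a rate-scaled,
# false-tip-augmented tree, plus minimum-depth back-calculation.

.merge_group_matrix <- function(G, merge) {
  # G: rows x 4 (AS, AC, ZS, ZC) weights; merge: named list of column sets
  out <- sapply(merge, function(cols) rowSums(G[, cols, drop = FALSE]))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(merge)))
  out
}

#' Reconstruct ancestral depths at internal nodes
#'
#' Phylogenetic predictive modeling of ancestral log10 depths: zero-length
#' false tips are grafted at every internal node of the rate-scaled tree and
#' node depths are predicted from a regression of depth on the path-wise
#' rate (root-to-node distance on the scaled tree) with group-specific
#' intercepts and slopes.  Real tips are coded 0/1 (0.5 for facultative
#' species); false tips are soft-coded with the node's posterior state
#' probabilities, with ZS and ZC merged (their probabilities summed) since
#' those groups showed no separate trend.  Predictions are the phylogenetic
#' conditional means given the fitted model (so reconstruction honours both
#' the regression and the residual covariance), with posterior spread over a
#' subset of the regression draws.  Median and maximum depth are
#' reconstructed in two separate fits; any node where the reconstructed
#' median exceeds the maximum is reconciled by swapping (and logged).
#'
#' @param tree a [timetree()] whose scalars are the significant median
#'   scalars (see [summarize_scaled_tree()]).
#' @param tip_median_log,tip_max_log observed log10 median/maximum depth per
#'   tip, named by tip label.
#' @param node_probs nodes x 4 state posteriors from
#'   [node_state_posteriors()] (all ape node indices).
#' @param tip_groups character group per tip (AS/AC/ZS/ZC), named by tip.
#' @param tip_facultative `NA`, `"symbiosis"` or `"coloniality"` per tip.
#' @param merge named list mapping merged group columns to state sets.
#' @param lambda passed to [pgls_regression()].
#' @param n_iter MCMC iterations for each regression fit.
#' @param n_pred_draws posterior draws used for node prediction spread.
#' @param seed optional integer seed.
#' @return data.frame (one row per internal node): `node_id`, `age_ma`,
#'   `median_log`, `median_sd`, `max_log`, `max_sd`, `min_log`, `swapped`.
#'   Attributes: `"fits"` (the two `pgls_fit`s), `"design"`.
#' @export
reconstruct_node_depths <- function(tree, tip_median_log, tip_max_log,
                                    node_probs, tip_groups,
                                    tip_facultative = NA,
                                    merge = list(AS = "AS", AC = "AC",
                                                 ZSZC = c("ZS", "ZC")),
                                    lambda = "estimated", n_iter = 3000,
                                    n_pred_draws = 50, seed = NULL) {
  tree <- as_timetree(tree)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  if (nrow(node_probs) < ntip + nnode) stop("missing node posteriors")
  y_med <- .match_tip_values(tree, tip_median_log)
  y_max <- .match_tip_values(tree, tip_max_log)
  if (!is.null(names(tip_groups))) tip_groups <- tip_groups[tree$tip.label]

  aug <- attach_false_tips(tree)
  host_map <- attr(aug, "host_map")
  pw_aug <- path_wise_distance(aug, use_scalars = TRUE)
  pw_real <- pw_aug[seq_len(ntip)]
  pw_false <- pw_aug[host_map$false_tip]

  G_real <- build_design_matrix(tip_groups, tip_facultative)
  G_real_m <- .merge_group_matrix(G_real, merge)
  G_false <- node_probs[host_map$host_orig, , drop = FALSE]
  G_false_m <- .merge_group_matrix(G_false, merge)
  present <- colSums(G_real_m) > 0
  if (!all(present)) {
    warning("groups with no tips dropped from the reconstruction design: ",
            paste(names(merge)[!present], collapse = ", "))
    # fold the empty groups' node probabilities into the remaining groups
    G_false_m <- G_false_m[, present, drop = FALSE]
    G_false_m <- G_false_m / pmax(rowSums(G_false_m), 1e-12)
    G_real_m <- G_real_m[, present, drop = FALSE]
    merge <- merge[present]
  }
  # a group slope is only identifiable when its tips differ in path-wise
  # distance; on an unscaled ultrametric tree (or for a group untouched by
  # any scalar) the slope column is collinear with the group intercept
  slope_ok <- vapply(seq_along(merge), function(j) {
    w <- G_real_m[, j] > 0
    sum(w) > 1 && stats::sd(pw_real[w]) > 1e-10
  }, TRUE)
  if (!any(slope_ok))
    warning("path-wise distances are constant within every group ",
            "(unscaled ultrametric tree?): fitting group intercepts only")
  mk_design <- function(G, pw) {
    X <- cbind(G, (G * pw)[, slope_ok, drop = FALSE])
    slope_nm <- if (any(slope_ok)) paste0("rate:", names(merge)[slope_ok]) else character(0)
    colnames(X) <- c(names(merge), slope_nm)
    X
  }
  X_real <- mk_design(G_real_m, pw_real)
  X_false <- mk_design(G_false_m, pw_false)

  # lambda-transformed covariance blocks on the augmented scaled tree
  Cfull <- .scaled_vcv(aug)
  o <- seq_len(ntip)
  f <- host_map$false_tip
  predict_nodes <- function(fit, y) {
    S <- fit$samples
    take <- unique(round(seq(1, nrow(S), length.out = min(n_pred_draws, nrow(S)))))
    p <- ncol(fit$design)
    pred <- matrix(NA_real_, length(f), length(take))
    cvar <- matrix(NA_real_, length(f), length(take))
    for (s in seq_along(take)) {
      b <- S[take[s], seq_len(p)]
      s2 <- S[take[s], "sigma2"]
      lam <- S[take[s], "lambda"]
      Cl <- lam * Cfull
      diag(Cl) <- diag(Cfull)
      R <- chol(Cl[o, o])
      resid <- y - drop(X_real %*% b)
      w <- backsolve(R, backsolve(R, resid, transpose = TRUE))
      Cfo <- Cl[f, o, drop = FALSE]
      pred[, s] <- drop(X_false %*% b) + drop(Cfo %*% w)
      # conditional (kriging) variance of the node value given the tips
      A <- backsolve(R, t(Cfo), transpose = TRUE)
      cvar[, s] <- s2 * pmax(diag(Cl)[f] - colSums(A^2), 0)
    }
    list(mean = apply(pred, 1, stats::median),
         sd = sqrt(apply(pred, 1, stats::var) + rowMeans(cvar)))
  }
  fit_med <- pgls_regression(tree, y_med, X_real, lambda = lambda,
                             n_iter = n_iter)
  fit_max <- pgls_regression(tree, y_max, X_real, lambda = lambda,
                             n_iter = n_iter)
  pm <- predict_nodes(fit_med, y_med)
  px <- predict_nodes(fit_max, y_max)
  med <- pm$mean; mx <- px$mean
  swapped <- med > mx
  if (any(swapped)) {
    tmp <- med[swapped]; med[swapped] <- mx[swapped]; mx[swapped] <- tmp
  }
  out <- data.frame(node_id = host_map$host_orig,
                    age_ma = node_ages(tree)[host_map$host_orig],
                    median_log = med, median_sd = pm$sd,
                    max_log = mx, max_sd = px$sd,
                    min_log = back_calculate_min_depth(med, mx),
                    swapped = swapped)
  attr(out, "fits") <- list(median = fit_med, max = fit_max)
  attr(out, "design") <- list(real = X_real, false = X_false)
  out
}

#' Back-calculate the minimum depth from median and maximum
#'
#' Minimum and maximum depths are taken to lie at the same *unlogged*
#' distance from the median, so `min = 2 * median - max` in meters; values
#' below 1 m (including negatives) are clamped to 1 m so the log10 minimum
#' is never negative.
#'
#' @param median_log,max_log log10 depths (m), vectorized.
#' @return log10 minimum depth (m).
#' @export
back_calculate_min_depth <- function(median_log, max_log) {
  if (any(median_log > max_log + 1e-12)) stop("median depth exceeds maximum")
  med <- 10^median_log
  mx <- 10^max_log
  mn <- pmax(2 * med - mx, 1)
  log10(mn)
}

#' Phylomorphospace table of all nodes and tips
#'
#' One row per tip and internal node (2n - 1 rows for a binary n-tip tree)
#' with the depth interval, lineage category of the branch that originates
#' the node, and rate class — the tabular form of the phylomorphospace
#' projection (depth against node age).
#'
#' @param tree a [timetree()].
#' @param node_depths data.frame from [reconstruct_node_depths()].
#' @param tip_median_log,tip_max_log observed tip log10 depths (named).
#' @param tip_min_log optional observed tip log10 minimum depths; default
#'   back-calculated from median and maximum.
#' @param branch_categories optional data.frame from [classify_branches()];
#'   a node inherits the category of its stem branch (root: `NA`).
#' @param rate_class optional factor per branch (see
#'   [summarize_scaled_tree()]); a node inherits its stem branch's class
#'   (root: `"constant"`).
#' @return data.frame with `node_id`, `is_tip`, `label`, `age_ma`,
#'   `min_log`, `median_log`, `max_log`, `category`, `rate_class`.
#' @export
phylomorphospace_table <- function(tree, node_depths, tip_median_log,
                                   tip_max_log, tip_min_log = NULL,
                                   branch_categories = NULL,
                                   rate_class = NULL) {
  tree <- as_timetree(tree)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  if (!all((ntip + 1):ntot %in% node_depths$node_id))
    stop("node_depths must cover every internal node")
  y_med <- .match_tip_values(tree, tip_median_log)
  y_max <- .match_tip_values(tree, tip_max_log)
  y_min <- if (is.null(tip_min_log)) back_calculate_min_depth(y_med, y_max)
           else .match_tip_values(tree, tip_min_log)
  ages <- node_ages(tree)
  med <- mx <- mn <- numeric(ntot)
  med[seq_len(ntip)] <- y_med; mx[seq_len(ntip)] <- y_max; mn[seq_len(ntip)] <- y_min
  ii <- node_depths$node_id
  med[ii] <- node_depths$median_log; mx[ii] <- node_depths$max_log
  mn[ii] <- node_depths$min_log
  stem_of <- match(seq_len(ntot), tree$edge[, 2])   # edge whose child is the node
  cat_v <- rep(NA_character_, ntot)
  if (!is.null(branch_categories))
    cat_v[!is.na(stem_of)] <- branch_categories$category[stem_of[!is.na(stem_of)]]
  rc <- rep("constant", ntot)
  if (!is.null(rate_class))
    rc[!is.na(stem_of)] <- as.character(rate_class)[stem_of[!is.na(stem_of)]]
  data.frame(node_id = seq_len(ntot),
             is_tip = seq_len(ntot) <= ntip,
             label = c(tree$tip.label, rep(NA_character_, tree$Nnode)),
             age_ma = ages, min_log = mn, median_log = med, max_log = mx,
             category = cat_v, rate_class = rc,
             stringsAsFactors = FALSE)
}
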