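# PAD direction statistics, cross-tree partition-rate comparison,
# long-term trend regressions and the depth-vs-scalar association.

#' Phylogenetic ancestor-descendant depth deltas
#'
#' One comparison per branch: the change in log10 depth (descendant minus
#' ancestor) for the minimum and maximum range limits, with a direction
#' label (`shallower` for negative deltas, `deeper` for positive, `none`
#' for exact zeros).  Deltas telescope: summed along any root-to-tip path
#' they equal tip minus root depth.
#'
#' @param tree a [timetree()].
#' @param min_log,max_log log10 min/max depth for *every* node (ape indices,
#'   tips included), e.g. assembled by [phylomorphospace_table()].
#' @param categories optional category per branch (e.g.
#'   `classify_branches()$category`).
#' @return data.frame: `branch_id`, `ancestor`, `descendant`, `category`,
#'   `delta_min`, `delta_max`, `direction_min`, `direction_max`.
#' @export
compute_pad_deltas <- function(tree, min_log, max_log, categories = NULL) {
  tree <- as_timetree(tree)
  ntot <- ape::Ntip(tree) + tree$Nnode
  if (length(min_log) != ntot || length(max_log) != ntot)
    stop("need a depth for every node and tip")
  if (any(!is.finite(min_log)) || any(!is.finite(max_log)))
    stop("missing depth at some node")
  pads <- enumerate_pads(tree)
  dmin <- min_log[pads$descendant] - min_log[pads$ancestor]
  dmax <- max_log[pads$descendant] - max_log[pads$ancestor]
  dir_of <- function(d) ifelse(d < 0, "shallower", ifelse(d > 0, "deeper", "none"))
  data.frame(pads,
             category = if (is.null(categories)) NA_character_ else categories,
             delta_min = dmin, delta_max = dmax,
             direction_min = dir_of(dmin), direction_max = dir_of(dmax),
             stringsAsFactors = FALSE)
}

#' Two-sided binomial test for directional depth change
#'
#' Tests whether shallower and deeper moves are equally likely (p = 0.5)
#' among the PAD comparisons, overall and per lineage category, separately
#' for the minimum and maximum depth limits.  Exact zero deltas are counted
#' as unchanged and excluded from the trials.
#'
#' @param pads data.frame from [compute_pad_deltas()].
#' @param by `"all"` for a single pooled test or `"category"`.
#' @param limit `"min"`, `"max"` or both.
#' @return data.frame: `category`, `limit`, `n_shallower`, `n_deeper`,
#'   `n_unchanged`, `n`, `prop_shallower`, `p_value` (NA when no non-zero
#'   deltas).
#' @export
binomial_direction_test <- function(pads, by = c("all", "category"),
                                    limit = c("min", "max")) {
  by <- match.arg(by)
  limit <- match.arg(limit, several.ok = TRUE)
  groups <- if (by == "all") list(all = pads) else
    split(pads, pads$category)
  rows <- list()
  for (g in names(groups)) {
    for (lim in limit) {
      d <- groups[[g]][[paste0("delta_", lim)]]
      ns <- sum(d < 0); nd <- sum(d > 0); nz <- sum(d == 0)
      p <- if (ns + nd == 0) NA_real_ else
        stats::binom.test(ns, ns + nd, p = 0.5)$p.value
      rows[[length(rows) + 1]] <- data.frame(
        category = g, limit = lim, n_shallower = ns, n_deeper = nd,
        n_unchanged = nz, n = ns + nd + nz,
        prop_shallower = if (ns + nd > 0) ns / (ns + nd) else NA_real_,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Compare partitioned colonization rates across a tree sample
#'
#' Takes per-tree posterior-median rates for each lineage category (rows =
#' trees, columns = categories), standardizes each tree by its minimum rate
#' (so the slowest category is exactly 1), log10-transforms, reports a
#' Shapiro-Wilk normality check descriptively, then tests for differences
#' with a Kruskal-Wallis omnibus test and post-hoc pairwise Wilcoxon
#' rank-sum tests with Holm adjustment.
#'
#' @param rate_matrix numeric matrix, trees x categories, of posterior
#'   median rates (e.g. stacked `partitioned_rates()$category_medians`).
#'   Categories absent (all NA) are dropped.
#' @param alpha significance level for the pairwise summary.
#' @return list: `standardized` (log10 standardized rates, trees x
#'   categories), `shapiro` (W, p), `kruskal` (chi-squared, df, p),
#'   `pairwise` (data.frame with raw and Holm-adjusted p per pair),
#'   `category_medians`.
#' @export
compare_partition_rates <- function(rate_matrix, alpha = 0.05) {
  M <- as.matrix(rate_matrix)
  if (is.null(colnames(M))) colnames(M) <- paste0("cat", seq_len(ncol(M)))
  drop <- apply(M, 2, function(x) all(is.na(x)))
  if (any(drop)) {
    warning("categories absent in all trees dropped: ",
            paste(colnames(M)[drop], collapse = ", "))
    M <- M[, !drop, drop = FALSE]
  }
  if (ncol(M) < 2 || nrow(M) < 2) stop("need >= 2 categories and >= 2 trees")
  std <- log10(M / apply(M, 1, min, na.rm = TRUE))
  vals <- as.vector(std)
  grp <- factor(rep(colnames(std), each = nrow(std)))
  ok <- !is.na(vals)
  sh <- if (sum(ok) >= 3 && sum(ok) <= 5000 && stats::sd(vals[ok]) > 0)
    stats::shapiro.test(vals[ok]) else NULL
  kw <- stats::kruskal.test(vals[ok], grp[ok])
  pw <- stats::pairwise.wilcox.test(vals[ok], grp[ok], p.adjust.method = "holm",
                                    exact = FALSE)
  pm <- pw$p.value
  pairs <- which(!is.na(pm), arr.ind = TRUE)
  pairwise <- data.frame(
    group1 = rownames(pm)[pairs[, 1]], group2 = colnames(pm)[pairs[, 2]],
    p_holm = pm[pairs], stringsAsFactors = FALSE)
  pairwise$significant <- pairwise$p_holm < alpha
  list(standardized = std,
       shapiro = if (is.null(sh)) NULL else
         list(W = unname(sh$statistic), p_value = sh$p.value),
       kruskal = list(chi_squared = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pairwise,
       category_medians = apply(std, 2, stats::median, na.rm = TRUE))
}

#' Long-term depth trend regressions by rate stratum
#'
#' Depth against node/tip age (Ma before present; larger = older), with
#' separate intercepts and slopes per lineage category, fitted separately
#' for the slow stratum (constant- plus decelerated-rate lineages, joined
#' because decelerations are rare) and the accelerated stratum.  Categories
#' with fewer than `min_branches` members in a stratum are excluded and
#' logged.  A negative slope means younger (more recent) lineages sit
#' shallower, i.e. a long-term trend toward shallow water.
#'
#' @param depth_log log10 depth per node/tip (root excluded upstream).
#' @param age_ma node/tip ages (Ma).
#' @param categories lineage category per node/tip.
#' @param rate_class `"accelerated"`, `"constant"` or `"decelerated"` per
#'   node/tip.
#' @param min_branches minimum members per category per stratum.
#' @param n_draws posterior draws per fit.
#' @param seed optional integer seed.
#' @return list with one element per stratum (`slow`, `accelerated`), each
#'   either `NULL` (empty stratum, with a warning) or a list holding the
#'   `pgls_fit` (non-phylogenetic Bayesian regression), `slopes` (posterior
#'   median slope per category), `slope_significance`
#'   ([posterior_crossing_significance()] per category) and
#'   `excluded_categories`.
#' @export
longterm_trend_regression <- function(depth_log, age_ma, categories,
                                      rate_class, min_branches = 10,
                                      n_draws = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(length(depth_log) == length(age_ma),
            length(categories) == length(depth_log),
            length(rate_class) == length(depth_log))
  stratum <- ifelse(rate_class == "accelerated", "accelerated", "slow")
  fit_stratum <- function(keep) {
    if (!any(keep)) return(NULL)
    d <- depth_log[keep]; a <- age_ma[keep]; g <- categories[keep]
    tab <- table(g)
    excl <- names(tab)[tab < min_branches]
    use <- !(g %in% excl)
    if (!any(use) || length(unique(g[use])) < 1) return(NULL)
    g <- factor(g[use]); d <- d[use]; a <- a[use]
    G <- vapply(levels(g), function(L) as.numeric(g == L), numeric(length(g)))
    if (is.null(dim(G))) G <- matrix(G, ncol = nlevels(g))
    colnames(G) <- levels(g)
    X <- cbind(G, G * a)
    colnames(X) <- c(levels(g), paste0("age:", levels(g)))
    fit <- .bayes_lm(d, X, n_draws = n_draws)
    slope_cols <- paste0("age:", levels(g))
    sig <- lapply(slope_cols, function(cc)
      posterior_crossing_significance(fit$samples[, cc]))
    names(sig) <- levels(g)
    list(fit = fit,
         slopes = fit$coefficients[slope_cols],
         slope_significance = sig,
         excluded_categories = excl, n = sum(use))
  }
  out <- list(slow = fit_stratum(stratum == "slow"),
              accelerated = fit_stratum(stratum == "accelerated"))
  if (is.null(out$slow)) warning("empty slow stratum: skipped")
  if (is.null(out$accelerated)) warning("empty accelerated stratum: skipped")
  out
}

#' Maximum depth predicted by the branch rate scalar
#'
#' Bayesian regression of maximum log10 depth at nodes/tips on the rate
#' scalar of the branch that originates them, with lineage categories as
#' co-variables.  The slope is d(max log10 depth)/d(scalar): a negative
#' slope means accelerated colonization becomes scarcer with increasing
#' depth, i.e. fast colonization is concentrated in (relatively) shallower
#' water.  Categories listed in
#' `exclude` (e.g. groups with too few detected accelerations) are dropped.
#'
#' @param max_depth_log maximum log10 depth per node/tip.
#' @param scalar branch scalar per node/tip (stem-branch scalar).
#' @param categories lineage category per node/tip.
#' @param exclude categories to drop before fitting.
#' @param n_draws posterior draws.
#' @param seed optional integer seed.
#' @return list with the `pgls_fit`, the scalar `slope`, its
#'   [posterior_crossing_significance()], and `n`.
#' @export
depth_vs_scalar_regression <- function(max_depth_log, scalar, categories,
                                       exclude = character(), n_draws = 2000,
                                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- !(categories %in% exclude) & !is.na(categories)
  if (!any(scalar[keep] > 1))
    warning("no accelerated branches in the data; fitting on the full set")
  d <- max_depth_log[keep]; s <- scalar[keep]
  g <- factor(categories[keep])
  X <- if (nlevels(g) > 1) {
    G <- stats::model.matrix(~ g - 1)
    colnames(G) <- levels(g)
    cbind(G, scalar = s)
  } else cbind(intercept = rep(1, length(d)), scalar = s)
  fit <- .bayes_lm(d, X, n_draws = n_draws)
  list(fit = fit, slope = unname(fit$coefficients["scalar"]),
       significance = posterior_crossing_significance(fit$samples[, "scalar"]),
       n = sum(keep))
}

#' Association between current depth and path-wise rate
#'
#' Phylogenetic regression (lambda estimated) of current log10 depth on the
#' path-wise rate — the root-to-tip distance on the rate-scaled tree — with
#' group-specific intercepts and slopes.  A significant negative slope for
#' a group means its shallow species got there through historically faster
#' colonization.  Groups with fewer than 3 tips are excluded.
#'
#' @param tree a rate-scaled [timetree()].
#' @param tip_depth_log current log10 depth per tip (named).
#' @param tip_groups group per tip (AS/AC/ZS/ZC), named by tip.
#' @param tip_facultative facultative flags per tip.
#' @param lambda,n_iter,seed passed to [pgls_regression()].
#' @return list with the `pgls_fit`, `slopes`, `slope_significance` per
#'   group and `excluded_groups`.
#' @export
pathwise_depth_association <- function(tree, tip_depth_log, tip_groups,
                                       tip_facultative = NA,
                                       lambda = "estimated", n_iter = 4000,
                                       seed = NULL) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, tip_depth_log)
  if (!is.null(names(tip_groups))) tip_groups <- tip_groups[tree$tip.label]
  ntip <- ape::Ntip(tree)
  pw <- path_wise_distance(tree, use_scalars = TRUE)[seq_len(ntip)]
  G <- build_design_matrix(tip_groups, tip_facultative)
  counts <- colSums(G > 0)
  excl <- names(counts)[counts < 3]
  usecol <- setdiff(colnames(G), excl)
  keep <- rowSums(G[, usecol, drop = FALSE]) > 0.999   # drop tips only in excluded groups
  G2 <- G[keep, usecol, drop = FALSE]
  # slopes are identifiable only for groups whose tips vary in path-wise rate
  slope_ok <- vapply(usecol, function(g) {
    w <- G2[, g] > 0
    sum(w) > 1 && stats::sd(pw[keep][w]) > 1e-10
  }, TRUE)
  X <- cbind(G2, (G2 * pw[keep])[, slope_ok, drop = FALSE])
  slope_nm <- if (any(slope_ok)) paste0("rate:", usecol[slope_ok]) else character(0)
  colnames(X) <- c(usecol, slope_nm)
  # bake the scalars into the branch lengths so the covariance survives pruning
  phy <- tree
  phy$edge.length <- tree$edge.length * branch_scalars(tree)
  phy$scalar <- NULL
  class(phy) <- "phylo"
  if (!all(keep)) phy <- ape::keep.tip(phy, tree$tip.label[keep])
  ord <- match(phy$tip.label, tree$tip.label[keep])
  fit <- pgls_regression(timetree(phy), y[keep][ord],
                         X[ord, , drop = FALSE],
                         lambda = lambda, n_iter = n_iter, seed = seed)
  slope_cols <- slope_nm
  sig <- lapply(slope_cols, function(cc)
    posterior_crossing_significance(fit$samples[, cc]))
  names(sig) <- usecol[slope_ok]
  list(fit = fit, slopes = fit$coefficients[slope_cols],
       slope_significance = sig, excluded_groups = excl)
}
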