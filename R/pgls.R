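# Bayesian phylogenetic regression (PGLS with sampled Pagel's lambda).

#' Dummy-coded design matrix for trait-defined groups
#'
#' Standard dummy (one column per group, no reference level) coding of the
#' four symbiosis/coloniality groups.  Facultative species — present in
#' populations of both states of one trait — contribute 0.5 to each of the
#' two groups they are part of (e.g. AC and ZC for a colonial species
#' facultative for symbiosis), so every row sums to 1.
#'
#' @param group character vector in `lineage_states()` (AS, AC, ZS, ZC);
#'   for a facultative species give the group of either compatible state.
#' @param facultative_for `NA` (ordinary species), `"symbiosis"` or
#'   `"coloniality"`, recycled as needed.
#' @return numeric matrix (n x 4) with columns AS, AC, ZS, ZC.
#' @export
build_design_matrix <- function(group, facultative_for = NA) {
  states <- lineage_states()
  if (any(!group %in% states))
    stop("unknown group: ", paste(setdiff(group, states), collapse = ", "))
  fac <- rep_len(facultative_for, length(group))
  if (any(!is.na(fac) & !fac %in% c("symbiosis", "coloniality")))
    stop("facultative_for must be NA, 'symbiosis' or 'coloniality'")
  X <- matrix(0, length(group), 4, dimnames = list(names(group), states))
  flip_symb <- c(AS = "ZS", AC = "ZC", ZS = "AS", ZC = "AC")
  flip_col <- c(AS = "AC", AC = "AS", ZS = "ZC", ZC = "ZS")
  for (i in seq_along(group)) {
    if (is.na(fac[i])) {
      X[i, group[i]] <- 1
    } else {
      other <- if (fac[i] == "symbiosis") flip_symb[[group[i]]] else flip_col[[group[i]]]
      X[i, group[i]] <- 0.5
      X[i, other] <- 0.5
    }
  }
  X
}

#' Bayesian phylogenetic regression (PGLS) with Pagel's lambda
#'
#' Fits `response = X beta + eps`, `eps ~ N(0, sigma2 * C_lambda)` where `C`
#' is the phylogenetic covariance of the (scalar-scaled) tree and lambda
#' multiplies its off-diagonal part.  A phylogenetic ANOVA is the special
#' case of a group design matrix (see [build_design_matrix()]).  Sampling:
#' Gibbs for `beta` (flat prior) and `sigma2` (Jeffreys), random-walk
#' Metropolis for `lambda` (uniform prior on `[0, 1]`), unless `lambda` is
#' fixed numerically.
#'
#' @param tree a [timetree()]; its branch scalars are part of the covariance.
#' @param response numeric tip values, named by tip label.
#' @param design numeric design matrix (rows = tips, in tree tip order), or
#'   `NULL` for an intercept-only model.
#' @param lambda `"estimated"` or a fixed value in `[0, 1]`.
#' @param n_iter,burnin,thin chain settings (post-burn-in draws are
#'   `(n_iter - burnin) / thin`).
#' @param seed optional integer seed.
#' @return object of class `"pgls_fit"`: posterior `samples` (matrix with
#'   coefficient, `sigma2`, `lambda`, `loglik` columns), posterior-median
#'   `coefficients`, `lambda`, `r_squared` (on the lambda-whitened scale),
#'   and the inputs.
#' @export
pgls_regression <- function(tree, response, design = NULL,
                            lambda = "estimated", n_iter = 4000,
                            burnin = floor(n_iter / 4), thin = 2,
                            seed = NULL) {
  tree <- as_timetree(tree)
  y <- .match_tip_values(tree, response)
  n <- length(y)
  X <- if (is.null(design)) matrix(1, n, 1, dimnames = list(NULL, "intercept"))
       else as.matrix(design)
  if (nrow(X) != n) stop("design rows must align with tips")
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design matrix")
  est_lambda <- identical(lambda, "estimated")
  lam <- if (est_lambda) 0.5 else {
    if (!is.numeric(lambda) || lambda < 0 || lambda > 1)
      stop("lambda must be 'estimated' or a number in [0, 1]")
    lambda
  }
  if (!is.null(seed)) set.seed(seed)

  C <- .scaled_vcv(tree)
  dC <- diag(C)
  make_chol <- function(l) chol(l * C + (1 - l) * diag(dC, n))
  R <- make_chol(lam)

  gls_draw <- function(R, sigma2) {
    # beta | sigma2, lambda ~ N(beta_hat, sigma2 (X' C^-1 X)^-1)
    Xw <- backsolve(R, X, transpose = TRUE)
    yw <- backsolve(R, y, transpose = TRUE)
    XtX <- crossprod(Xw)
    bhat <- solve(XtX, crossprod(Xw, yw))
    L <- chol(solve(XtX))
    beta <- bhat + sqrt(sigma2) * crossprod(L, stats::rnorm(ncol(X)))
    rw <- yw - Xw %*% beta
    list(beta = drop(beta), rss = sum(rw^2), yw = yw, Xw = Xw)
  }
  ll_fun <- function(R, beta, sigma2) {
    rw <- backsolve(R, y - X %*% beta, transpose = TRUE)
    -0.5 * (n * log(2 * pi * sigma2) + 2 * sum(log(diag(R))) + sum(rw^2) / sigma2)
  }

  sigma2 <- stats::var(y) / mean(dC)
  beta <- rep(0, ncol(X))
  keep <- (n_iter - burnin) %/% thin
  samples <- matrix(NA_real_, keep, ncol(X) + 3,
                    dimnames = list(NULL, c(colnames(X), "sigma2", "lambda", "loglik")))
  k <- 0
  ll <- ll_fun(R, beta, sigma2)
  for (it in seq_len(n_iter)) {
    g <- gls_draw(R, sigma2)
    beta <- g$beta
    # sigma2 | beta ~ Inv-Gamma(n/2, rss/2) with Jeffreys prior
    rw <- g$yw - g$Xw %*% beta
    sigma2 <- sum(rw^2) / stats::rgamma(1, n / 2, 1 / 2)
    ll <- ll_fun(R, beta, sigma2)
    if (est_lambda) {
      lam_p <- lam + stats::rnorm(1, 0, 0.1)
      lam_p <- abs(lam_p); lam_p <- 2 * (lam_p > 1) * (1 - lam_p) + lam_p  # reflect
      if (lam_p >= 0 && lam_p <= 1) {
        Rp <- make_chol(lam_p)
        llp <- ll_fun(Rp, beta, sigma2)
        if (log(stats::runif(1)) < llp - ll) {
          lam <- lam_p; R <- Rp; ll <- llp
        }
      }
    }
    if (it > burnin && (it - burnin) %% thin == 0) {
      k <- k + 1
      samples[k, ] <- c(beta, sigma2, lam, ll)
    }
  }
  coef_med <- apply(samples[, seq_len(ncol(X)), drop = FALSE], 2, stats::median)
  lam_med <- stats::median(samples[, "lambda"])
  Rm <- make_chol(lam_med)
  yw <- backsolve(Rm, y, transpose = TRUE)
  fit_w <- backsolve(Rm, X %*% coef_med, transpose = TRUE)
  r2 <- 1 - sum((yw - fit_w)^2) / sum((yw - mean(yw))^2)
  structure(list(samples = samples, coefficients = coef_med,
                 lambda = lam_med, sigma2 = stats::median(samples[, "sigma2"]),
                 r_squared = max(0, min(1, r2)), n = n,
                 lambda_estimated = est_lambda, design = X),
            class = "pgls_fit")
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("Bayesian phylogenetic regression (", nrow(x$samples), " draws)\n", sep = "")
  cat("  coefficients (posterior medians):\n")
  print(round(x$coefficients, 4))
  cat("  lambda =", round(x$lambda, 3),
      if (x$lambda_estimated) "(estimated)" else "(fixed)",
      " sigma2 =", signif(x$sigma2, 4), "\n")
  cat("  R^2 =", round(x$r_squared, 3), " n =", x$n, "\n")
  invisible(x)
}

#' Equal-tailed credible interval from posterior samples
#' @param samples numeric vector of draws.
#' @param level credibility level.
#' @return length-2 vector (lower, upper).
#' @export
credible_interval <- function(samples, level = 0.9) {
  a <- (1 - level) / 2
  unname(stats::quantile(samples, c(a, 1 - a)))
}

# Conjugate Bayesian linear regression (flat prior on beta, Jeffreys on
# sigma2): exact posterior draws.  Used for the non-phylogenetic
# node/tip-level regressions (long-term trends, depth-vs-scalar).
.bayes_lm <- function(y, X, n_draws = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (qr(X)$rank < p) stop("rank-deficient design matrix")
  XtX <- crossprod(X)
  bhat <- solve(XtX, crossprod(X, y))
  rss <- sum((y - X %*% bhat)^2)
  Lc <- chol(solve(XtX))
  draws <- matrix(NA_real_, n_draws, p + 1,
                  dimnames = list(NULL, c(colnames(X), "sigma2")))
  for (i in seq_len(n_draws)) {
    s2 <- rss / stats::rgamma(1, (n - p) / 2, 1 / 2)
    b <- bhat + sqrt(s2) * crossprod(Lc, stats::rnorm(p))
    draws[i, ] <- c(b, s2)
  }
  r2 <- 1 - rss / sum((y - mean(y))^2)
  structure(list(samples = draws,
                 coefficients = apply(draws[, seq_len(p), drop = FALSE], 2, stats::median),
                 lambda = 0, sigma2 = stats::median(draws[, p + 1]),
                 r_squared = max(0, min(1, r2)), n = n,
                 lambda_estimated = FALSE, design = X),
            class = "pgls_fit")
}
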