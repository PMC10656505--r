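test_that("with no active scalars the chain likelihood equals bm_loglik", {
  tr <- simulate_tree(25, seed = 401)
  sim <- simulate_depth(tr, sigma2 = 0.02, root_depth_log = 3, seed = 402)
  ch <- vr_rjmcmc(tr, sim$tip_depths, n_iter = 2000, burnin = 500, thin = 5,
                  seed = 3)
  k0 <- which(ch$samples[, "k"] == 0)
  expect_gt(length(k0), 0)
  for (i in head(k0, 5)) {
    expect_equal(unname(ch$samples[i, "loglik"]),
                 bm_loglik(tr, sim$tip_depths, ch$samples[i, "sigma2"],
                           ch$samples[i, "root_mean"]),
                 tolerance = 1e-10)
  }
  expect_error(vr_rjmcmc(tr, stats::setNames(rep(1, 25), tr$tip.label)),
               "constant")
})

test_that("a clade simulated at r = 25 is detected as accelerated", {
  tt <- simulate_tree(60, seed = 403)
  cl <- coraldepth:::.clade_edges(tt)
  sizes <- vapply(cl, length, 1L)
  edges <- cl[[which(sizes >= 8 & sizes <= 16)[1]]]
  trs <- timetree(tt, replace(rep(1, ape::Nedge(tt)), edges, 25))
  sim <- simulate_depth(trs, sigma2 = 0.005, root_depth_log = 3, seed = 404)
  ch <- vr_rjmcmc(tt, sim$tip_depths, n_iter = 15000, burnin = 4000,
                  thin = 10, seed = 4)
  sm <- attr(summarize_scaled_tree(ch), "summary")
  expect_gt(stats::median(sm$median_scalar[edges]), 2)
  # single-replicate bound; the averaged false-flag rate is checked in the
  # dedicated type-I simulations
  expect_lt(mean(sm$significant[-edges]), 0.25)
})

test_that("the median-tree significance rule follows presence and magnitude", {
  tt <- simulate_tree(4, seed = 405)
  ne <- ape::Nedge(tt)
  draws <- 100
  S <- matrix(1, draws, ne)
  S[1:60, 1] <- 3                     # scaled to 3 in 60% -> flagged, r = 3
  S[1:40, 2] <- 3                     # 40% presence -> r = 1
  S[1:90, 3] <- 1.5                   # magnitude below 2 -> r = 1
  S[1:80, 4] <- 0.2                   # compression, median 0.2 -> flagged
  ch <- structure(list(scalars = S,
                       samples = matrix(0, draws, 4,
                                        dimnames = list(NULL, c("sigma2", "root_mean", "k", "loglik"))),
                       tree = tt, has_design = FALSE, seed = 1),
                  class = "vr_chain")
  st <- summarize_scaled_tree(ch)
  r <- branch_scalars(st)
  expect_equal(r[1], 3)
  expect_equal(r[2], 1)
  expect_equal(r[3], 1)
  expect_equal(r[4], 0.2)
  expect_equal(as.character(attr(st, "rate_class"))[1:4],
               c("accelerated", "constant", "constant", "decelerated"))
})

test_that("partitioned rates recover a 10x ratio and reduce for one category", {
  tt <- simulate_tree(80, seed = 406)
  set.seed(407)
  part <- sample(c("A", "B"), ape::Nedge(tt), replace = TRUE)
  sim <- simulate_depth(timetree(tt, ifelse(part == "B", 10, 1)),
                        sigma2 = 0.01, root_depth_log = 3, seed = 408)
  pr <- partitioned_rates(tt, sim$tip_depths, part, n_iter = 5000, seed = 5)
  ratio <- pr$category_medians["B"] / pr$category_medians["A"]
  expect_gt(ratio, 5); expect_lt(ratio, 20)

  # single category: scalar and sigma2 are confounded, but the implied total
  # rate (scalar x sigma2) matches the maximum-likelihood BM rate
  sim0 <- simulate_depth(tt, sigma2 = 0.02, root_depth_log = 3, seed = 409)
  pr0 <- partitioned_rates(tt, sim0$tip_depths,
                           rep("all", ape::Nedge(tt)), n_iter = 4000,
                           seed = 6)
  eff <- stats::median(pr0$rates[, "all"] * pr0$samples[, "sigma2"])
  grid <- seq(0.005, 0.08, by = 0.0005)
  ll <- vapply(grid, function(s2)
    bm_loglik(tt, sim0$tip_depths, s2, mean(sim0$tip_depths)), numeric(1))
  s2_ml <- grid[which.max(ll)]
  expect_equal(eff, s2_ml, tolerance = 0.35)
  expect_warning(partitioned_rates(tt, sim0$tip_depths,
                                   factor(rep("all", ape::Nedge(tt)),
                                          levels = c("all", "ghost")),
                                   n_iter = 200, seed = 7),
                 "empty")
})

test_that("all-equal partitions give rates within a factor two of each other", {
  # branch counts near the study scale: per-category rate precision grows
  # with the number of branches per category
  ok <- vapply(1:10, function(i) {
    tt <- simulate_tree(200, seed = 410 + i)
    set.seed(420 + i)
    part <- sample(c("A", "B", "C"), ape::Nedge(tt), replace = TRUE)
    sim <- simulate_depth(tt, sigma2 = 0.01, root_depth_log = 3,
                          seed = 430 + i)
    pr <- partitioned_rates(tt, sim$tip_depths, part, n_iter = 6000,
                            seed = i)
    m <- pr$category_medians
    max(m) / min(m) < 2
  }, TRUE)
  expect_gte(mean(ok), 0.9)
})
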