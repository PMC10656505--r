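test_that("PAD deltas carry sign conventions, counts and telescoping", {
  tr <- simulate_tree(30, seed = 901)
  sim <- simulate_depth(tr, sigma2 = 0.05, root_depth_log = 3, seed = 902)
  x <- sim$node_depths
  pads <- compute_pad_deltas(tr, x, x + 0.2)
  expect_equal(nrow(pads), ape::Nedge(tr))
  expect_true(all(pads$direction_min[pads$delta_min < 0] == "shallower"))
  expect_true(all(pads$direction_min[pads$delta_min > 0] == "deeper"))
  root <- 31
  tip <- 4
  path_sum <- 0
  node <- tip
  while (node != root) {
    e <- which(tr$edge[, 2] == node)
    path_sum <- path_sum + pads$delta_min[e]
    node <- tr$edge[e, 1]
  }
  expect_equal(path_sum, x[tip] - x[root], tolerance = 1e-12)
  expect_error(compute_pad_deltas(tr, x[-1], x[-1]), "every node")
})

test_that("binomial direction test matches closed forms and partitions counts", {
  mk <- function(dmin) data.frame(branch_id = seq_along(dmin),
                                  ancestor = 1, descendant = 2,
                                  category = "AS",
                                  delta_min = dmin, delta_max = dmin,
                                  direction_min = "x", direction_max = "x")
  r1 <- binomial_direction_test(mk(c(rep(-1, 0), rep(1, 8))), limit = "min")
  expect_equal(r1$p_value, 2 * 0.5^8, tolerance = 1e-12)   # 0 of 8
  r2 <- binomial_direction_test(mk(c(rep(-1, 5), rep(1, 5))), limit = "min")
  expect_equal(r2$p_value, 1)
  r3 <- binomial_direction_test(mk(c(-1, -2, 0, 0, 3)), limit = "min")
  expect_equal(r3$n_shallower + r3$n_deeper + r3$n_unchanged, 5L)
  expect_equal(r3$n_unchanged, 2L)
  r0 <- binomial_direction_test(mk(c(0, 0)), limit = "min")
  expect_true(is.na(r0$p_value))
  # enumeration oracle for n <= 20
  for (n in c(5, 11, 20)) {
    for (k in c(0, 2, floor(n / 2))) {
      d <- c(rep(-1, k), rep(1, n - k))
      got <- binomial_direction_test(mk(d), limit = "min")$p_value
      dens <- stats::dbinom(0:n, n, 0.5)
      expect_equal(got, sum(dens[dens <= stats::dbinom(k, n, 0.5) + 1e-12]),
                   tolerance = 1e-9)
    }
  }
})

test_that("per-category tests run on both limits", {
  set.seed(903)
  pads <- data.frame(branch_id = 1:40, ancestor = 1, descendant = 2,
                     category = rep(c("AS", "ZC"), 20),
                     delta_min = rnorm(40), delta_max = rnorm(40))
  out <- binomial_direction_test(pads, by = "category")
  expect_equal(nrow(out), 4L)
  expect_setequal(unique(out$category), c("AS", "ZC"))
})

test_that("standardized rates hit the worked example and Holm is monotone", {
  M <- rbind(c(2, 4, 8), c(3, 6, 12))
  colnames(M) <- c("a", "b", "c")
  res <- compare_partition_rates(M)
  expect_equal(unname(res$standardized[1, ]), c(0, log10(2), log10(4)),
               tolerance = 1e-12)
  expect_equal(unname(apply(res$standardized, 1, min)), c(0, 0))
  set.seed(904)
  p_raw <- runif(8)
  p_holm <- p.adjust(sort(p_raw), "holm")
  expect_true(all(diff(p_holm) >= -1e-15))
  expect_true(all(p_holm >= sort(p_raw)))
})

test_that("a 10x category is detected across trees; the omnibus controls size", {
  set.seed(905)
  hits <- replicate(10, {
    M <- matrix(exp(rnorm(50 * 4, 0, 0.4)), 50, 4)
    M[, 3] <- M[, 3] * 10
    colnames(M) <- c("AS", "AC", "ZS", "ZC")
    res <- compare_partition_rates(M)
    res$kruskal$p_value < 0.05 &&
      names(which.max(res$category_medians)) == "ZS"
  })
  expect_gte(mean(hits), 0.9)
  null_rej <- replicate(60, {
    M <- matrix(exp(rnorm(40 * 4, 0, 0.4)), 40, 4)
    colnames(M) <- c("AS", "AC", "ZS", "ZC")
    compare_partition_rates(M)$kruskal$p_value < 0.05
  })
  expect_lte(mean(null_rej), 0.1)
})

test_that("long-term trends recover a planted negative age slope", {
  set.seed(906)
  n <- 300
  age <- runif(n, 0, 400)
  cat <- sample(c("AS", "ZC"), n, replace = TRUE)
  rc <- sample(c("constant", "accelerated"), n, replace = TRUE)
  depth <- 1.5 + ifelse(cat == "AS", 0.003, 0) * age + rnorm(n, 0, 0.15)
  out <- longterm_trend_regression(depth, age, cat, rc, seed = 1)
  # positive depth-age slope for AS: older lineages deeper = shallowing trend
  for (stratum in c("slow", "accelerated")) {
    expect_gt(out[[stratum]]$slopes[["age:AS"]], 0)
    expect_true(out[[stratum]]$slope_significance$AS$significant)
    expect_false(out[[stratum]]$slope_significance$ZC$significant)
  }
})

test_that("categories under the membership floor are excluded", {
  set.seed(907)
  n <- 60
  age <- runif(n, 0, 100)
  cat <- c(rep("AS", 51), rep("UncS", 9))
  depth <- rnorm(n, 2, 0.2)
  out <- suppressWarnings(longterm_trend_regression(depth, age, cat,
                                                    rep("constant", n),
                                                    seed = 2))
  expect_equal(out$slow$excluded_categories, "UncS")
  expect_warning(
    longterm_trend_regression(depth, age, cat, rep("constant", n)),
    "accelerated")
})

test_that("depth-vs-scalar regression recovers a negative association", {
  set.seed(908)
  n <- 200
  depth <- runif(n, 1, 3.5)
  scalar <- pmax(0.2, 6 - 1.5 * depth + rnorm(n, 0, 0.4))
  cats <- sample(c("AS", "AC"), n, replace = TRUE)
  out <- depth_vs_scalar_regression(depth, scalar, cats, seed = 3)
  expect_lt(out$slope, 0)
  expect_true(out$significance$significant)
  flat <- depth_vs_scalar_regression(depth, rep(2, n) + rnorm(n, 0, 0.3),
                                     cats, seed = 4)
  expect_false(flat$significance$significant)
})

test_that("path-wise association flags only the group carrying signal", {
  tt <- simulate_tree(90, seed = 909)
  # heterogeneous terminal scalars so path-wise rates vary within groups
  # (a uniformly scaled clade keeps tips equidistant on an ultrametric tree)
  set.seed(910)
  term <- which(tt$edge[, 2] <= 90)
  sc <- rep(1, ape::Nedge(tt))
  boosted <- sample(term, 45)
  sc[boosted] <- runif(45, 2, 8)
  trs <- timetree(tt, sc)
  pw <- path_wise_distance(trs)[1:90]
  groups <- stats::setNames(rep("ZC", 90), tt$tip.label)
  groups[tt$edge[boosted, 2]] <- "AS"
  depth <- 3 - 0.3 * (pw - mean(pw)) * (groups == "AS") + rnorm(90, 0, 0.1)
  names(depth) <- tt$tip.label
  out <- pathwise_depth_association(trs, depth, groups, n_iter = 3000,
                                    seed = 5)
  expect_lt(out$slopes[["rate:AS"]], 0)
  expect_true(out$slope_significance$AS$significant)
})
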