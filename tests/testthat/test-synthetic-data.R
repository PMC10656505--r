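test_that("birth-death simulation is ultrametric, sized and seed-deterministic", {
  tr <- simulate_tree(510, seed = 11)
  expect_equal(ape::Ntip(tr), 510L)
  expect_equal(nrow(tr$edge), 1018L)
  expect_equal(ape::Ntip(tr) + tr$Nnode, 1019L)
  expect_true(ape::is.ultrametric(tr, tol = 1e-8))
  tr2 <- simulate_tree(510, seed = 11)
  expect_identical(write_timetree(tr), write_timetree(tr2))
  expect_error(simulate_tree(1), "n_tips")
  expect_error(simulate_tree(10, birth = 0.5, death = 0.7), "birth")
})

test_that("correlated-trait simulation respects Q structure and determinism", {
  tr <- simulate_tree(40, seed = 21)
  Q0 <- correlated_Q(rep(0, 8))
  sim <- simulate_correlated_traits(tr, Q0, root_state = "ZC", seed = 1)
  expect_true(all(sim$tip_states == "ZC"))
  expect_true(all(sim$node_states == "ZC"))

  Q <- correlated_Q(rep(0.4, 8))
  a <- simulate_correlated_traits(tr, Q, "AS", seed = 5)
  b <- simulate_correlated_traits(tr, Q, "AS", seed = 5)
  expect_identical(a, b)

  bad <- unclass(correlated_Q(rep(0.1, 8)))
  bad[1, 4] <- 0.2; bad[1, 1] <- -sum(bad[1, -1])
  expect_error(simulate_correlated_traits(tr, bad, "AS"), "dual")
})

test_that("long-branch tip states approach the stationary distribution of Q", {
  # star-like: many tips far from the root relative to 1/rate
  tr <- ape::stree(600, type = "star")
  tr$edge.length <- rep(50, 600)
  Q <- correlated_Q(c(0.5, 0.25, 0.3, 0.6, 0.45, 0.2, 0.35, 0.4))
  pi_eig <- stationary_distribution(Q)
  sim <- simulate_correlated_traits(timetree(tr), Q, "AS", seed = 31)
  freq <- table(factor(sim$tip_states, levels = lineage_states())) / 600
  expect_lt(max(abs(as.numeric(freq) - pi_eig)), 0.07)
})

test_that("depth simulation matches the Brownian closed form", {
  tr <- read_timetree("(A:4,B:4);")
  reps <- vapply(seq_len(400), function(i)
    simulate_depth(tr, sigma2 = 0.05, root_depth_log = 2, seed = 500 + i)$tip_depths[["A"]],
    numeric(1))
  expect_equal(stats::var(reps), 0.05 * 4, tolerance = 0.25)
  # a 25x scalar inflates increment variance 25-fold
  trs <- timetree(tr, c(25, 1))
  reps2 <- vapply(seq_len(400), function(i)
    simulate_depth(trs, sigma2 = 0.05, root_depth_log = 2, seed = 900 + i)$tip_depths,
    numeric(2))
  ratio <- stats::var(reps2["A", ]) / stats::var(reps2["B", ])
  expect_gt(ratio, 15); expect_lt(ratio, 40)
  # zero-length branch changes nothing
  trz <- read_timetree("(A:0,B:3);")
  sz <- simulate_depth(trz, sigma2 = 0.1, root_depth_log = 2, seed = 3)
  expect_equal(sz$tip_depths[["A"]], sz$node_depths[3])
})

test_that("group trends drift depths deterministically", {
  tr <- read_timetree("(A:10,B:10);")
  grp <- c("up", "flat")[order(tr$edge[, 2])]  # branch to A gets "up"
  reps <- vapply(seq_len(200), function(i)
    simulate_depth(tr, sigma2 = 1e-4, trend_beta = c(up = -0.05),
                   branch_groups = grp, root_depth_log = 3,
                   seed = 1500 + i)$tip_depths, numeric(2))
  expect_equal(mean(reps["A", ]), 3 - 0.5, tolerance = 0.02)
  expect_equal(mean(reps["B", ]), 3, tolerance = 0.02)
})

test_that("occurrence simulation plants labelled violations and is reproducible", {
  rt <- demo_range_table()
  out <- simulate_occurrences(rt, n_per_species = 10,
                              violations = c(bathy_mismatch = 3,
                                             photic_gap = 2, az_deep = 1),
                              seed = 41)
  occ <- out$occurrences
  expect_equal(sum(occ$violation == "bathy_mismatch"), 3L)
  expect_equal(sum(occ$violation == "photic_gap"), 2L)
  expect_equal(sum(occ$violation == "az_deep"), 1L)
  expect_equal(sum(occ$violation == ""), 10L * nrow(rt))
  # planted bathymetry mismatches really deviate by > 500 m from the grid
  bm <- occ[occ$violation == "bathy_mismatch", ]
  expect_true(all(abs(bm$depth - raster_depth_at(out$raster, bm$lon, bm$lat)) > 500))
  out2 <- simulate_occurrences(rt, n_per_species = 10,
                               violations = c(bathy_mismatch = 3,
                                              photic_gap = 2, az_deep = 1),
                               seed = 41)
  expect_identical(out$occurrences, out2$occurrences)
})

test_that("ascii raster round-trips through disk", {
  r <- make_bathymetry_raster(cell_size = 2)
  f <- tempfile(fileext = ".asc")
  write_ascii_raster(r, f)
  r2 <- read_ascii_raster(f)
  expect_equal(r2$depth, r$depth, tolerance = 1e-8)
  expect_equal(raster_depth_at(r2, 5.2, -3.7), raster_depth_at(r, 5.2, -3.7))
  unlink(f)
})
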