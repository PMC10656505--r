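make_traits <- function(rt) data.frame(species = rt$species,
                                       symbiotic = rt$symbiotic,
                                       stringsAsFactors = FALSE)

test_that("bathymetry, photic-gap and depth-cap rules fire on the book examples", {
  raster <- make_bathymetry_raster(lon_range = c(0, 10), lat_range = c(0, 10),
                                   cell_size = 10,
                                   depth_fun = function(lon, lat) rep(100, length(lon)))
  traits <- data.frame(species = c("az1", "z1"), symbiotic = c(FALSE, TRUE))
  # record at 700 m in a 100 m cell -> dropped (|600| > 500)
  occ <- data.frame(species = "az1", lon = 5, lat = 5, depth = 700)
  out <- apply_depth_filters(occ, raster, traits)
  expect_equal(nrow(out$kept), 0L)
  expect_equal(out$removal_log$rule, "bathymetry_mismatch")

  deep_raster <- make_bathymetry_raster(lon_range = c(0, 10), lat_range = c(0, 10),
                                        cell_size = 10,
                                        depth_fun = function(lon, lat) rep(500, length(lon)))
  # zooxanthellate depths {10, 50, 160, 170, 400}: 170 kept (gap 10 from 160),
  # 400 dropped (gap 230)
  occ2 <- data.frame(species = "z1", lon = 5, lat = 5,
                     depth = c(10, 50, 160, 170, 400))
  out2 <- apply_depth_filters(occ2, deep_raster, traits)
  expect_setequal(out2$kept$depth, c(10, 50, 160, 170))
  expect_equal(out2$removal_log$depth, 400)
  expect_equal(out2$removal_log$rule, "photic_gap")

  # azooxanthellate record at 6000 m -> dropped (> 5740)
  deep6 <- make_bathymetry_raster(lon_range = c(0, 10), lat_range = c(0, 10),
                                  cell_size = 10,
                                  depth_fun = function(lon, lat) rep(5900, length(lon)))
  occ3 <- data.frame(species = "az1", lon = 5, lat = 5, depth = c(5700, 6000))
  out3 <- apply_depth_filters(occ3, deep6, traits)
  expect_equal(out3$kept$depth, 5700)
  expect_equal(out3$removal_log$rule, "azoox_depth_cap")

  expect_error(apply_depth_filters(
    data.frame(species = "mystery", lon = 5, lat = 5, depth = 10),
    raster, traits), "mystery")
})

test_that("filtering is order-independent within a species", {
  raster <- make_bathymetry_raster(lon_range = c(0, 10), lat_range = c(0, 10),
                                   cell_size = 10,
                                   depth_fun = function(lon, lat) rep(300, length(lon)))
  traits <- data.frame(species = "z1", symbiotic = TRUE)
  depths <- c(400, 10, 170, 160, 50)
  occ <- data.frame(species = "z1", lon = 5, lat = 5, depth = depths)
  shuffled <- occ[c(3, 1, 5, 2, 4), ]
  shuffled$record_id <- NULL
  a <- apply_depth_filters(occ, raster, traits)
  b <- apply_depth_filters(shuffled, raster, traits)
  expect_setequal(a$kept$depth, b$kept$depth)
})

test_that("range summaries use the median, clamp sub-metre depths and zero the equator", {
  occ <- data.frame(species = rep(c("sp1", "sp2", "sp3"), times = c(3, 2, 2)),
                    lat = c(5, 8, 10, -10, 30, 12, 18),
                    depth = c(5, 10, 100, 0.4, 2, 7, 9))
  rs <- summarize_species_ranges(occ)
  sp1 <- rs[rs$species == "sp1", ]
  expect_equal(sp1$median_depth, 10)
  expect_equal(sp1$median_depth_log, 1)
  sp2 <- rs[rs$species == "sp2", ]
  expect_equal(sp2$min_depth_log, 0)       # 0.4 m clamps to 1 m
  expect_equal(sp2$min_lat, 0)             # crosses the equator
  expect_equal(sp2$max_lat, 30)
  sp3 <- rs[rs$species == "sp3", ]
  expect_equal(sp3$min_lat, 12)
})

test_that("dataset agreement recovers rank identity, antitone reversal and errors", {
  rt <- demo_range_table()
  occ <- simulate_occurrences(rt, n_per_species = 15, seed = 51)$occurrences
  ra <- summarize_species_ranges(occ)
  expect_equal(dataset_agreement(ra, ra)$rho, rep(1, 3))
  rb <- ra
  rb$min_depth_log <- -rb$min_depth_log
  rb$median_depth_log <- -rb$median_depth_log
  rb$max_depth_log <- -rb$max_depth_log
  expect_equal(dataset_agreement(ra, rb)$rho, rep(-1, 3))
  expect_error(dataset_agreement(ra[1:2, ], ra[1:2, ]), "3 shared")
})

test_that("independent range tables give small rho and roughly uniform p", {
  set.seed(61)
  ps <- replicate(60, {
    n <- 25
    a <- data.frame(species = paste0("s", 1:n),
                    min_depth_log = runif(n), median_depth_log = runif(n),
                    max_depth_log = runif(n))
    b <- data.frame(species = paste0("s", 1:n),
                    min_depth_log = runif(n), median_depth_log = runif(n),
                    max_depth_log = runif(n))
    dataset_agreement(a, b)$p_value[2]
  })
  expect_gt(mean(ps), 0.3)               # centred, not piled near 0
  expect_lt(mean(ps < 0.05), 0.15)       # ~5% nominal false positives
})

test_that("planted violations are fully recalled with zero false drops", {
  rt <- demo_range_table()
  out <- simulate_occurrences(rt, n_per_species = 25,
                              violations = c(bathy_mismatch = 4,
                                             photic_gap = 3, az_deep = 2),
                              seed = 71)
  res <- apply_depth_filters(out$occurrences, out$raster, make_traits(rt))
  planted <- out$occurrences$record_id[out$occurrences$violation != ""]
  dropped <- res$removal_log$record_id
  expect_setequal(dropped, planted)                 # recall 100%, precision 100%
  expect_equal(nrow(res$kept), sum(out$occurrences$violation == ""))
})
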