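#' Simulate an ultrametric birth-death time tree
#'
#' Conditions on the number of tips (grow-until-n) via [ape::rphylo()], so
#' fixtures have a fixed size; branch lengths are in Ma and all tip ages are
#' zero.  With a fixed seed the output is reproducible byte for byte.
#'
#' @param n_tips number of extant tips (>= 2).
#' @param birth,death speciation/extinction rates (events per Ma),
#'   `birth > death >= 0`.
#' @param seed optional integer seed.
#' @return a [timetree()] with all branch scalars 1.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = NULL) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_tips, birth = birth, death = death)
  timetree(phy)
}

#' Build a correlated two-trait rate matrix
#'
#' 4-state continuous-time Markov chain on the combined states
#' AS (azooxanthellate-solitary), AC (azooxanthellate-colonial),
#' ZS (zooxanthellate-solitary), ZC (zooxanthellate-colonial).  Only one
#' trait may change per event, so the two dual-transition entries
#' (AS<->ZC, AC<->ZS) are structurally zero; the 8 single-trait transition
#' rates are free.
#'
#' @param rates numeric vector of 8 non-negative rates, named or in the order
#'   `qAS.AC, qAC.AS, qAS.ZS, qZS.AS, qAC.ZC, qZC.AC, qZS.ZC, qZC.ZS`
#'   (events per Ma).
#' @return a 4x4 rate matrix with rows summing to zero, dimnames
#'   `c("AS","AC","ZS","ZC")`, class `"correlated_Q"`.
#' @export
correlated_Q <- function(rates) {
  nm <- c("qAS.AC", "qAC.AS", "qAS.ZS", "qZS.AS",
          "qAC.ZC", "qZC.AC", "qZS.ZC", "qZC.ZS")
  if (!is.null(names(rates))) {
    if (!all(nm %in% names(rates))) stop("rates must be named ", paste(nm, collapse = ", "))
    rates <- rates[nm]
  }
  if (length(rates) != 8 || any(rates < 0) || any(!is.finite(rates)))
    stop("need 8 finite non-negative rates")
  s <- lineage_states()
  Q <- matrix(0, 4, 4, dimnames = list(s, s))
  Q["AS", "AC"] <- rates[1]; Q["AC", "AS"] <- rates[2]
  Q["AS", "ZS"] <- rates[3]; Q["ZS", "AS"] <- rates[4]
  Q["AC", "ZC"] <- rates[5]; Q["ZC", "AC"] <- rates[6]
  Q["ZS", "ZC"] <- rates[7]; Q["ZC", "ZS"] <- rates[8]
  diag(Q) <- -rowSums(Q)
  class(Q) <- c("correlated_Q", "matrix")
  Q
}

#' The four combined trait states
#' @return `c("AS","AC","ZS","ZC")`.
#' @export
lineage_states <- function() c("AS", "AC", "ZS", "ZC")

.validate_Q <- function(Q) {
  if (!is.matrix(Q) || nrow(Q) != 4 || ncol(Q) != 4)
    stop("Q must be a 4x4 matrix")
  offd <- Q; diag(offd) <- 0
  if (any(offd < 0)) stop("Q off-diagonals must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("Q rows must sum to 0")
  if (abs(Q[1, 4]) > 0 || abs(Q[4, 1]) > 0 || abs(Q[2, 3]) > 0 || abs(Q[3, 2]) > 0)
    stop("dual-transition entries of Q must be 0")
  invisible(TRUE)
}

#' Stationary distribution of a rate matrix
#' @param Q square rate matrix (rows sum to 0).
#' @return probability vector over states.
#' @export
stationary_distribution <- function(Q) {
  e <- eigen(t(unclass(Q)))
  i <- which.min(abs(e$values))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(Q))
}

#' Simulate correlated binary traits on a tree
#'
#' Evolves the 4-state combined symbiosis/coloniality chain from the root
#' down each branch; node and tip states are drawn exactly from the
#' transition probabilities `expm(Q t)` of each branch.
#'
#' @param tree a [timetree()].
#' @param Q a [correlated_Q()] matrix.
#' @param root_state state at the root (one of `lineage_states()`).
#' @param seed optional integer seed.
#' @return list with `tip_states` (named character over tips) and
#'   `node_states` (character over all nodes, ape indices).
#' @export
simulate_correlated_traits <- function(tree, Q, root_state = "AS", seed = NULL) {
  tree <- as_timetree(tree)
  .validate_Q(Q)
  states <- lineage_states()
  root_state <- match.arg(root_state, states)
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  st <- integer(ntot)
  st[ntip + 1] <- match(root_state, states)
  edge <- tree$edge
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  Pcache <- list()
  for (e in ord) {
    len <- tree$edge.length[e]
    key <- format(len, digits = 15)
    P <- Pcache[[key]]
    if (is.null(P)) {
      P <- as.matrix(Matrix::expm(unclass(Q) * len))
      P[P < 0] <- 0
      Pcache[[key]] <- P
    }
    p <- P[st[edge[e, 1]], ]
    st[edge[e, 2]] <- sample.int(4, 1, prob = p)
  }
  list(tip_states = stats::setNames(states[st[seq_len(ntip)]], tree$tip.label),
       node_states = states[st])
}

#' Simulate log10 depth under rate-scaled Brownian motion with trends
#'
#' Brownian increments along each branch have variance
#' `sigma2 * branch_length * r` where `r` is the branch's scalar; group-
#' labelled branches may additionally drift by `beta * branch_length`
#' (a controllable stand-in for emergent directional trends).
#'
#' @param tree a [timetree()].
#' @param sigma2 Brownian variance of log10 depth per Ma (> 0).
#' @param scalar_map optional named numeric vector `branch_id -> r`
#'   overriding the tree's own scalars on those branches.
#' @param trend_beta optional named numeric vector of drifts (log10 m per Ma)
#'   per group label; requires `branch_groups`.
#' @param branch_groups optional character vector of group labels per branch.
#' @param root_depth_log log10 depth (m) at the root.
#' @param seed optional integer seed.
#' @return list with `tip_depths` (named, log10 m) and `node_depths`
#'   (all nodes, ape indices).
#' @export
simulate_depth <- function(tree, sigma2 = 0.01, scalar_map = NULL,
                           trend_beta = NULL, branch_groups = NULL,
                           root_depth_log = 3, seed = NULL) {
  tree <- as_timetree(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  sc <- branch_scalars(tree)
  ne <- nrow(tree$edge)
  if (!is.null(scalar_map)) {
    ids <- as.integer(names(scalar_map))
    if (any(is.na(ids)) || any(ids < 1 | ids > ne))
      stop("scalar_map names must be branch ids in 1..", ne)
    sc[ids] <- scalar_map
  }
  drift <- rep(0, ne)
  if (!is.null(trend_beta)) {
    if (is.null(branch_groups) || length(branch_groups) != ne)
      stop("trend_beta requires branch_groups, one label per branch")
    known <- branch_groups %in% names(trend_beta)
    drift[known] <- trend_beta[branch_groups[known]]
  }
  if (!is.null(seed)) set.seed(seed)
  ntip <- ape::Ntip(tree)
  ntot <- ntip + tree$Nnode
  x <- numeric(ntot)
  x[ntip + 1] <- root_depth_log
  ord <- ape::reorder.phylo(tree, "cladewise", index.only = TRUE)
  for (e in ord) {
    len <- tree$edge.length[e]
    x[tree$edge[e, 2]] <- x[tree$edge[e, 1]] + drift[e] * len +
      stats::rnorm(1, 0, sqrt(sigma2 * len * sc[e]))
  }
  list(tip_depths = stats::setNames(x[seq_len(ntip)], tree$tip.label),
       node_depths = x)
}

#' Synthetic bathymetry raster
#'
#' A coarse regular lon/lat grid of positive water depths (m), written and
#' read as a plain-text ESRI-ASCII-style grid.  Lookup is nearest cell.
#'
#' @param lon_range,lat_range extents in degrees.
#' @param cell_size cell size in degrees.
#' @param depth_fun function of (lon, lat) giving cell depth in m; default a
#'   smooth shelf-to-abyss gradient with longitude.
#' @return list of class `"bathy_raster"`: `depth` matrix (rows = latitudes,
#'   north first), plus grid metadata.
#' @export
make_bathymetry_raster <- function(lon_range = c(-30, 30), lat_range = c(-30, 30),
                                   cell_size = 1,
                                   depth_fun = function(lon, lat)
                                     50 + (lon - min(lon)) / diff(range(lon)) * 5950) {
  lons <- seq(lon_range[1] + cell_size / 2, lon_range[2], by = cell_size)
  lats <- seq(lat_range[1] + cell_size / 2, lat_range[2], by = cell_size)
  g <- expand.grid(lon = lons, lat = lats)
  z <- depth_fun(g$lon, g$lat)
  depth <- matrix(z, nrow = length(lats), byrow = TRUE)
  depth <- depth[rev(seq_len(nrow(depth))), , drop = FALSE]  # north row first
  structure(list(depth = depth, lons = lons, lats = rev(lats),
                 cell_size = cell_size,
                 xll = lon_range[1], yll = lat_range[1]),
            class = "bathy_raster")
}

#' Raster depth at coordinates (nearest cell)
#' @param raster a `bathy_raster`.
#' @param lon,lat coordinates in degrees.
#' @return depth in m at the nearest cell.
#' @export
raster_depth_at <- function(raster, lon, lat) {
  ci <- pmin(pmax(round((lon - raster$xll - raster$cell_size / 2) /
                          raster$cell_size) + 1, 1), length(raster$lons))
  lat_top <- raster$lats[1]
  ri <- pmin(pmax(round((lat_top - lat) / raster$cell_size) + 1, 1),
             nrow(raster$depth))
  raster$depth[cbind(ri, ci)]
}

#' Write / read a bathymetry raster as a plain-text grid
#' @param raster a `bathy_raster`.
#' @param path file path.
#' @return `read_ascii_raster` returns a `bathy_raster`.
#' @export
write_ascii_raster <- function(raster, path) {
  hdr <- c(paste("ncols", ncol(raster$depth)),
           paste("nrows", nrow(raster$depth)),
           paste("xllcorner", raster$xll),
           paste("yllcorner", raster$yll),
           paste("cellsize", raster$cell_size))
  body <- apply(raster$depth, 1, paste, collapse = " ")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_ascii_raster
#' @export
read_ascii_raster <- function(path) {
  ln <- readLines(path)
  hdr <- strsplit(ln[1:5], "\\s+")
  val <- vapply(hdr, function(h) as.numeric(h[2]), numeric(1))
  names(val) <- vapply(hdr, `[`, "", 1)
  depth <- do.call(rbind, lapply(ln[-(1:5)], function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
  cs <- val[["cellsize"]]
  lons <- val[["xllcorner"]] + cs / 2 + cs * (seq_len(val[["ncols"]]) - 1)
  lats_bottom_up <- val[["yllcorner"]] + cs / 2 + cs * (seq_len(val[["nrows"]]) - 1)
  structure(list(depth = depth, lons = lons, lats = rev(lats_bottom_up),
                 cell_size = cs, xll = val[["xllcorner"]],
                 yll = val[["yllcorner"]]),
            class = "bathy_raster")
}

#' Simulate occurrence records with planted curation violations
#'
#' Draws `n_per_species` records uniformly inside each species'
#' depth/latitude box, consistent with a synthetic bathymetry raster, then
#' plants labelled rule violations so curation recall and precision are
#' computable: `"bathy_mismatch"` (recorded depth differs from the raster
#' cell by > 500 m), `"photic_gap"` (a zooxanthellate record below the
#' photic cutoff isolated by a > 50 m sorted-depth gap) and `"az_deep"`
#' (an azooxanthellate record beyond the depth cap).
#'
#' @param ranges data.frame with `species`, `min_depth`, `max_depth`,
#'   `min_lat`, `max_lat`, `symbiotic` (logical).
#' @param n_per_species clean records per species.
#' @param violations named counts, e.g.
#'   `c(bathy_mismatch = 3, photic_gap = 2, az_deep = 1)`.
#' @param raster optional `bathy_raster`; default [make_bathymetry_raster()].
#' @param photic_cutoff,gap,az_cap,tol rule constants (m) used to construct
#'   violating records; defaults match the curation defaults.
#' @param seed optional integer seed.
#' @return list with `occurrences` (data.frame: `species`, `lon`, `lat`,
#'   `depth`, `violation` — `""` for clean records) and `raster`.
#' @export
simulate_occurrences <- function(ranges, n_per_species = 20,
                                 violations = c(bathy_mismatch = 0,
                                                photic_gap = 0, az_deep = 0),
                                 raster = NULL, photic_cutoff = 165,
                                 gap = 50, az_cap = 5740, tol = 500,
                                 seed = NULL) {
  stopifnot(all(c("species", "min_depth", "max_depth", "min_lat", "max_lat",
                  "symbiotic") %in% names(ranges)))
  if (any(ranges$min_depth > ranges$max_depth)) stop("invalid ranges: min > max")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(raster)) raster <- make_bathymetry_raster()
  # invert the raster's monotone lon->depth gradient to place records in
  # cells whose depth is consistent with the record (within the tolerance)
  lon_for_depth <- function(d) {
    col_depth <- raster$depth[1, ]
    raster$lons[vapply(d, function(z) which.min(abs(col_depth - z)), 1L)]
  }
  rows <- list()
  for (i in seq_len(nrow(ranges))) {
    r <- ranges[i, ]
    d <- stats::runif(n_per_species, r$min_depth, r$max_depth)
    lat <- stats::runif(n_per_species, r$min_lat, r$max_lat)
    rows[[i]] <- data.frame(species = r$species, lon = lon_for_depth(d),
                            lat = lat, depth = d, violation = "",
                            stringsAsFactors = FALSE)
  }
  occ <- do.call(rbind, rows)
  vio <- list()
  nv <- function(nm) if (nm %in% names(violations)) violations[[nm]] else 0
  az <- ranges[!ranges$symbiotic, , drop = FALSE]
  zx <- ranges[ranges$symbiotic, , drop = FALSE]
  if (nv("bathy_mismatch") > 0) {
    sp <- ranges$species[sample.int(nrow(ranges), nv("bathy_mismatch"), replace = TRUE)]
    for (s in sp) {
      d <- 100                                  # shallow record ...
      lon <- lon_for_depth(3000 + stats::runif(1, tol + 200, 2000))  # ... deep cell
      vio[[length(vio) + 1]] <- data.frame(species = s, lon = lon,
                                           lat = 0, depth = d,
                                           violation = "bathy_mismatch",
                                           stringsAsFactors = FALSE)
    }
  }
  if (nv("photic_gap") > 0) {
    if (nrow(zx) == 0) stop("photic_gap violations need a zooxanthellate species")
    sp <- zx$species[sample.int(nrow(zx), nv("photic_gap"), replace = TRUE)]
    for (s in sp) {
      prev <- max(c(occ$depth[occ$species == s], photic_cutoff))
      d <- prev + gap + stats::runif(1, 50, 400)   # isolated deep record
      vio[[length(vio) + 1]] <- data.frame(species = s, lon = lon_for_depth(d),
                                           lat = 0, depth = d,
                                           violation = "photic_gap",
                                           stringsAsFactors = FALSE)
    }
  }
  if (nv("az_deep") > 0) {
    if (nrow(az) == 0) stop("az_deep violations need an azooxanthellate species")
    sp <- az$species[sample.int(nrow(az), nv("az_deep"), replace = TRUE)]
    for (s in sp) {
      d <- az_cap + stats::runif(1, 10, 200)
      vio[[length(vio) + 1]] <- data.frame(species = s, lon = lon_for_depth(d),
                                           lat = 0, depth = d,
                                           violation = "az_deep",
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(vio)) occ <- rbind(occ, do.call(rbind, vio))
  occ$record_id <- seq_len(nrow(occ))
  list(occurrences = occ, raster = raster)
}
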