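#' Filter occurrence records against bathymetry and trait-based depth rules
#'
#' Applies, in order, three curation rules to a table of occurrence records:
#' \enumerate{
#'   \item \strong{bathymetry}: drop records whose recorded depth deviates
#'     from the bathymetry-grid depth at their coordinates by more than
#'     `tol` (default 500 m, a wide interval owing to grid precision);
#'   \item \strong{photic gap}: for zooxanthellate species, records below the
#'     photic cutoff (deepest documented zooxanthellate register, 165 m) are
#'     kept only while consecutive sorted depths differ by at most `gap`
#'     (50 m) starting from the shallowest record below the cutoff — isolated
#'     deep records are likely identification or sampling errors;
#'   \item \strong{azooxanthellate cap}: drop azooxanthellate records deeper
#'     than `az_cap` (5740 m).
#' }
#' Records exactly at the cutoff count as above it.  Filtering is
#' order-independent within a species (depths are sorted internally).
#'
#' @param occurrences data.frame with `species`, `lon`, `lat`, `depth` (m,
#'   positive down) and optionally `record_id`.
#' @param raster a `bathy_raster` (see [make_bathymetry_raster()]).
#' @param traits data.frame with `species` and logical `symbiotic`
#'   (zooxanthellate) columns; every species present must be listed.
#' @param tol bathymetry mismatch tolerance (m).
#' @param photic_cutoff deepest accepted unconditional zooxanthellate depth (m).
#' @param gap maximum consecutive sorted-depth gap (m) below the cutoff.
#' @param az_cap maximum azooxanthellate depth (m).
#' @return list with `kept` (filtered occurrences) and `removal_log`
#'   (data.frame: `record_id`, `species`, `depth`, `rule`).
#' @export
apply_depth_filters <- function(occurrences, raster, traits, tol = 500,
                                photic_cutoff = 165, gap = 50, az_cap = 5740) {
  occ <- occurrences
  if (is.null(occ$record_id)) occ$record_id <- seq_len(nrow(occ))
  if (any(occ$depth < 0)) stop("depths must be >= 0 (m, positive down)")
  missing_tr <- setdiff(unique(occ$species), traits$species)
  if (length(missing_tr))
    stop("species missing trait flags: ", paste(missing_tr, collapse = ", "))
  symb <- stats::setNames(traits$symbiotic, traits$species)
  if (any(is.na(symb[unique(occ$species)])))
    stop("species with NA symbiosis flag: ",
         paste(unique(occ$species)[is.na(symb[unique(occ$species)])], collapse = ", "))

  drops <- list()
  note <- function(rows, rule) {
    if (nrow(rows)) drops[[length(drops) + 1]] <<-
        data.frame(record_id = rows$record_id, species = rows$species,
                   depth = rows$depth, rule = rule, stringsAsFactors = FALSE)
  }

  grid_depth <- raster_depth_at(raster, occ$lon, occ$lat)
  bad <- abs(occ$depth - grid_depth) > tol
  note(occ[bad, ], "bathymetry_mismatch")
  occ <- occ[!bad, , drop = FALSE]

  keep <- rep(TRUE, nrow(occ))
  for (s in unique(occ$species)) {
    if (!isTRUE(symb[[s]])) next
    idx <- which(occ$species == s)
    d <- occ$depth[idx]
    below <- which(d > photic_cutoff)
    if (!length(below)) next
    ds <- sort(d[below])
    # gaps are between consecutive sorted depths; the first sub-photic record
    # is compared against the deepest record at or above the cutoff (or the
    # cutoff itself when the species has none)
    prev <- if (any(d <= photic_cutoff)) max(d[d <= photic_cutoff]) else photic_cutoff
    cut_at <- length(ds) + 1
    for (j in seq_along(ds)) {
      if (ds[j] - prev > gap) { cut_at <- j; break }
      prev <- ds[j]
    }
    if (cut_at <= length(ds)) {
      bad_depths <- ds[cut_at:length(ds)]
      keep[idx[d %in% bad_depths & d > photic_cutoff]] <- FALSE
    }
  }
  note(occ[!keep, ], "photic_gap")
  occ <- occ[keep, , drop = FALSE]

  is_az <- !symb[occ$species]
  bad <- is_az & occ$depth > az_cap
  note(occ[bad, ], "azoox_depth_cap")
  occ <- occ[!bad, , drop = FALSE]

  log <- if (length(drops)) do.call(rbind, drops) else
    data.frame(record_id = integer(), species = character(),
               depth = numeric(), rule = character(), stringsAsFactors = FALSE)
  list(kept = occ, removal_log = log)
}

#' Summarize curated occurrences into species depth/latitude ranges
#'
#' The median (not the mean) summarizes the depth distribution because
#' sampling effort decreases with depth, so the mean is biased shallow.
#' Depths below 1 m are clamped to 1 m before log10 so log-depths are
#' non-negative.  For species whose latitudinal range crosses the equator
#' the minimum (absolute) latitude is set to zero.
#'
#' @param occurrences curated occurrence data.frame (`species`, `lat`, `depth`).
#' @return data.frame with one row per species: `species`, `min_depth`,
#'   `median_depth`, `max_depth` (m), their log10 counterparts
#'   (`min_depth_log` etc., on depths clamped to >= 1 m), `min_lat`,
#'   `max_lat` (absolute degrees).
#' @export
summarize_species_ranges <- function(occurrences) {
  sp <- split(occurrences, occurrences$species)
  empty <- vapply(sp, function(x) nrow(x) == 0, TRUE)
  if (any(empty)) {
    warning("species with no records omitted: ",
            paste(names(sp)[empty], collapse = ", "))
    sp <- sp[!empty]
  }
  out <- do.call(rbind, lapply(sp, function(x) {
    d <- x$depth
    crosses <- min(x$lat) < 0 && max(x$lat) > 0
    data.frame(species = x$species[1],
               min_depth = min(d), median_depth = stats::median(d),
               max_depth = max(d),
               min_depth_log = log10(max(min(d), 1)),
               median_depth_log = log10(max(stats::median(d), 1)),
               max_depth_log = log10(max(max(d), 1)),
               min_lat = if (crosses) 0 else min(abs(x$lat)),
               max_lat = max(abs(x$lat)),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Spearman agreement between two range tables
#'
#' Rank correlation between two independently curated datasets for the
#' log minimum, median and maximum depths, used to decide whether the two
#' datasets imply the same pattern (so one can be dropped).
#'
#' @param rangesA,rangesB range tables from [summarize_species_ranges()].
#' @return data.frame with `metric`, `rho`, `p_value`, `n`.
#' @export
dataset_agreement <- function(rangesA, rangesB) {
  shared <- intersect(rangesA$species, rangesB$species)
  if (length(shared) < 3) stop("need at least 3 shared species")
  a <- rangesA[match(shared, rangesA$species), ]
  b <- rangesB[match(shared, rangesB$species), ]
  metrics <- c("min_depth_log", "median_depth_log", "max_depth_log")
  do.call(rbind, lapply(metrics, function(m) {
    ct <- suppressWarnings(stats::cor.test(a[[m]], b[[m]], method = "spearman"))
    data.frame(metric = m, rho = unname(ct$estimate),
               p_value = ct$p.value, n = length(shared),
               stringsAsFactors = FALSE)
  }))
}
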