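# min pairwise Euclidean distance between two point sets (n x 2 matrices)
min_cross_dist <- function(a, b) {
  dx <- outer(a[, 1], b[, 1], `-`)
  dy <- outer(a[, 2], b[, 2], `-`)
  sqrt(min(dx^2 + dy^2))
}

# per-row minimum distance from points (x, y) to a focal location matrix
row_min_dist <- function(x, y, focal) {
  d2 <- outer(x, focal[, 1], `-`)^2 + outer(y, focal[, 2], `-`)^2
  sqrt(do.call(pmin, as.data.frame(d2)))
}

as_loc_matrix <- function(p) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 2)
  m <- as.matrix(p)
  storage.mode(m) <- "double"
  m
}

#' Buffer-overlap test between two location sets
#'
#' Two sets of sighting locations overlap when the smallest pairwise
#' Euclidean distance between them is at or below the buffer radius —
#' equivalently, when any location of one set falls inside the union of
#' radius-`radius_km` discs around the other. The rule is boundary-inclusive
#' and symmetric.
#'
#' @param entity_locations,focal_locations two-column matrices (or length-2
#'   vectors) of x/y coordinates in km; non-empty.
#' @param radius_km buffer radius in km (> 0); default 2.06, the median
#'   maximum within-season distance moved.
#' @return Logical scalar.
#' @export
overlaps <- function(entity_locations, focal_locations, radius_km = 2.06) {
  a <- as_loc_matrix(entity_locations)
  b <- as_loc_matrix(focal_locations)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty location set", call. = FALSE)
  if (radius_km <= 0) stop("radius_km must be positive", call. = FALSE)
  min_cross_dist(a, b) <= radius_km
}

#' Terrestrial area of a buffered location set
#'
#' Area (km^2) of the union of radius-`radius_km` discs around the given
#' locations, clipped to the island rectangle, evaluated by counting cell
#' centres of a regular grid. With the default 0.02-km cell the error for a
#' single 2.06-km disc is well under 1%.
#'
#' @param locations two-column matrix of x/y km coordinates.
#' @param island an `oss_island` (or any list with `length_km`, `width_km`).
#' @param radius_km buffer radius in km.
#' @param cell_km grid resolution in km.
#' @return Area in km^2; errors if the clipped buffer has zero area
#'   (location set entirely off-island).
#' @export
buffered_area <- function(locations, island, radius_km = 2.06, cell_km = 0.02) {
  locs <- as_loc_matrix(locations)
  stopifnot(nrow(locs) >= 1, radius_km > 0, cell_km > 0)
  x0 <- max(0, min(locs[, 1]) - radius_km)
  x1 <- min(island$length_km, max(locs[, 1]) + radius_km)
  y0 <- max(0, min(locs[, 2]) - radius_km)
  y1 <- min(island$width_km, max(locs[, 2]) + radius_km)
  if (x1 <= x0 || y1 <= y0) stop("buffered locations fall outside the island", call. = FALSE)
  gx <- seq(x0 + cell_km / 2, x1, by = cell_km)
  gy <- seq(y0 + cell_km / 2, y1, by = cell_km)
  inside <- matrix(FALSE, length(gx), length(gy))
  r2 <- radius_km^2
  for (i in seq_len(nrow(locs))) {
    dx2 <- (gx - locs[i, 1])^2
    dy2 <- (gy - locs[i, 2])^2
    inside <- inside | outer(dx2, dy2, `+`) <= r2
  }
  area <- sum(inside) * cell_km^2
  if (area <= 0) stop("buffered area is zero: band off-island", call. = FALSE)
  area
}

#' Local adult sex ratio around a focal band
#'
#' ASR is adult males / (adult males + adult females), restricted to
#' individuals whose sighting location overlaps the focal band's buffered
#' location set. Adult males are all males aged >= 4 (dominant, tag, or
#' bachelor); adult females are females aged >= 2. The default method
#' computes the ratio per census occasion — using each individual's location
#' on that occasion — and averages over occasions with at least one
#' overlapping adult; `method = "season"` instead pools unique individuals
#' whose season-wide locations overlap into a single ratio.
#'
#' @param focal_locations two-column matrix of the focal band's locations.
#' @param records sighting records for the same season (see
#'   [simulate_surveys()] for the schema).
#' @param radius_km buffer radius in km.
#' @param method `"occasion"` (per-occasion mean, default) or `"season"`.
#' @return ASR in `[0, 1]`; errors when no adult ever overlaps.
#' @export
local_asr <- function(focal_locations, records, radius_km = 2.06,
                      method = c("occasion", "season")) {
  method <- match.arg(method)
  focal <- as_loc_matrix(focal_locations)
  is_adult_m <- records$sex == "M" & records$age_class == "4+"
  is_adult_f <- records$sex == "F" & records$age_class %in% c("2-3", "4+")
  adults <- records[is_adult_m | is_adult_f, , drop = FALSE]
  if (nrow(adults) == 0) stop("no adults in records", call. = FALSE)
  near <- row_min_dist(adults$x_km, adults$y_km, focal) <= radius_km
  adults <- adults[near, , drop = FALSE]
  if (nrow(adults) == 0) stop("no overlapping adults for focal band", call. = FALSE)
  male <- adults$sex == "M"
  if (method == "season") {
    m <- length(unique(adults$individual_id[male]))
    f <- length(unique(adults$individual_id[!male]))
    return(m / (m + f))
  }
  ratios <- tapply(male, adults$occasion, function(z) sum(z) / length(z))
  mean(ratios)
}

#' Build the buffer-overlap neighborhood of a focal band-season
#'
#' Collects all band-seasons and bachelors of the same season whose locations
#' overlap the focal band's buffered locations, and derives the spatial
#' covariates used downstream: mean distance from the focal locations to the
#' nearest permanent pond, and season-unique unpaired-male and total-horse
#' counts per km^2 of buffered terrestrial area.
#'
#' @param focal_id band id of the focal band.
#' @param band_seasons band-season table for one season from
#'   [build_band_seasons()].
#' @param records sighting records for the same season.
#' @param ponds pond table (`x_km`, `y_km`).
#' @param island an `oss_island` (for the terrestrial clip).
#' @param radius_km buffer radius in km.
#' @param cell_km grid resolution forwarded to [buffered_area()].
#' @return A list of class `oss_neighborhood`: focal id, member band ids,
#'   member bachelor ids, qualified male/female counts, buffered area, and a
#'   `covariates` list (`dist_water_km`, `unpaired_male_density`,
#'   `total_density`).
#' @export
build_neighborhood <- function(focal_id, band_seasons, records, ponds, island,
                               radius_km = 2.06, cell_km = 0.05) {
  fi <- match(focal_id, band_seasons$band_id)
  if (is.na(fi)) stop("focal band not found: ", focal_id, call. = FALSE)
  focal <- as_loc_matrix(band_seasons$locations[[fi]])
  nloc <- vapply(band_seasons$locations, nrow, integer(1))
  stack <- do.call(rbind, band_seasons$locations)
  band_of <- rep(seq_len(nrow(band_seasons)), nloc)
  near_loc <- row_min_dist(stack[, 1], stack[, 2], focal) <= radius_km
  member <- tapply(near_loc, band_of, any)
  mem <- band_seasons[member, , drop = FALSE]
  near_rec <- row_min_dist(records$x_km, records$y_km, focal) <= radius_km
  nr <- records[near_rec, , drop = FALSE]
  bach_ids <- unique(nr$individual_id[nr$status == "bachelor" & nr$age_class == "4+"])
  area <- buffered_area(focal, island, radius_km, cell_km)
  dist_w <- mean(dist_to_water(focal[, 1], focal[, 2], ponds))
  n_total <- length(unique(nr$individual_id))
  qm <- sum(1L + lengths(mem$tag_ids)) + length(bach_ids)
  structure(list(
    focal_id = focal_id,
    member_band_ids = mem$band_id,
    member_bachelor_ids = bach_ids,
    harem_sizes = mem$qualified_mare_count,
    males_per_band = 1L + lengths(mem$tag_ids),
    qualified_male_count = qm,
    buffered_area_km2 = area,
    covariates = list(dist_water_km = dist_w,
                      unpaired_male_density = length(bach_ids) / area,
                      total_density = n_total / area)),
    class = "oss_neighborhood")
}
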