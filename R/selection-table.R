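#' Per-male selection metrics over buffer-overlap neighborhoods
#'
#' The modelling table of the analysis: one row per dominant male per season
#' carrying the three opportunity-for-selection statistics computed over his
#' band's buffer-overlap neighborhood (total `I`, harem-acquisition
#' `I_harem`, mate-acquisition `I_mares_given_harem`), the local adult sex
#' ratio, and the spatial covariates (mean distance to permanent water,
#' unpaired-male density, total density per km^2 of buffered terrestrial
#' area), plus the season's precipitation index.
#'
#' Rows whose statistics are undefined (zero mean mating success in the
#' neighborhood) are returned as `NA` and dropped with a logged count in
#' attribute `"dropped"` when `drop_undefined = TRUE`.
#'
#' @param records validated sighting records.
#' @param ponds pond table (`x_km`, `y_km`).
#' @param island an `oss_island` (geometry and precipitation index source).
#' @param radius_km buffer radius in km (default 2.06).
#' @param precipitation_index optional named (by year) numeric vector
#'   overriding the island's index.
#' @param asr_method forwarded to [local_asr()].
#' @param cell_km area-grid resolution forwarded to [build_neighborhood()].
#' @param drop_undefined drop rows with undefined statistics (default TRUE).
#' @return A data.frame with columns `male_id`, `band_id`, `year`, `x_km`,
#'   `y_km` (mean focal location), `I`,
#'   `I_harem`, `I_mares_given_harem`, `asr`, `dist_water_km`,
#'   `unpaired_male_density`, `total_density`, `precipitation_index`;
#'   attribute `"dropped"` counts removed rows.
#' @export
selection_table <- function(records, ponds, island, radius_km = 2.06,
                            precipitation_index = NULL,
                            asr_method = c("occasion", "season"),
                            cell_km = 0.05, drop_undefined = TRUE) {
  asr_method <- match.arg(asr_method)
  bs_all <- build_band_seasons(records)
  if (is.null(precipitation_index)) {
    precipitation_index <- stats::setNames(island$precipitation_index,
                                           island$years)
  }
  rows <- vector("list", nrow(bs_all))
  k <- 0L
  for (yr in sort(unique(bs_all$year))) {
    bs <- bs_all[bs_all$year == yr, , drop = FALSE]
    recs <- records[records$year == yr, , drop = FALSE]
    pidx <- unname(precipitation_index[as.character(yr)])
    for (i in seq_len(nrow(bs))) {
      nb <- build_neighborhood(bs$band_id[i], bs, recs, ponds, island,
                               radius_km, cell_km)
      holders <- length(nb$member_band_ids)
      ih <- i_harem(holders, nb$qualified_male_count)
      it <- suppressWarnings(i_total(nb$harem_sizes, nb$males_per_band))
      im <- suppressWarnings(i_mares_given_harem(nb$harem_sizes))
      asr <- local_asr(bs$locations[[i]], recs, radius_km, asr_method)
      floc <- as_loc_matrix(bs$locations[[i]])
      k <- k + 1L
      rows[[k]] <- data.frame(
        male_id = bs$dominant_male_id[i], band_id = bs$band_id[i], year = yr,
        x_km = mean(floc[, 1]), y_km = mean(floc[, 2]),
        I = it, I_harem = ih, I_mares_given_harem = im, asr = asr,
        dist_water_km = nb$covariates$dist_water_km,
        unpaired_male_density = nb$covariates$unpaired_male_density,
        total_density = nb$covariates$total_density,
        precipitation_index = pidx)
    }
  }
  tbl <- do.call(rbind, rows[seq_len(k)])
  rownames(tbl) <- NULL
  undef <- !stats::complete.cases(tbl[, c("I", "I_harem", "I_mares_given_harem")])
  if (drop_undefined) {
    dropped <- sum(undef)
    tbl <- tbl[!undef, , drop = FALSE]
    rownames(tbl) <- NULL
  } else dropped <- 0L
  attr(tbl, "dropped") <- dropped
  tbl
}
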