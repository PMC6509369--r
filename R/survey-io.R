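sighting_columns <- c("date", "occasion", "year", "individual_id", "sex",
                      "age_class", "status", "band_id", "x_km", "y_km")

#' Read and validate a sighting table
#'
#' Reads a CSV of individual sighting records, enforces the schema, and
#' applies row-level validation: rows with non-numeric coordinates are
#' dropped, duplicate records of the same individual on the same occasion
#' are reduced to the first, dominant males without a band id are dropped
#' (the record cannot be attributed), and mares without a band id are flagged
#' but kept. The validation tally is attached as attribute `"validation"`
#' (see [validation_report()]).
#'
#' @param path path to a CSV with columns `date`, `occasion`, `year`,
#'   `individual_id`, `sex`, `age_class`, `status`, `band_id`, `x_km`,
#'   `y_km`.
#' @return A validated sighting data.frame.
#' @export
load_sightings <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(sighting_columns, names(raw))
  if (length(missing) > 0) {
    stop("sighting file missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[, sighting_columns]
  raw$band_id[raw$band_id %in% c("", "NA")] <- NA_character_
  flags <- list()
  num <- function(v) suppressWarnings(as.numeric(v))
  x <- num(raw$x_km); y <- num(raw$y_km)
  occ <- num(raw$occasion); yr <- num(raw$year)
  bad <- is.na(x) | is.na(y) | is.na(occ) | is.na(yr)
  if (any(bad)) {
    flags[["non-numeric field (row dropped)"]] <- sum(bad)
    raw <- raw[!bad, , drop = FALSE]
    x <- x[!bad]; y <- y[!bad]; occ <- occ[!bad]; yr <- yr[!bad]
  }
  rec <- data.frame(date = raw$date, occasion = as.integer(occ),
                    year = as.integer(yr), individual_id = raw$individual_id,
                    sex = raw$sex, age_class = raw$age_class,
                    status = raw$status, band_id = raw$band_id,
                    x_km = x, y_km = y)
  dup <- duplicated(rec[, c("year", "individual_id", "occasion")])
  if (any(dup)) {
    flags[["duplicate (individual, occasion) (deduplicated)"]] <- sum(dup)
    rec <- rec[!dup, , drop = FALSE]
  }
  dom_nb <- rec$status == "dominant" & is.na(rec$band_id)
  if (any(dom_nb)) {
    flags[["dominant without band (row dropped)"]] <- sum(dom_nb)
    rec <- rec[!dom_nb, , drop = FALSE]
  }
  mare_nb <- rec$status == "mare" & is.na(rec$band_id)
  if (any(mare_nb)) flags[["mare without band (flagged)"]] <- sum(mare_nb)
  rownames(rec) <- NULL
  attr(rec, "validation") <- if (length(flags) > 0) {
    data.frame(rule = names(flags), count = unlist(flags, use.names = FALSE))
  } else data.frame(rule = character(0), count = integer(0))
  rec
}

#' Validation tally of a loaded sighting table
#' @param records a data.frame returned by [load_sightings()].
#' @return data.frame with columns `rule` and `count`.
#' @export
validation_report <- function(records) {
  v <- attr(records, "validation")
  if (is.null(v)) data.frame(rule = character(0), count = integer(0)) else v
}

#' Write a sighting table to CSV
#' @param records sighting data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sightings <- function(records, path) {
  utils::write.csv(records[, sighting_columns], path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Derive band-season structures from sighting records
#'
#' One row per (band, season): the dominant male, the set of tag males, the
#' count of unique qualified mares (females aged >= 2 affiliated with the
#' band that season), and the band's location set — one location per census
#' occasion on which the band was sighted (all members share the band
#' location, so the first member record of an occasion defines it).
#'
#' @param records validated sighting records.
#' @return A data.frame with columns `band_id`, `year`, `dominant_male_id`,
#'   `qualified_mare_count`, `n_occasions` plus list columns `tag_ids` and
#'   `locations` (two-column matrices). Errors if any band-season has zero
#'   or more than one dominant male.
#' @export
build_band_seasons <- function(records) {
  aff <- records[!is.na(records$band_id), , drop = FALSE]
  if (nrow(aff) == 0) stop("no band-affiliated records", call. = FALSE)
  key <- interaction(aff$year, aff$band_id, drop = TRUE)
  pieces <- split(aff, key)
  bad <- character(0)
  rows <- lapply(pieces, function(p) {
    dom <- unique(p$individual_id[p$status == "dominant"])
    if (length(dom) != 1) {
      bad <<- c(bad, sprintf("%s/%d (%d dominant males)", p$band_id[1], p$year[1], length(dom)))
      return(NULL)
    }
    qmare <- unique(p$individual_id[p$sex == "F" & p$age_class %in% c("2-3", "4+")])
    tags <- unique(p$individual_id[p$status == "tag"])
    first <- p[!duplicated(p$occasion), , drop = FALSE]
    first <- first[order(first$occasion), , drop = FALSE]
    list(band_id = p$band_id[1], year = p$year[1], dominant_male_id = dom,
         qualified_mare_count = length(qmare), n_occasions = nrow(first),
         tag_ids = tags,
         locations = cbind(x = first$x_km, y = first$y_km))
  })
  if (length(bad) > 0) {
    stop("band-season integrity error (need exactly one dominant male): ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  out <- data.frame(
    band_id = vapply(rows, `[[`, character(1), "band_id"),
    year = as.integer(vapply(rows, function(r) as.numeric(r$year), numeric(1))),
    dominant_male_id = vapply(rows, `[[`, character(1), "dominant_male_id"),
    qualified_mare_count = vapply(rows, `[[`, integer(1), "qualified_mare_count"),
    n_occasions = vapply(rows, `[[`, integer(1), "n_occasions"))
  out$tag_ids <- lapply(rows, `[[`, "tag_ids")
  out$locations <- lapply(rows, `[[`, "locations")
  rownames(out) <- NULL
  out[order(out$year, out$band_id), , drop = FALSE]
}
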