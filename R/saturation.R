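#' First census occasion at which a fitted saturation curve reaches 1
#'
#' For a logarithmic encounter curve `y = a*ln(x) + b`, returns the smallest
#' integer occasion `x` with predicted proportion at or above 1 — the
#' occasion by which a dominant male is estimated to have encountered all of
#' his season's competitor males.
#'
#' @param a,b curve coefficients.
#' @param max_x search bound (default 10000).
#' @return Integer occasion, or `NA_integer_` when the curve never reaches 1
#'   within `max_x` (flat or decreasing curves included).
#' @examples
#' saturation_occasion(0.184, 0.626)  # 8
#' @export
saturation_occasion <- function(a, b, max_x = 10000L) {
  if (b >= 1) return(1L)
  if (a <= 0) return(NA_integer_)
  x <- exp((1 - b) / a)
  x <- ceiling(x - 1e-9)
  if (x > max_x) return(NA_integer_)
  as.integer(max(x, 1))
}

#' Competitor-encounter saturation analysis
#'
#' For each focal dominant male and season, tracks the cumulative number of
#' unique competitor males (other dominant stallions and bachelors aged
#' >= 4) encountered within the buffer radius of the focal band's location
#' across consecutive census occasions, expressed as a proportion of that
#' male's season total. All male-occasion points are pooled and a
#' least-squares logarithmic curve `y = a*ln(x) + b` is fitted; the curve's
#' [saturation_occasion()] estimates when sampling effort suffices to have
#' met every competitor.
#'
#' @param records validated sighting records (any number of seasons).
#' @param radius_km buffer radius in km.
#' @param per_male if `TRUE`, also return per-male fitted coefficients.
#' @return An object of class `oss_saturation`: `a`, `b`, `r2`,
#'   `saturation_occasion`, `reached`, a pooled per-occasion summary
#'   `curve` (occasion, mean proportion, number of males), and the pooled
#'   point set `points`.
#' @export
saturation_analysis <- function(records, radius_km = 2.06, per_male = FALSE) {
  if (length(unique(records$occasion)) < 2) {
    stop("saturation analysis needs >= 2 census occasions", call. = FALSE)
  }
  pts <- list()
  for (yr in sort(unique(records$year))) {
    recs <- records[records$year == yr, , drop = FALSE]
    comp <- recs[(recs$status %in% c("dominant", "bachelor")) &
                   recs$age_class == "4+", , drop = FALSE]
    doms <- unique(recs$individual_id[recs$status == "dominant"])
    occs <- sort(unique(recs$occasion))
    for (d in doms) {
      drecs <- recs[recs$individual_id == d, , drop = FALSE]
      met <- vector("list", length(occs))
      for (ti in seq_along(occs)) {
        t <- occs[ti]
        floc <- drecs[drecs$occasion == t, c("x_km", "y_km"), drop = FALSE]
        if (nrow(floc) == 0) { met[[ti]] <- character(0); next }
        ct <- comp[comp$occasion == t & comp$individual_id != d, , drop = FALSE]
        if (nrow(ct) == 0) { met[[ti]] <- character(0); next }
        dist <- sqrt((ct$x_km - floc$x_km[1])^2 + (ct$y_km - floc$y_km[1])^2)
        met[[ti]] <- unique(ct$individual_id[dist <= radius_km])
      }
      cum <- integer(length(occs))
      seen <- character(0)
      for (ti in seq_along(occs)) {
        seen <- union(seen, met[[ti]])
        cum[ti] <- length(seen)
      }
      total <- cum[length(occs)]
      if (total == 0) next
      pts[[length(pts) + 1L]] <- data.frame(
        male_id = d, year = yr, occasion = occs, cum_prop = cum / total)
    }
  }
  if (length(pts) == 0) stop("no dominant male encountered any competitor", call. = FALSE)
  points <- do.call(rbind, pts)
  fit <- stats::lm(cum_prop ~ log(occasion), data = points)
  a <- unname(stats::coef(fit)[2])
  b <- unname(stats::coef(fit)[1])
  r2 <- summary(fit)$r.squared
  so <- saturation_occasion(a, b)
  curve <- stats::aggregate(cum_prop ~ occasion, data = points, FUN = mean)
  curve$n_males <- stats::aggregate(cum_prop ~ occasion, data = points, FUN = length)$cum_prop
  names(curve)[2] <- "mean_prop"
  out <- structure(list(a = a, b = b, r2 = r2,
                        saturation_occasion = so, reached = !is.na(so),
                        curve = curve, points = points),
                   class = "oss_saturation")
  if (per_male) {
    out$per_male <- do.call(rbind, lapply(split(points, points$male_id), function(p) {
      if (length(unique(p$occasion)) < 2) return(NULL)
      cf <- stats::coef(stats::lm(cum_prop ~ log(occasion), data = p))
      data.frame(male_id = p$male_id[1], a = unname(cf[2]), b = unname(cf[1]))
    }))
  }
  out
}

#' @export
print.oss_saturation <- function(x, ...) {
  cat(sprintf("Competitor-encounter saturation: y = %.3f ln(x) + %.3f (r2 = %.3f)\n",
              x$a, x$b, x$r2))
  if (x$reached) {
    cat(sprintf("Estimated full encounter by occasion %d\n", x$saturation_occasion))
  } else cat("Saturation not reached (flat or decreasing curve)\n")
  invisible(x)
}
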