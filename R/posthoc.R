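#' Year-specific covariate slopes from a `year x covariate` model
#'
#' Under treatment coding with the first year as reference, the rate at
#' which the response changes with the covariate in year `t` is the
#' covariate main coefficient plus that year's interaction coefficient (the
#' main coefficient alone for the reference year). Used post hoc to extract
#' the annual distance-from-water rates of the mate-acquisition episode.
#'
#' @param fit an `oss_lmm` whose formula is `response ~ year_f * covariate`.
#' @param covariate covariate name; default: detected from the formula.
#' @return data.frame with columns `year` and `beta`.
#' @export
year_slopes <- function(fit, covariate = NULL) {
  stopifnot(inherits(fit, "oss_lmm"))
  cf <- lme4::fixef(fit$fit)
  if (is.null(covariate)) {
    vars <- setdiff(all.vars(fit$formula[[3]]), "year_f")
    if (length(vars) != 1) stop("cannot infer covariate from formula", call. = FALSE)
    covariate <- vars
  }
  int_names <- grep(paste0("^year_f.*:", covariate, "$"), names(cf), value = TRUE)
  if (!covariate %in% names(cf) || length(int_names) == 0) {
    stop("model has no year x ", covariate, " interaction", call. = FALSE)
  }
  years <- levels(fit$fit@frame$year_f)
  beta <- stats::setNames(rep(cf[[covariate]], length(years)), years)
  for (nm in int_names) {
    yr <- sub(paste0(":", covariate, "$"), "", sub("^year_f", "", nm))
    beta[yr] <- beta[yr] + cf[[nm]]
  }
  data.frame(year = as.integer(names(beta)), beta = unname(beta))
}

#' Climate regression on annual covariate slopes
#'
#' Competes polynomial (linear and linear + quadratic) ordinary
#' least-squares regressions of the year-specific slopes on each candidate
#' climate variable, ranked by AICc with `n` = number of years and `k` =
#' number of regression coefficients. Climate variables are standardized
#' (z-scores across years) before fitting unless already on an index scale
#' and `standardize = FALSE`. With five years the quadratic correction
#' denominator `n - k - 1` equals 1; candidates with `n - k - 1 <= 0` get
#' `NA` AICc (reported, not fatal) and candidates with `n - k - 1 <= 1` are
#' flagged.
#'
#' @param slopes data.frame from [year_slopes()] (`year`, `beta`).
#' @param climate data.frame with a `year` column and one column per climate
#'   variable.
#' @param standardize z-score the climate variables across years (default
#'   TRUE).
#' @return An object of class `oss_climate_fit`: `table` (model, k, dAICc,
#'   weight, logLik, r_squared, small_sample flag), `winner` (model label),
#'   `winner_coefficients`, `concave` (sign of the winning quadratic term,
#'   NA for linear winners), and the list of `lm` fits.
#' @export
climate_fit <- function(slopes, climate, standardize = TRUE) {
  stopifnot(all(c("year", "beta") %in% names(slopes)),
            "year" %in% names(climate))
  n <- nrow(slopes)
  if (n < 4) stop("need >= 4 years for the quadratic candidates", call. = FALSE)
  dat <- merge(slopes, climate, by = "year")
  if (nrow(dat) < n) stop("climate table missing years", call. = FALSE)
  vars <- setdiff(names(climate), "year")
  if (standardize) {
    for (v in vars) dat[[v]] <- as.numeric(scale(dat[[v]]))
  }
  cands <- list()
  for (v in vars) {
    cands[[v]] <- stats::as.formula(paste("beta ~", v))
    cands[[paste0(v, " + ", v, "^2")]] <-
      stats::as.formula(paste0("beta ~ ", v, " + I(", v, "^2)"))
  }
  fits <- lapply(cands, stats::lm, data = dat)
  k <- vapply(fits, function(f) length(stats::coef(f)), numeric(1))
  ll <- vapply(fits, function(f) as.numeric(stats::logLik(f)), numeric(1))
  r2 <- vapply(fits, function(f) summary(f)$r.squared, numeric(1))
  r2[is.nan(r2)] <- 0
  if (stats::var(dat$beta) < 1e-20) r2[] <- 0  # constant response
  aval <- mapply(function(l, kk) {
    if (n <= kk + 1) NA_real_ else aicc(l, kk, n)
  }, ll, k)
  tab <- data.frame(model = names(fits), k = k, logLik = ll,
                    r_squared = r2, AICc = aval,
                    small_sample = n - k - 1 <= 1)
  tab$dAICc <- tab$AICc - min(tab$AICc, na.rm = TRUE)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), c("model", "k", "dAICc", "weight", "logLik",
                                "r_squared", "AICc", "small_sample")]
  rownames(tab) <- NULL
  winner <- tab$model[1]
  wc <- stats::coef(fits[[winner]])
  quad <- grep("^I\\(", names(wc))
  structure(list(table = tab, winner = winner, winner_coefficients = wc,
                 concave = if (length(quad)) unname(wc[quad]) < 0 else NA,
                 fits = fits, data = dat),
            class = "oss_climate_fit")
}

#' @export
print.oss_climate_fit <- function(x, ...) {
  cat("Climate regression on annual slopes\n")
  tab <- x$table
  tab$dAICc <- round(tab$dAICc, 2)
  tab$weight <- round(tab$weight, 3)
  tab$logLik <- round(tab$logLik, 1)
  tab$r_squared <- round(tab$r_squared, 2)
  print(tab[, c("model", "k", "dAICc", "weight", "logLik", "r_squared")])
  cat(sprintf("Winner: %s%s\n", x$winner,
              if (isTRUE(x$concave)) " (concave quadratic)" else ""))
  invisible(x)
}

#' Generate synthetic annual climate covariates
#'
#' Returns the candidate climate table for the post hoc regression: the
#' island's summer precipitation index plus three independent standardized
#' series (summer maximum temperature, winter precipitation, winter minimum
#' temperature) that carry no planted signal.
#'
#' @param island an `oss_island`.
#' @param seed integer seed (default: island seed + 3).
#' @return data.frame with columns `year`, `summer_precipitation`,
#'   `summer_max_temp`, `winter_precipitation`, `winter_min_temp`.
#' @export
synth_climate <- function(island, seed = NULL) {
  set.seed(if (is.null(seed)) island$seed + 3L else as.integer(seed))
  n <- island$n_years
  z <- function() as.numeric(scale(stats::rnorm(n)))
  data.frame(year = island$years,
             summer_precipitation = island$precipitation_index,
             summer_max_temp = z(),
             winter_precipitation = z(),
             winter_min_temp = z())
}
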