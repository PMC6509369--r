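#' AICc competition of residual-based candidate models
#'
#' Fits the fixed candidate set of the second inference stage to a response
#' (normally the standardized marginal residuals of a stage-1 ASR model):
#' a null intercept model, a categorical year model, and one
#' `year x covariate` model per covariate (year main effects, centred
#' covariate main effect, and their interactions), each with the male
#' random intercept, by maximum likelihood. Models are ranked by AICc
#' (sample size = number of rows) with Akaike weights.
#'
#' @param data data.frame with the response, `year`, the covariates, and the
#'   grouping column.
#' @param response response column name.
#' @param covariates covariate column names; default the three spatial
#'   covariates of the analysis.
#' @param group random-intercept grouping column (default `"male_id"`).
#' @return An object of class `oss_competition`: a `table` data.frame
#'   (model, k, logLik, AICc, dAICc, weight, marginal_r2) sorted by AICc,
#'   and the named list of `oss_lmm` `fits`.
#' @export
compete_models <- function(data, response,
                           covariates = c("dist_water_km",
                                          "unpaired_male_density",
                                          "total_density"),
                           group = "male_id") {
  stopifnot(response %in% names(data), group %in% names(data),
            "year" %in% names(data), all(covariates %in% names(data)))
  data <- as.data.frame(data)
  data$year_f <- factor(data$year)
  if (nlevels(data$year_f) < 2) stop("need >= 2 years", call. = FALSE)
  specs <- c(
    list(null = stats::as.formula(paste(response, "~ 1")),
         year = stats::as.formula(paste(response, "~ year_f"))),
    stats::setNames(
      lapply(covariates, function(cv) {
        stats::as.formula(paste(response, "~ year_f *", cv))
      }),
      paste("year x", covariates)))
  fits <- lapply(specs, fit_lmm, data = data, group = group)
  tab <- data.frame(
    model = names(fits),
    k = vapply(fits, `[[`, numeric(1), "k"),
    logLik = vapply(fits, `[[`, numeric(1), "logLik"),
    AICc = vapply(fits, `[[`, numeric(1), "aicc"),
    marginal_r2 = vapply(fits, `[[`, numeric(1), "marginal_r2"))
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- tab[order(tab$AICc), c("model", "k", "dAICc", "weight", "logLik",
                                "marginal_r2", "AICc")]
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, response = response,
                 covariates = covariates),
            class = "oss_competition")
}

#' Best model of a competition
#' @param competition an `oss_competition`.
#' @return The winning `oss_lmm` fit, with its model label in attribute
#'   `"model"`.
#' @export
best_model <- function(competition) {
  stopifnot(inherits(competition, "oss_competition"))
  nm <- competition$table$model[1]
  structure(competition$fits[[nm]], model = nm)
}

#' @export
print.oss_competition <- function(x, ...) {
  cat(sprintf("AICc competition for %s (n candidates = %d)\n",
              x$response, nrow(x$table)))
  tab <- x$table
  tab$dAICc <- round(tab$dAICc, 2)
  tab$weight <- round(tab$weight, 3)
  tab$logLik <- round(tab$logLik, 1)
  tab$marginal_r2 <- round(tab$marginal_r2, 2)
  print(tab[, c("model", "k", "dAICc", "weight", "logLik", "marginal_r2")])
  invisible(x)
}
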