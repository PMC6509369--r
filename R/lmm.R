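#' Fit a random-intercept linear mixed model by maximum likelihood
#'
#' The workhorse fit of both inference stages: fixed effects from `formula`,
#' a random intercept for each level of `group` (individual male identity),
#' estimated by maximum likelihood. Numeric covariates on the right-hand
#' side are mean-centred before fitting (centres are stored and re-applied
#' by `predict`). Returns a classed object carrying the quantities the
#' analysis reports: coefficients, variance components, log-likelihood,
#' AICc, marginal R-squared, and standardized marginal residuals.
#'
#' @param formula fixed-effects formula, e.g. `I_harem ~ asr`.
#' @param data data.frame containing the response, covariates and `group`.
#' @param group name of the random-intercept grouping column (default
#'   `"male_id"`).
#' @param center mean-centre numeric right-hand-side variables (default
#'   TRUE).
#' @return An object of class `oss_lmm` with components `fit` (the
#'   underlying `lmerTest` fit), `k` (parameter count including both
#'   variance components), `logLik`, `aicc`, `marginal_r2`, `sigma_alpha2`,
#'   `sigma_eps2`, `centers`, `n`, `n_groups`.
#' @export
fit_lmm <- function(formula, data, group = "male_id", center = TRUE) {
  stopifnot(inherits(formula, "formula"), group %in% names(data))
  data <- as.data.frame(data)
  rhs_vars <- setdiff(all.vars(formula[[3]]), group)
  centers <- numeric(0)
  for (v in rhs_vars) {
    if (v %in% names(data) && is.numeric(data[[v]]) && center) {
      if (stats::var(data[[v]]) == 0) {
        stop("covariate has zero variance: ", v, call. = FALSE)
      }
      centers[v] <- mean(data[[v]])
      data[[v]] <- data[[v]] - centers[v]
    }
  }
  if (length(unique(data[[group]])) < 2) {
    stop("need >= 2 grouping levels", call. = FALSE)
  }
  lf <- stats::as.formula(paste(deparse(formula, width.cutoff = 500L),
                                "+ (1 |", group, ")"))
  fit <- suppressMessages(lmerTest::lmer(lf, data = data, REML = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  s_a2 <- vc$vcov[vc$grp == group]
  s_e2 <- vc$vcov[vc$grp == "Residual"]
  ll <- stats::logLik(fit)
  k <- attr(ll, "df")
  n <- stats::nobs(fit)
  xb <- as.numeric(lme4::getME(fit, "X") %*% lme4::fixef(fit))
  r2m <- marginal_r2_components(stats::var(xb), s_a2, s_e2)
  structure(list(fit = fit, formula = formula, group = group,
                 centers = centers, n = n,
                 n_groups = length(unique(data[[group]])),
                 k = k, logLik = as.numeric(ll),
                 aicc = aicc(as.numeric(ll), k, n),
                 sigma_alpha2 = s_a2, sigma_eps2 = s_e2,
                 marginal_r2 = r2m),
            class = "oss_lmm")
}

#' Marginal R-squared from variance components
#'
#' Proportion of total variance (fixed + random intercept + residual)
#' explained by the fixed effects alone:
#' `var_f / (var_f + sigma_alpha2 + sigma_eps2)`.
#'
#' @param var_fixed variance of the fixed-effect linear predictor.
#' @param sigma_alpha2,sigma_eps2 random-intercept and residual variances.
#' @return Value in `[0, 1]`.
#' @export
marginal_r2_components <- function(var_fixed, sigma_alpha2, sigma_eps2) {
  stopifnot(var_fixed >= 0, sigma_alpha2 >= 0, sigma_eps2 >= 0)
  var_fixed / (var_fixed + sigma_alpha2 + sigma_eps2)
}

#' Marginal R-squared of a fitted model
#' @param fit an `oss_lmm`.
#' @return Value in `[0, 1]`.
#' @export
marginal_r2 <- function(fit) {
  stopifnot(inherits(fit, "oss_lmm"))
  fit$marginal_r2
}

#' Second-order Akaike information criterion
#'
#' `AICc = -2*logLik + 2k + 2k(k+1)/(n - k - 1)`.
#'
#' @param logLik model log-likelihood (ML).
#' @param k parameter count (fixed coefficients plus variance components for
#'   mixed models).
#' @param n number of observations.
#' @return AICc value; errors when `n <= k + 1` (correction undefined).
#' @export
aicc <- function(logLik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n <= k + 1", call. = FALSE)
  -2 * logLik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Akaike weights from AICc values
#' @param aicc_values numeric vector of AICc values (NA allowed; weight NA).
#' @return Weights summing to 1 over the non-NA entries.
#' @export
akaike_weights <- function(aicc_values) {
  d <- aicc_values - min(aicc_values, na.rm = TRUE)
  w <- exp(-d / 2)
  w / sum(w, na.rm = TRUE)
}

#' Fixed-effect term test with Satterthwaite denominator df
#'
#' Type III Wald F statistic for `term` with denominator degrees of freedom
#' by Satterthwaite's approximation — the test the single-random-intercept
#' design calls for. A likelihood-ratio fallback (`method = "lrt"`: ML
#' refit without the term, chi-square reference) is available for designs
#' where the Satterthwaite approximation is distrusted; it returns the
#' chi-square statistic in `F` with `df2 = Inf`.
#'
#' @param fit an `oss_lmm`.
#' @param term fixed-effect term label as it appears in the model formula.
#' @param method `"satterthwaite"` (default) or `"lrt"`.
#' @return List with `F`, `df1`, `df2`, `p_value`.
#' @export
satterthwaite_f <- function(fit, term, method = c("satterthwaite", "lrt")) {
  stopifnot(inherits(fit, "oss_lmm"))
  method <- match.arg(method)
  an <- suppressMessages(stats::anova(fit$fit, type = 3, ddf = "Satterthwaite"))
  if (!term %in% rownames(an)) {
    stop("term not in fixed effects: ", term, " (have: ",
         paste(rownames(an), collapse = ", "), ")", call. = FALSE)
  }
  if (method == "lrt") {
    reduced <- stats::update(fit$fit,
                             stats::as.formula(paste(". ~ . -", term)))
    lr <- 2 * (as.numeric(stats::logLik(fit$fit)) -
                 as.numeric(stats::logLik(reduced)))
    df1 <- an[term, "NumDF"]
    return(list(F = lr, df1 = df1, df2 = Inf,
                p_value = stats::pchisq(lr, df1, lower.tail = FALSE)))
  }
  list(F = an[term, "F value"], df1 = an[term, "NumDF"],
       df2 = an[term, "DenDF"], p_value = an[term, "Pr(>F)"])
}

#' Standardized marginal residuals
#'
#' Marginal residuals are the response minus the fixed-effect prediction
#' (random effects are not subtracted); they carry the variation left after
#' the fixed effects and are the stage-2 response of the analysis.
#' Standardization divides each residual by the square root of its marginal
#' variance `diag(V)`, `V = sigma_alpha2 * Z Z' + sigma_eps2 * I` — a
#' diagonal (Pearson) standardization that preserves the row-to-covariate
#' correspondence the residual models rely on (for a random-intercept model
#' `diag(V)` is constant, so this is a pure rescale).
#'
#' @param fit an `oss_lmm`.
#' @param standardized divide by `sqrt(diag(V))` (default TRUE).
#' @return Numeric vector, one residual per model row.
#' @export
extract_marginal_residuals <- function(fit, standardized = TRUE) {
  stopifnot(inherits(fit, "oss_lmm"))
  m <- fit$fit
  y <- lme4::getME(m, "y")
  xb <- as.numeric(lme4::getME(m, "X") %*% lme4::fixef(m))
  r <- y - xb
  if (!standardized) return(r)
  Z <- lme4::getME(m, "Z")
  vdiag <- fit$sigma_alpha2 * Matrix::rowSums(Z * Z) + fit$sigma_eps2
  as.numeric(r / sqrt(vdiag))
}

#' @export
print.oss_lmm <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (ML): %s + (1 | %s)\n",
              deparse(x$formula), x$group))
  cat(sprintf("  n = %d rows, %d groups; k = %d; logLik = %.2f; AICc = %.2f\n",
              x$n, x$n_groups, x$k, x$logLik, x$aicc))
  cat(sprintf("  sigma^2_alpha = %.4g, sigma^2_eps = %.4g, marginal R2 = %.3f\n",
              x$sigma_alpha2, x$sigma_eps2, x$marginal_r2))
  cat("Fixed effects:\n")
  print(round(lme4::fixef(x$fit), 4))
  invisible(x)
}

#' @export
summary.oss_lmm <- function(object, ...) {
  s <- summary(object$fit)
  cat(sprintf("AICc = %.2f, marginal R2 = %.3f\n", object$aicc, object$marginal_r2))
  s
}

#' @export
coef.oss_lmm <- function(object, ...) lme4::fixef(object$fit)

#' @export
logLik.oss_lmm <- function(object, ...) stats::logLik(object$fit)

#' Fixed-effect predictions from an `oss_lmm`
#'
#' @param object an `oss_lmm`.
#' @param newdata optional data.frame on the original (uncentred) covariate
#'   scale; defaults to the training rows.
#' @param ... unused.
#' @return Numeric vector of marginal (fixed-effects-only) predictions.
#' @export
predict.oss_lmm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(as.numeric(lme4::getME(object$fit, "X") %*% lme4::fixef(object$fit)))
  }
  newdata <- as.data.frame(newdata)
  for (v in names(object$centers)) {
    newdata[[v]] <- newdata[[v]] - object$centers[v]
  }
  as.numeric(stats::predict(object$fit, newdata = newdata, re.form = NA))
}

#' @export
residuals.oss_lmm <- function(object,
                              type = c("marginal_standardized", "marginal",
                                       "conditional"), ...) {
  type <- match.arg(type)
  switch(type,
         marginal_standardized = extract_marginal_residuals(object, TRUE),
         marginal = extract_marginal_residuals(object, FALSE),
         conditional = stats::residuals(object$fit))
}

#' @export
simulate.oss_lmm <- function(object, nsim = 1, seed = NULL, ...) {
  stats::simulate(object$fit, nsim = nsim, seed = seed, ...)
}
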