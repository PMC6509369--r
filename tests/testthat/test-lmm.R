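test_that("with no group variance the ML fit collapses to OLS", {
  d <- sim_lmm_data(n_males = 80, sigma_a = 0, sigma_e = 0.1, seed = 2)
  fit <- fit_lmm(y ~ x, d, group = "male_id")
  expect_lt(fit$sigma_alpha2, 1e-3)
  ols <- lm(y ~ I(x - mean(x)), data = d)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-4)
})

test_that("coefficients are sufficient statistics: duplicating rows preserves them", {
  d <- sim_lmm_data(n_males = 40, seed = 3)
  f1 <- fit_lmm(y ~ x, d)
  f2 <- fit_lmm(y ~ x, rbind(d, d))
  expect_equal(coef(f1), coef(f2), tolerance = 1e-3)
})

test_that("a planted ASR slope of 1.7 is recovered within 2 SE at n = 300", {
  d <- sim_lmm_data(n_males = 100, obs_per_male = 3, beta = 1.7,
                    sigma_a = 0.06, sigma_e = 0.07, seed = 4)
  fit <- fit_lmm(y ~ x, d)
  est <- coef(fit)[["x"]]
  se <- summary(fit$fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(est - 1.7), 2 * se)
})

test_that("marginal R2 identities and strong-link recovery", {
  expect_equal(marginal_r2_components(1, 1, 2), 0.25)
  expect_equal(marginal_r2_components(0, 1, 2), 0)
  d <- sim_lmm_data(seed = 5)
  null_fit <- fit_lmm(y ~ 1, d)
  expect_equal(marginal_r2(null_fit), 0)
  # strong planted link: true marginal R2 ~ 0.74
  b <- 1.725; vx <- 0.12^2
  s_tot <- b^2 * vx * 0.26 / 0.74
  d2 <- sim_lmm_data(n_males = 100, obs_per_male = 3, beta = b,
                     sigma_a = sqrt(s_tot / 2), sigma_e = sqrt(s_tot / 2),
                     x_sd = 0.12, seed = 6)
  fit <- fit_lmm(y ~ x, d2)
  expect_lt(abs(marginal_r2(fit) - 0.74), 0.1)
})

test_that("marginal R2 is invariant to linear rescaling of the response", {
  d <- sim_lmm_data(seed = 7)
  f1 <- fit_lmm(y ~ x, d)
  d$y <- 100 + 7 * d$y
  f2 <- fit_lmm(y ~ x, d)
  expect_equal(marginal_r2(f1), marginal_r2(f2), tolerance = 1e-6)
})

test_that("Satterthwaite F equals squared t for a single-df term", {
  d <- sim_lmm_data(n_males = 60, seed = 8)
  fit <- fit_lmm(y ~ x, d)
  sw <- satterthwaite_f(fit, "x")
  tval <- summary(fit$fit)$coefficients["x", "t value"]
  expect_equal(sw$F, tval^2, tolerance = 1e-6)
  expect_equal(sw$df1, 1)
  expect_gt(sw$df2, 0)
  expect_error(satterthwaite_f(fit, "nope"), "not in fixed effects")
  # likelihood-ratio fallback agrees with the F route on a strong effect
  lrt <- satterthwaite_f(fit, "x", method = "lrt")
  expect_gte(lrt$F, 0)
  expect_identical(lrt$df2, Inf)
  expect_lt(lrt$p_value, 0.001)
  expect_lt(sw$p_value, 0.001)
})

test_that("Satterthwaite df collapse to the OLS residual df without group variance", {
  d <- sim_lmm_data(n_males = 90, obs_per_male = 2, sigma_a = 0,
                    sigma_e = 0.1, seed = 9)
  fit <- fit_lmm(y ~ x, d)
  sw <- satterthwaite_f(fit, "x")
  expect_equal(sw$df2, nrow(d) - 2, tolerance = 0.05 * nrow(d))
})

test_that("marginal residuals match the direct linear-algebra oracle", {
  d <- sim_lmm_data(n_males = 30, seed = 10)
  fit <- fit_lmm(y ~ x, d)
  m <- fit$fit
  # oracle: r = y - X beta, standardized by sqrt(diag(V)),
  # V = sigma_a2 * Z Z' + sigma_e2 * I
  X <- as.matrix(lme4::getME(m, "X"))
  Z <- as.matrix(lme4::getME(m, "Z"))
  y <- lme4::getME(m, "y")
  V <- fit$sigma_alpha2 * tcrossprod(Z) + fit$sigma_eps2 * diag(length(y))
  r_oracle <- (y - X %*% lme4::fixef(m)) / sqrt(diag(V))
  expect_equal(extract_marginal_residuals(fit), as.numeric(r_oracle),
               tolerance = 1e-10)
  # raw marginal residuals are response minus fixed-effect prediction
  expect_equal(extract_marginal_residuals(fit, standardized = FALSE),
               d$y - predict(fit), tolerance = 1e-12)
  # near-zero mean
  expect_lt(abs(mean(extract_marginal_residuals(fit))), 0.05)
})

test_that("predict re-applies stored covariate centres on new data", {
  d <- sim_lmm_data(seed = 11)
  fit <- fit_lmm(y ~ x, d)
  expect_equal(predict(fit, newdata = d), predict(fit), tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  d <- sim_lmm_data(seed = 12)
  d$x <- 1
  expect_error(fit_lmm(y ~ x, d), "zero variance")
  d2 <- sim_lmm_data(seed = 13)
  d2$male_id <- "M001"
  expect_error(fit_lmm(y ~ x, d2), "grouping levels")
})

test_that("simulate method reproduces the fitted generative model", {
  d <- sim_lmm_data(seed = 14)
  fit <- fit_lmm(y ~ x, d)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(d), 2))
})
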