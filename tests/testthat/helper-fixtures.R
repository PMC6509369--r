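# shared fixtures, built once per test run

.fx <- new.env(parent = emptyenv())

# one default-scale pipeline run reused by several test files
default_run <- function() {
  if (is.null(.fx$run)) .fx$run <- run_pipeline(run_config(seed = 42))
  .fx$run
}

# a single-season synthetic survey at reduced scale
small_survey <- function() {
  if (is.null(.fx$small)) {
    isl <- generate_island(island_config(n_years = 1, seed = 5,
                                         occasions_per_year = 9))
    tr <- truth_params(n_bands_per_year = 30L, mean_harem_size = 2.4)
    pop <- generate_population(isl, tr)
    .fx$small <- list(island = isl, truth = tr, pop = pop,
                      records = simulate_surveys(pop))
  }
  .fx$small
}

# hand-built sighting records: one row per (id, occasion) combination
make_records <- function(id, occasion, x, y = 0.75, year = 2008L, sex = "M",
                         age_class = "4+", status = "dominant",
                         band_id = NA_character_) {
  g <- expand.grid(individual_id = id, occasion = as.integer(occasion),
                   stringsAsFactors = FALSE)
  n <- nrow(g)
  data.frame(date = format(as.Date(sprintf("%d-06-01", rep_len(as.integer(year), n))) +
                             g$occasion - 1L),
             occasion = g$occasion, year = rep_len(as.integer(year), n),
             individual_id = g$individual_id, sex = rep_len(sex, n),
             age_class = rep_len(age_class, n), status = rep_len(status, n),
             band_id = rep_len(band_id, n), x_km = rep_len(x, n),
             y_km = rep_len(y, n))
}

# simulate random-intercept data with known parameters
sim_lmm_data <- function(n_males = 100, obs_per_male = 3, beta = 1.7,
                         intercept = -0.4, sigma_a = 0.05, sigma_e = 0.05,
                         x_mean = 0.5, x_sd = 0.12, seed = 1) {
  set.seed(seed)
  male <- rep(sprintf("M%03d", seq_len(n_males)), each = obs_per_male)
  u <- rep(rnorm(n_males, 0, sigma_a), each = obs_per_male)
  x <- rnorm(length(male), x_mean, x_sd)
  y <- intercept + beta * x + u + rnorm(length(male), 0, sigma_e)
  data.frame(male_id = male, x = x, y = y)
}

# brute-force opportunity statistic on an expanded per-male success list
expanded_opportunity <- function(successes) {
  mu <- mean(successes)
  v <- mean((successes - mu)^2)
  v / mu^2
}
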