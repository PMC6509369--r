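test_that("island geometry is valid, deterministic, and spans the water gradient", {
  isl <- generate_island(island_config(seed = 3))
  expect_equal(isl$length_km * isl$width_km, 73.5)
  isl2 <- generate_island(island_config(seed = 3))
  expect_identical(isl$ponds, isl2$ponds)
  expect_true(all(isl$ponds$x_km >= 0 & isl$ponds$x_km <= 49))
  expect_true(all(isl$ponds$y_km >= 0 & isl$ponds$y_km <= 1.5))
  # distance to nearest pond spans ~0-15 km across the island's length
  d <- dist_to_water(seq(0, 49, by = 0.5), rep(0.75, 99), isl$ponds)
  expect_lt(min(d), 1.5)
  expect_gt(max(d), 10)
  expect_lt(max(d), 18)
  expect_error(island_config(length_km = -1), "positive")
  expect_error(island_config(pond_positions = data.frame(x_km = 60, y_km = 1)),
               "outside")
})

test_that("distance oracle: single far pond", {
  isl <- generate_island(island_config(
    pond_positions = data.frame(x_km = 48, y_km = 0.75), seed = 1))
  d <- dist_to_water(c(0, 20, 41), c(0.75, 0.75, 0.75), isl$ponds)
  expect_equal(d, c(48, 28, 7))
  expect_gte(max(d), 7)
})

test_that("population structure: one dominant per band, rare tags, age rules", {
  s <- small_survey()
  roster <- s$pop$roster
  bands <- s$pop$bands
  expect_equal(nrow(bands), 30)
  doms <- roster[roster$status == "dominant", ]
  expect_equal(nrow(doms), 30)
  expect_equal(sort(doms$band_id), sort(bands$band_id))
  expect_true(all(doms$age_class == "4+"))
  expect_true(all(roster$age_class[roster$status == "bachelor"] == "4+"))
  expect_true(all(roster$age_class[roster$status == "mare"] %in% c("2-3", "4+")))
  # tags present in well under 5% of bands at the default rate (large sample)
  isl <- generate_island(island_config(n_years = 1, seed = 11))
  big <- generate_population(isl, truth_params(n_bands_per_year = 1000L))
  tag_bands <- unique(big$roster$band_id[big$roster$status == "tag"])
  expect_lt(length(tag_bands) / 1000, 0.08)
})

test_that("bachelor_fraction 0 leaves only dominants and tags qualified", {
  isl <- generate_island(island_config(n_years = 1, seed = 2))
  pop <- generate_population(isl, truth_params(n_bands_per_year = 40L,
                                               bachelor_fraction = 0))
  expect_false("bachelor" %in% pop$roster$status)
  qualified <- pop$roster[pop$roster$sex == "M" & pop$roster$age_class == "4+", ]
  expect_true(all(qualified$status %in% c("dominant", "tag")))
  expect_error(truth_params(bachelor_fraction = 1), "infeasible")
})

test_that("harem sizes hit the target mean (Monte Carlo, 1000 bands)", {
  isl <- generate_island(island_config(n_years = 1, seed = 9))
  pop <- generate_population(isl, truth_params(n_bands_per_year = 1000L,
                                               mean_harem_size = 2.5))
  hz <- table(pop$roster$band_id[pop$roster$status == "mare"])
  se <- sqrt(1.5 / 1000)  # var of 1 + Poisson(1.5)
  expect_lt(abs(mean(hz) - 2.5), 3 * se)
})

test_that("male identities persist across seasons at the study's scale", {
  run <- default_run()
  sel <- run$selection
  expect_equal(nrow(sel), 335)
  n_males <- length(unique(sel$male_id))
  expect_gt(nrow(sel) / n_males, 2)   # repeat observations of the same males
  expect_lt(n_males, 180)
})

test_that("resight distribution matches the calibrated truncated family", {
  p <- resight_pmf(2.84, 1.43, 9L)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(attr(p, "mean"), 2.84, tolerance = 1e-6)
  # SD pinned at the truncated-Poisson lower limit (~1.50, above target 1.43)
  expect_equal(attr(p, "sd"), 1.50, tolerance = 0.02)
  # overdispersed targets are matched in both moments
  p2 <- resight_pmf(3, 2.2, 12L)
  expect_equal(attr(p2, "mean"), 3, tolerance = 1e-6)
  expect_equal(attr(p2, "sd"), 2.2, tolerance = 0.05)
})

test_that("surveys: bounds, shared band locations, resight moments, coverage", {
  s <- small_survey()
  rec <- s$records
  K <- s$island$occasions_per_year[1]
  expect_true(all(rec$occasion >= 1 & rec$occasion <= K))
  # all members of a band share one location per occasion
  aff <- rec[!is.na(rec$band_id), ]
  locs_per <- tapply(paste(aff$x_km, aff$y_km),
                     paste(aff$band_id, aff$occasion),
                     function(z) length(unique(z)))
  expect_true(all(locs_per == 1))
  # every individual in the roster is sighted at least once
  expect_setequal(unique(rec$individual_id), s$pop$roster$individual_id)
  # empirical resight moments at >= 500 individuals
  run <- default_run()
  cnt <- as.numeric(table(paste(run$records$year, run$records$individual_id)))
  expect_gt(length(cnt), 500)
  expect_lt(abs(mean(cnt) - 2.84), 0.1)
  expect_lt(abs(sd(cnt) - 1.50), 0.15)
})

test_that("generation is byte-identical under a fixed seed", {
  isl <- generate_island(island_config(n_years = 2, seed = 21))
  tr <- truth_params(n_bands_per_year = 15L)
  r1 <- simulate_surveys(generate_population(isl, tr))
  r2 <- simulate_surveys(generate_population(isl, tr))
  expect_identical(r1, r2)
})

test_that("plant_effects links responses to covariates at the planted rates", {
  run <- default_run()
  sel <- run$selection
  # planted water slopes follow the precipitation regime pattern
  ws <- attr(sel, "planted_water_slopes")
  expect_equal(unname(ws), c(0.02, -0.05, -0.05, 0.02, 0.02))
  # observed mechanical metrics preserved and nonnegative
  expect_true(all(sel$I_harem_observed >= 0))
  expect_true(all(sel$I_observed >= 0))
  # null planting leaves no unpaired-density signal in the ASR residuals
  tbl <- sel
  tbl$I <- tbl$I_observed
  tbl$I_harem <- tbl$I_harem_observed
  tbl$I_mares_given_harem <- tbl$I_mares_given_harem_observed
  null_truth <- truth_params(unpaired_effect_on_Iharem = 0,
                             water_by_precip_effect_on_Imares = c(0, 0))
  null_tbl <- plant_effects(tbl, null_truth, seed = 1)
  f0 <- fit_lmm(I_harem ~ asr, null_tbl)
  r0 <- extract_marginal_residuals(f0)
  expect_lt(abs(cor(r0, null_tbl$unpaired_male_density)), 0.15)
  # positive planted effect -> positive association beyond ASR (part of the
  # planted signal is absorbed by ASR, which shares the bachelor driver)
  pos_tbl <- plant_effects(tbl, truth_params(), seed = 1)
  f1 <- fit_lmm(I_harem ~ asr, pos_tbl)
  r1 <- extract_marginal_residuals(f1)
  expect_gt(cor(r1, pos_tbl$unpaired_male_density), 0.1)
  expect_lt(cor.test(r1, pos_tbl$unpaired_male_density)$p.value, 0.01)
  # determinism
  expect_identical(plant_effects(tbl, truth_params(), seed = 4),
                   plant_effects(tbl, truth_params(), seed = 4))
})

test_that("demographic sanity: ASR within [0, 1] and harems equal dominants", {
  run <- default_run()
  expect_true(all(run$selection$asr >= 0 & run$selection$asr <= 1))
  for (yr in unique(run$records$year)) {
    r <- run$records[run$records$year == yr, ]
    expect_equal(length(unique(r$band_id[!is.na(r$band_id)])),
                 length(unique(r$individual_id[r$status == "dominant"])))
  }
})
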