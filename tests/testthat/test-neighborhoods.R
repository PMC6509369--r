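test_that("overlap rule is boundary-inclusive on the buffer radius", {
  expect_true(overlaps(c(0, 0), c(0, 0), 2.06))            # coincident
  expect_true(overlaps(c(0, 0), c(2.06, 0), 2.06))         # exactly on boundary
  expect_false(overlaps(c(0, 0), c(2.07, 0), 2.06))        # just outside
  expect_true(overlaps(c(0, 0), c(2.07, 0), 2.07))
  expect_error(overlaps(matrix(numeric(0), ncol = 2), c(0, 0)), "empty")
  expect_error(overlaps(c(0, 0), c(1, 0), radius_km = 0), "positive")
})

test_that("overlaps agrees with a brute-force all-pairs scan", {
  set.seed(5)
  for (i in 1:50) {
    a <- cbind(runif(sample(1:100, 1), 0, 30), runif(1, 0, 1.5))
    b <- cbind(runif(sample(1:100, 1), 0, 30), runif(1, 0, 1.5))
    r <- runif(1, 0.5, 5)
    brute <- FALSE
    for (j in seq_len(nrow(a))) {
      for (k in seq_len(nrow(b))) {
        if (sqrt(sum((a[j, ] - b[k, ])^2)) <= r) brute <- TRUE
      }
    }
    expect_identical(overlaps(a, b, r), brute)
    expect_identical(overlaps(b, a, r), brute)   # symmetric
  }
})

test_that("buffered area of a fully interior disc matches the closed form", {
  big <- list(length_km = 20, width_km = 20)
  a <- buffered_area(cbind(10, 10), big, radius_km = 2.06, cell_km = 0.02)
  expect_equal(a, pi * 2.06^2, tolerance = 0.005)
  # clipped by the island: half-disc at the edge
  h <- buffered_area(cbind(10, 0), big, radius_km = 2.06, cell_km = 0.02)
  expect_equal(h, pi * 2.06^2 / 2, tolerance = 0.01)
  expect_error(buffered_area(cbind(40, 10), big, radius_km = 1), "outside")
})

test_that("distance to water averages per-location nearest-pond distances", {
  ponds <- data.frame(x_km = c(0, 10), y_km = c(0, 0))
  d <- dist_to_water(c(4, 6), c(0, 0), ponds)
  expect_equal(d, c(4, 4))
  expect_equal(mean(d), 4)
})

test_that("neighborhood membership and area grow monotonically with radius", {
  s <- small_survey()
  bs <- build_band_seasons(s$records)
  focal <- bs$band_id[3]
  prev_members <- character(0)
  prev_area <- 0
  for (r in c(0.5, 1, 2.06, 4, 8)) {
    nb <- build_neighborhood(focal, bs, s$records, s$island$ponds, s$island,
                             radius_km = r, cell_km = 0.05)
    expect_true(all(prev_members %in% nb$member_band_ids))
    expect_gte(nb$buffered_area_km2, prev_area)
    expect_true(focal %in% nb$member_band_ids)
    prev_members <- nb$member_band_ids
    prev_area <- nb$buffered_area_km2
  }
})

test_that("an island-wide radius captures every band and the global density", {
  s <- small_survey()
  bs <- build_band_seasons(s$records)
  nb <- build_neighborhood(bs$band_id[1], bs, s$records, s$island$ponds,
                           s$island, radius_km = 100, cell_km = 0.05)
  expect_setequal(nb$member_band_ids, bs$band_id)
  expect_equal(nb$buffered_area_km2, 49 * 1.5, tolerance = 0.01)
  n_pop <- length(unique(s$records$individual_id))
  expect_equal(nb$covariates$total_density, n_pop / nb$buffered_area_km2,
               tolerance = 1e-6)
})

test_that("densities are invariant to duplicated sightings of an individual", {
  s <- small_survey()
  bs <- build_band_seasons(s$records)
  nb1 <- build_neighborhood(bs$band_id[2], bs, s$records, s$island$ponds,
                            s$island, cell_km = 0.05)
  dup <- rbind(s$records, s$records[s$records$status == "bachelor", ])
  nb2 <- build_neighborhood(bs$band_id[2], bs, dup, s$island$ponds,
                            s$island, cell_km = 0.05)
  expect_equal(nb1$covariates$unpaired_male_density,
               nb2$covariates$unpaired_male_density)
  expect_equal(nb1$covariates$total_density, nb2$covariates$total_density)
})

test_that("qualified male count combines dominants, tags, and bachelors", {
  s <- small_survey()
  bs <- build_band_seasons(s$records)
  nb <- build_neighborhood(bs$band_id[1], bs, s$records, s$island$ponds,
                           s$island, cell_km = 0.05)
  expect_equal(nb$qualified_male_count,
               sum(nb$males_per_band) + length(nb$member_bachelor_ids))
  expect_equal(length(nb$harem_sizes), length(nb$member_band_ids))
})
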