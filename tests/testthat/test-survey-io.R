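write_fixture_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, na = "NA")
  path
}

ten_rows <- function() {
  rbind(make_records("M1", 1:4, x = 2, band_id = "B1"),
        make_records("F1", 1:4, x = 2, sex = "F", age_class = "2-3",
                     status = "mare", band_id = "B1"),
        make_records("M9", 1:2, x = 5, status = "bachelor"))
}

test_that("well-formed file loads with typed columns and no flags", {
  rec <- load_sightings(write_fixture_csv(ten_rows()))
  expect_equal(nrow(rec), 10)
  expect_equal(nrow(validation_report(rec)), 0)
  expect_type(rec$x_km, "double")
  expect_type(rec$occasion, "integer")
  expect_true(all(is.na(rec$band_id[rec$status == "bachelor"])))
})

test_that("schema and row-level validation rules fire", {
  df <- ten_rows()
  expect_error(load_sightings(write_fixture_csv(df[, -10])), "missing columns")
  # non-numeric coordinate: row dropped and logged
  df2 <- df; df2$x_km <- as.character(df2$x_km); df2$x_km[3] <- "east-end"
  rec <- load_sightings(write_fixture_csv(df2))
  expect_equal(nrow(rec), 9)
  v <- validation_report(rec)
  expect_equal(v$count[grepl("non-numeric", v$rule)], 1)
  # mare without band: flagged, kept
  df3 <- df; df3$band_id[5] <- NA
  rec3 <- load_sightings(write_fixture_csv(df3))
  expect_equal(nrow(rec3), 10)
  expect_true(any(grepl("mare without band", validation_report(rec3)$rule)))
  # duplicate (individual, occasion): first wins, logged
  df4 <- rbind(df, df[1, ])
  rec4 <- load_sightings(write_fixture_csv(df4))
  expect_equal(nrow(rec4), 10)
  expect_true(any(grepl("duplicate", validation_report(rec4)$rule)))
})

test_that("sighting tables round-trip through CSV", {
  s <- small_survey()
  path <- tempfile(fileext = ".csv")
  write_sightings(s$records, path)
  back <- load_sightings(path)
  expect_equal(back$individual_id, s$records$individual_id)
  expect_equal(back$x_km, s$records$x_km, tolerance = 1e-12)
})

test_that("band seasons apply the age-qualification threshold", {
  recs <- rbind(
    make_records("M1", 1:4, x = 2, band_id = "B1"),
    make_records("F1", 1, x = 2, sex = "F", age_class = "1",
                 status = "juvenile", band_id = "B1"),
    make_records("F2", 1, x = 2, sex = "F", age_class = "2-3",
                 status = "mare", band_id = "B1"),
    make_records("F3", 1, x = 2, sex = "F", age_class = "2-3",
                 status = "mare", band_id = "B1"),
    make_records("F4", 1, x = 2, sex = "F", age_class = "0",
                 status = "juvenile", band_id = "B1"))
  bs <- build_band_seasons(recs)
  expect_equal(nrow(bs), 1)
  # females aged {1, 2-3, 2-3, 0}: exactly the two >= 2-year-olds qualify
  expect_equal(bs$qualified_mare_count, 2L)
  # band seen on 4 occasions -> 4 locations
  expect_equal(bs$n_occasions, 4L)
  expect_equal(nrow(bs$locations[[1]]), 4)
})

test_that("band seasons: one row per band-year at generator scale", {
  isl <- generate_island(island_config(n_years = 1, seed = 13))
  pop <- generate_population(isl, truth_params(n_bands_per_year = 60L))
  recs <- simulate_surveys(pop)
  bs <- build_band_seasons(recs)
  expect_equal(nrow(bs), 60)
  expect_equal(anyDuplicated(paste(bs$band_id, bs$year)), 0L)
  # unique dominant male ids, one per band
  expect_equal(length(unique(bs$dominant_male_id)), 60)
  # re-deriving from the same records changes nothing
  expect_identical(bs, build_band_seasons(recs))
})

test_that("dominant-male integrity violations are reported by band", {
  recs <- rbind(make_records(c("M1", "M2"), 1, x = 2, band_id = "B1"),
                make_records("F1", 1, x = 2, sex = "F", status = "mare",
                             band_id = "B1"))
  expect_error(build_band_seasons(recs), "B1.*2 dominant males")
  no_dom <- make_records("F1", 1:2, x = 2, sex = "F", status = "mare",
                         band_id = "B2")
  expect_error(build_band_seasons(no_dom), "B2.*0 dominant males")
})
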