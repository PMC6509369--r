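test_that("grouped opportunity matches hand-computed cases", {
  # all males equal -> zero variance
  expect_equal(opportunity(f = 2, m = 3), 0)
  # two males {2, 0}: mean 1, variance 1
  expect_equal(opportunity(f = c(2, 0), m = c(1, 1)), 1)
  # expanded {3, 1, 1}: mean 5/3, variance 8/9, I = 8/25
  expect_equal(opportunity(f = c(3, 1), m = c(1, 2)), 0.32)
  # weighting by m: groups {(3, 2), (1, 1)} expand to {3, 3, 1} -> 8/49
  expect_equal(opportunity(f = c(3, 1), m = c(2, 1)), 8 / 49)
})

test_that("grouped statistic equals brute-force expanded statistic", {
  set.seed(101)
  for (i in 1:1000) {
    g <- sample(1:6, 1)
    f <- sample(0:8, g, replace = TRUE)
    m <- sample(1:5, g, replace = TRUE)
    if (sum(f * m) == 0) f[1] <- 1
    expect_equal(opportunity(f, m),
                 expanded_opportunity(rep(f, m)),
                 tolerance = 1e-12)
  }
})

test_that("opportunity is nonnegative, zero iff all equal, scale invariant", {
  set.seed(7)
  for (i in 1:50) {
    f <- sample(1:9, 4, replace = TRUE)
    m <- sample(1:3, 4, replace = TRUE)
    v <- opportunity(f, m)
    expect_gte(v, 0)
    expect_equal(v, opportunity(f * 3.7, m), tolerance = 1e-12)
    if (length(unique(rep(f, m))) == 1) expect_equal(v, 0)
    if (v == 0) expect_length(unique(rep(f, m)), 1)
  }
})

test_that("undefined statistic (zero mean) yields NA with warning", {
  expect_warning(res <- opportunity(f = c(0, 0), m = c(1, 2)), "undefined")
  expect_true(is.na(res))
  expect_error(opportunity(f = c(-1, 2), m = c(1, 1)), "nonnegative")
  expect_error(opportunity(f = 1, m = 0), ">= 1")
})

test_that("i_total reproduces the band-grouped cases", {
  expect_equal(i_total(3), 0)                       # single band
  expect_equal(i_total(c(4, 2)), 1 / 9)             # mean 3, var 1
  expect_equal(i_total(c(3, 1), c(1, 2)), 0.32)     # expanded {3,1,1}
  expect_equal(i_total(c(3, 1), c(2, 1)), 8 / 49)   # tag weighting
  expect_warning(expect_true(is.na(i_total(c(0, 0)))))
})

test_that("i_harem equals the Bernoulli closed form (1 - p) / p", {
  for (q in c(2L, 5L, 13L, 40L)) {
    for (h in seq_len(q)) {
      expect_equal(i_harem(h, q), (1 - h / q) / (h / q), tolerance = 1e-12)
    }
  }
  expect_equal(i_harem(4, 4), 0)        # p = 1: every male succeeds
  expect_equal(i_harem(1, 4), 3)        # p = 0.25
  expect_equal(i_harem(2, 4), 1)        # p = 0.5
  expect_error(i_harem(0, 4), "undefined")
  expect_error(i_harem(5, 4), "exceed")
})

test_that("i_harem decreases strictly with the harem-holder fraction", {
  q <- 120L
  vals <- vapply(seq.int(6L, q, by = 6L), function(h) i_harem(h, q), numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("i_mares_given_harem covers the dominant-male-only episode", {
  expect_equal(i_mares_given_harem(c(2, 2, 2)), 0)
  expect_equal(i_mares_given_harem(c(2, 0)), 1)
  expect_equal(i_mares_given_harem(c(3, 1, 1)), 0.32)
})

test_that("local_asr hits the stated endpoints and averages occasions", {
  # only females overlap -> 0
  fem <- make_records(id = c("F1", "F2"), occasion = 1, x = 1, sex = "F",
                      age_class = "4+", status = "mare", band_id = "B1")
  expect_equal(local_asr(cbind(1, 0.75), fem), 0)
  # equal males and females each occasion -> 0.5
  eq <- rbind(make_records("M1", 1:2, 1),
              make_records("F1", 1:2, 1, sex = "F", status = "mare", band_id = "B1"))
  expect_equal(local_asr(cbind(1, 0.75), eq), 0.5)
  # per-occasion ratios {0.4, 0.6} -> mean 0.5
  r1 <- make_records(paste0("M", 1:2), 1, 1)
  r2 <- make_records(paste0("F", 1:3), 1, 1, sex = "F", status = "mare", band_id = "B1")
  r3 <- make_records(paste0("M", 1:3), 2, 1)
  r4 <- make_records(paste0("F", 1:2), 2, 1, sex = "F", status = "mare", band_id = "B1")
  expect_equal(local_asr(cbind(1, 0.75), rbind(r1, r2, r3, r4)), 0.5)
  # juveniles and far animals never count
  far <- make_records("M9", 1, x = 30)
  juv <- make_records("J1", 1, x = 1, age_class = "1", status = "juvenile")
  expect_equal(local_asr(cbind(1, 0.75), rbind(fem, far, juv), radius_km = 2.06), 0)
  # no overlapping adults at all -> error
  expect_error(local_asr(cbind(1, 0.75), far), "no overlapping")
})

test_that("season-pooled ASR variant counts unique individuals once", {
  recs <- rbind(make_records("M1", 1:5, 1),
                make_records("F1", 1, 1, sex = "F", status = "mare", band_id = "B1"))
  # per-occasion: mean(1, .5, 1, 1, 1); season-unique: 1 male, 1 female
  expect_equal(local_asr(cbind(1, 0.75), recs, method = "season"), 0.5)
  expect_equal(local_asr(cbind(1, 0.75), recs, method = "occasion"), 0.9)
})
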