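new_test_result <- function(statistic, df, p_value, method) {
  structure(list(statistic = unname(statistic), df = df,
                 p_value = unname(p_value), method = method),
            class = "oss_test")
}

#' @export
print.oss_test <- function(x, ...) {
  dfs <- paste(format(x$df, digits = 4), collapse = ", ")
  cat(sprintf("%s: statistic = %.4g, df = (%s), p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  invisible(x)
}

#' Brown-Forsythe Levene-type test of equal variances
#'
#' One-way ANOVA of the absolute deviations from the group medians — the
#' median centring is what distinguishes the Brown-Forsythe variant from
#' classic Levene. The statistic `W` is the plain ANOVA F on those
#' deviations with df `(g - 1, N - g)`.
#'
#' @param groups list of numeric vectors, each of length >= 2.
#' @return An `oss_test` with fields `statistic` (W), `df`, `p_value`.
#' @export
brown_forsythe <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(lengths(groups) < 2)) stop("each group needs >= 2 values", call. = FALSE)
  dev <- lapply(groups, function(g) abs(g - stats::median(g)))
  ns <- lengths(dev)
  g <- length(dev)
  N <- sum(ns)
  means <- vapply(dev, mean, numeric(1))
  grand <- sum(means * ns) / N
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum(vapply(seq_len(g), function(i) sum((dev[[i]] - means[i])^2), numeric(1)))
  if (ssw == 0) {
    w <- if (ssb == 0) 0 else Inf
  } else {
    w <- (ssb / (g - 1)) / (ssw / (N - g))
  }
  p <- if (is.infinite(w)) 0 else stats::pf(w, g - 1, N - g, lower.tail = FALSE)
  new_test_result(w, c(g - 1, N - g), p, "Brown-Forsythe Levene-type test")
}

#' Kruskal-Wallis rank sum test
#'
#' Tie-corrected H statistic with a chi-square reference on `g - 1` df,
#' via [stats::kruskal.test()]. A fully degenerate input (every pooled value
#' identical) returns `H = 0`, `p = 1` rather than an error.
#'
#' @param groups list of numeric vectors (>= 2 groups).
#' @return An `oss_test` with fields `statistic` (H), `df`, `p_value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  x <- unlist(groups, use.names = FALSE)
  gl <- factor(rep(seq_along(groups), lengths(groups)))
  if (length(unique(x)) == 1) {
    return(new_test_result(0, length(groups) - 1, 1, "Kruskal-Wallis rank sum test"))
  }
  kt <- stats::kruskal.test(x, gl)
  new_test_result(kt$statistic, unname(kt$parameter), kt$p.value,
                  "Kruskal-Wallis rank sum test")
}

#' Annual harem abundance against population size
#'
#' Ordinary least squares of the yearly number of harems on total population
#' size, the island-wide check that harem abundance tracks population growth.
#'
#' @param summary data.frame with columns `population` and `harems` (and
#'   optionally `year`), one row per year; >= 3 rows.
#' @return An `oss_test` (F statistic, df `(1, n - 2)`, p) with extra fields
#'   `slope`, `intercept`, `r_squared`.
#' @export
harems_population_lm <- function(summary) {
  stopifnot(all(c("population", "harems") %in% names(summary)))
  if (nrow(summary) < 3) stop("need >= 3 years", call. = FALSE)
  fit <- stats::lm(harems ~ population, data = summary)
  s <- summary(fit)
  out <- new_test_result(s$fstatistic[1],
                         unname(c(s$fstatistic[2], s$fstatistic[3])),
                         stats::pf(s$fstatistic[1], s$fstatistic[2],
                                   s$fstatistic[3], lower.tail = FALSE),
                         "harems ~ population linear model")
  out$slope <- unname(stats::coef(fit)[2])
  out$intercept <- unname(stats::coef(fit)[1])
  out$r_squared <- s$r.squared
  out
}

#' Island-wide annual tests on the selection metrics
#'
#' Runs, for each selection metric (`I`, `I_harem`, `I_mares_given_harem`)
#' with individual dominant males as the sampling unit: the Brown-Forsythe
#' test of equal variances across years and the Kruskal-Wallis test of equal
#' locations across years.
#'
#' @param tbl a selection table from [selection_table()].
#' @return A data.frame with one row per (metric, test): statistic, df1,
#'   df2 (NA for Kruskal-Wallis), p_value.
#' @export
islandwide_tests <- function(tbl) {
  metrics <- c("I", "I_harem", "I_mares_given_harem")
  rows <- list()
  for (mt in metrics) {
    groups <- split(tbl[[mt]], tbl$year)
    groups <- groups[lengths(groups) >= 2]
    bf <- brown_forsythe(groups)
    kw <- kruskal_wallis(groups)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mt, test = "Brown-Forsythe", statistic = bf$statistic,
      df1 = bf$df[1], df2 = bf$df[2], p_value = bf$p_value)
    rows[[length(rows) + 1L]] <- data.frame(
      metric = mt, test = "Kruskal-Wallis", statistic = kw$statistic,
      df1 = kw$df[1], df2 = NA_real_, p_value = kw$p_value)
  }
  do.call(rbind, rows)
}

#' Annual census summary of a sighting table
#'
#' Per season: unique individuals of any age (population), unique adult
#' males (>= 4 y), unique adult females (>= 2 y), number of harems (bands
#' with a dominant male), and mean harem size (qualified mares per band)
#' with a normal-approximation 95% confidence interval.
#'
#' @param records validated sighting records.
#' @return data.frame with columns `year`, `population`, `adult_males`,
#'   `adult_females`, `harems`, `harem_size_mean`, `harem_size_ci_half`.
#' @export
annual_summary <- function(records) {
  bs <- build_band_seasons(records)
  years <- sort(unique(records$year))
  out <- lapply(years, function(yr) {
    r <- records[records$year == yr, , drop = FALSE]
    b <- bs[bs$year == yr, , drop = FALSE]
    hz <- b$qualified_mare_count
    data.frame(
      year = yr,
      population = length(unique(r$individual_id)),
      adult_males = length(unique(r$individual_id[r$sex == "M" & r$age_class == "4+"])),
      adult_females = length(unique(r$individual_id[r$sex == "F" & r$age_class %in% c("2-3", "4+")])),
      harems = nrow(b),
      harem_size_mean = mean(hz),
      harem_size_ci_half = 1.96 * stats::sd(hz) / sqrt(length(hz)))
  })
  do.call(rbind, out)
}
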