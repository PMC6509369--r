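#' Published annual census summary of the study population
#'
#' Island-wide annual counts for the five breeding seasons of the feral
#' horse study system (2008-2012): total population (all age classes),
#' adult males (>= 4 y), adult females (>= 2 y), number of harems, and mean
#' harem size with its 95% confidence half-width. Used as the reference
#' input for the harems-against-population regression.
#'
#' @format data.frame with columns `year`, `population`, `adult_males`,
#'   `adult_females`, `harems`, `harem_size_mean`, `harem_size_ci_half`.
#' @export
census_reference <- data.frame(
  year = 2008:2012,
  population = c(375L, 425L, 484L, 450L, 534L),
  adult_males = c(137L, 152L, 167L, 183L, 214L),
  adult_females = c(134L, 143L, 165L, 145L, 175L),
  harems = c(52L, 58L, 73L, 73L, 79L),
  harem_size_mean = c(2.60, 2.71, 2.33, 2.12, 2.32),
  harem_size_ci_half = c(0.59, 0.42, 0.35, 0.27, 0.34))

#' Published competitor-encounter saturation coefficients
#'
#' Coefficients of the pooled logarithmic encounter curve
#' `y = a ln(x) + b` reported for dominant males of the study system;
#' the curve first reaches 1 at the 8th census occasion.
#'
#' @format Named numeric vector with elements `a`, `b`, `r2`.
#' @export
saturation_reference <- c(a = 0.184, b = 0.626, r2 = 0.565)
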