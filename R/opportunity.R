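#' Opportunity for selection from grouped mating success
#'
#' Crow's index of the opportunity for selection, `I = variance / mean^2`,
#' computed from grouped success counts. Each group contributes `m` males
#' sharing success `f` (number of qualified mates). The statistic equals the
#' population variance over squared mean of the expanded per-male success
#' list, i.e. with `N = sum(m)`:
#' `mean = sum(f * m) / N`, `variance = sum(f^2 * m) / N - mean^2`.
#'
#' @param f integer vector of per-male success counts (>= 0), one per group.
#' @param m integer vector of male multiplicities (>= 1), same length as `f`.
#' @return A single nonnegative number, or `NA_real_` with a warning when the
#'   mean success is zero (the statistic is undefined; callers drop such rows).
#' @examples
#' opportunity(f = c(2, 0), m = c(1, 1))     # mean 1, variance 1 -> I = 1
#' opportunity(f = c(3, 1), m = c(1, 2))     # expanded {3,1,1}   -> I = 0.32
#' @export
opportunity <- function(f, m) {
  stopifnot(length(f) == length(m), length(f) >= 1)
  if (any(!is.finite(f)) || any(!is.finite(m))) {
    stop("non-finite success counts or multiplicities")
  }
  if (any(f < 0)) stop("success counts `f` must be nonnegative")
  if (any(m < 1)) stop("multiplicities `m` must be >= 1")
  n <- sum(m)
  mu <- sum(f * m) / n
  if (mu == 0) {
    warning("mean mating success is zero; opportunity undefined (NA)")
    return(NA_real_)
  }
  v <- sum(f^2 * m) / n - mu^2
  max(v, 0) / mu^2
}

#' Total opportunity for sexual selection in a neighborhood
#'
#' Band-grouped Crow's index over all bands in a buffer-overlap neighborhood:
#' each member band contributes one group with `f` = its count of qualified
#' mares (the band's harem, mating success attributed to the dominant male)
#' and `m` = its count of dominant plus tag males. Tag males never receive
#' mates but add weight to their band's group, reflecting that they are
#' counted among the males competing at the site.
#'
#' @param harem_sizes integer vector: qualified mares per member band.
#' @param males_per_band integer vector: dominant + tag males per member band
#'   (default 1 each).
#' @return Nonnegative number or `NA_real_` (all harems empty).
#' @seealso [opportunity()], [i_harem()], [i_mares_given_harem()]
#' @export
i_total <- function(harem_sizes, males_per_band = rep(1L, length(harem_sizes))) {
  stopifnot(length(harem_sizes) >= 1)
  opportunity(f = harem_sizes, m = males_per_band)
}

#' Opportunity for selection in the harem-acquisition episode
#'
#' Success at this episode is binary: a qualified male (dominant, tag, or
#' bachelor, all aged >= 4) either holds a harem or not. With
#' `p = holders / qualified`, Crow's index reduces to the Bernoulli closed
#' form `(1 - p) / p`; the implementation routes through [opportunity()] on
#' the grouped counts so the equivalence is a checkable identity rather than
#' an assumption.
#'
#' @param holders number of harem-holding (dominant) males in the neighborhood.
#' @param qualified total qualified males (dominant + tag + bachelor, >= 4 y).
#' @return Nonnegative number; errors when there are no holders (undefined).
#' @export
i_harem <- function(holders, qualified) {
  stopifnot(length(holders) == 1, length(qualified) == 1)
  if (qualified < 1) stop("need at least one qualified male")
  if (holders < 1) stop("no harem holders in neighborhood: I_harem undefined")
  if (holders > qualified) stop("holders exceed qualified males")
  nonholders <- qualified - holders
  f <- c(1L, 0L)[c(TRUE, nonholders > 0)]
  m <- c(holders, nonholders)[c(TRUE, nonholders > 0)]
  opportunity(f = f, m = m)
}

#' Opportunity for selection in the mate-acquisition episode
#'
#' Crow's index among dominant males only, given that each already holds a
#' harem: `f` = qualified mares per dominant male, one male per group.
#'
#' @param harem_sizes integer vector of qualified-mare counts, one per
#'   dominant male in the neighborhood.
#' @return Nonnegative number or `NA_real_` when every harem has zero
#'   qualified mares (mean success zero).
#' @export
i_mares_given_harem <- function(harem_sizes) {
  stopifnot(length(harem_sizes) >= 1)
  opportunity(f = harem_sizes, m = rep(1L, length(harem_sizes)))
}
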