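# Closed-form digital-PCR and enrichment mathematics. These formulas are
# idealized design tools (no WGA dispersion, no merged droplets) and serve as
# cross-checks for the droplet simulator; each is testable against Monte-Carlo
# means.

#' Digital-PCR positive-droplet fraction
#'
#' Under Poisson loading with mean `lambda_t` target molecules per droplet,
#' the fraction of droplets containing at least one target is
#' `1 - exp(-lambda_t)`.
#'
#' @param lambda_t Mean target molecules per droplet (>= 0); vectorized.
#' @return Positive fraction in `[0, 1)`.
#' @export
positive_fraction <- function(lambda_t) {
  if (any(lambda_t < 0)) stop("lambda_t must be non-negative", call. = FALSE)
  -expm1(-lambda_t)
}

#' Invert the digital-PCR law
#'
#' Recovers the Poisson loading rate from an observed positive fraction:
#' `lambda = -log(1 - f)`.
#'
#' @param f Positive fraction in `[0, 1)`; vectorized.
#' @return Loading rate `lambda_t`.
#' @export
lambda_from_fraction <- function(f) {
  if (any(f < 0 | f >= 1)) stop("f must be in [0, 1)", call. = FALSE)
  -log1p(-f)
}

#' Expected target-molecule purity of the sorted pool
#'
#' A collected true-positive droplet carries on average
#' `T = lambda_t / (1 - exp(-lambda_t))` target molecules (zero-truncated
#' Poisson mean) plus `lambda_b` background molecules. False sorts add
#' gate-negative droplets — carrying background only — at `false_sort_rate`
#' among the `1 - p` negatives. Molecule purity is the target fraction of all
#' collected molecules.
#'
#' @param lambda_t,lambda_b Per-droplet means.
#' @param false_sort_rate Collection probability for gate-negative droplets.
#' @return Expected fraction of sorted-pool molecules that are targets.
#' @export
expected_purity <- function(lambda_t, lambda_b, false_sort_rate = 0) {
  if (lambda_t + lambda_b <= 0) stop("lambda_t + lambda_b must be > 0",
                                     call. = FALSE)
  .assert_rate(false_sort_rate, "false_sort_rate")
  p <- positive_fraction(lambda_t)
  Tm <- if (lambda_t == 0) 1 else lambda_t / p
  num <- p * Tm
  den <- p * (Tm + lambda_b) + (1 - p) * false_sort_rate * lambda_b
  if (den == 0) return(1)
  num / den
}

#' Expected sorted-droplet purity
#'
#' The fraction of collected droplets that truly contain a target — the
#' quantity a droplet-counting readout (e.g. fluorescence microscopy of the
#' sorted emulsion) measures: `p / (p + (1 - p) * false_sort_rate)`.
#'
#' @inheritParams expected_purity
#' @return Expected fraction of collected droplets containing a target.
#' @export
expected_droplet_purity <- function(lambda_t, false_sort_rate = 0) {
  p <- positive_fraction(lambda_t)
  p / (p + (1 - p) * false_sort_rate)
}

#' Calibrate the false-sort rate to a measured sorted-droplet purity
#'
#' Solves `expected_droplet_purity(lambda_t, f) = purity` for `f`:
#' `f = p (1 - purity) / (purity (1 - p))`. Used to reproduce a measured
#' post-sort purity when the instrument's false-sort rate is not known
#' directly.
#'
#' @param lambda_t Target loading rate.
#' @param purity Observed fraction of sorted droplets containing target,
#'   in `(0, 1]`.
#' @return The implied false-sort rate.
#' @export
calibrate_false_sort_rate <- function(lambda_t, purity) {
  .assert_scalar_number(purity, "purity", 1e-12, 1)
  p <- positive_fraction(lambda_t)
  p * (1 - purity) / (purity * (1 - p))
}

#' Expected number of target molecules recovered
#'
#' `N * lambda_t * (1 - pcr_failure_rate)`: every target molecule sits in
#' some droplet, and that droplet fluoresces (hence is collected by a sorter
#' with no false negatives) unless its PCR failed.
#'
#' @param lambda_t Target loading rate.
#' @param N Number of droplets.
#' @param pcr_failure_rate Probability a target droplet fails to fluoresce.
#' @return Expected target molecules collected.
#' @export
expected_recovery <- function(lambda_t, N, pcr_failure_rate = 0) {
  .assert_scalar_number(N, "N", 0)
  .assert_rate(pcr_failure_rate, "pcr_failure_rate")
  N * lambda_t * (1 - pcr_failure_rate)
}

#' Fragment coverage kernel around the probe
#'
#' Probability that a fragment known to cover the probe point also covers the
#' point at distance `d`. For fixed fragment length `L` this is the triangle
#' `max(0, 1 - |d|/L)` (the amplicon is treated as a point; the error is
#' O(amplicon/L)). For a length distribution, lengths are first length-biased
#' (longer fragments are more likely to cover the probe) and the triangle is
#' mixed over them.
#'
#' @param d Distance(s) from the probe in bp.
#' @param L Fragment length (bp), or a vector of lengths defining an empirical
#'   length distribution.
#' @param weights Optional probability weights for a length distribution.
#' @return Coverage probability, same length as `d`.
#' @export
coverage_kernel <- function(d, L, weights = NULL) {
  if (any(L <= 0)) stop("L must be positive", call. = FALSE)
  if (length(L) == 1L) return(pmax(0, 1 - abs(d) / L))
  if (is.null(weights)) weights <- rep(1, length(L))
  wb <- L * weights / sum(L * weights)  # length-biased mixture
  sapply(d, function(dd) sum(wb * pmax(0, 1 - abs(dd) / L)))
}

#' Expected fold enrichment over a probe-centered window
#'
#' In the ideal sorted pool each collected droplet carries one target fragment
#' (small `lambda_t`) plus `lambda_b` background fragments, all of length `L`.
#' The target fragment's coverage concentrates under the triangle kernel
#' around its probe, while background spreads over the whole genome, giving
#' for window size `s <= 2L`
#' \deqn{fold(s) = \frac{G (s - s^2/(4L))}{n\, s (1+\lambda_b) L} +
#'   \frac{\lambda_b}{1+\lambda_b}}
#' and for `s >= 2L` the saturated form `G / (n s (1+lambda_b)) +
#' lambda_b/(1+lambda_b)` (continuous at `s = 2L`). With `n_loci > 1` loci
#' sharing the sorted pool, each droplet's target belongs to a given locus
#' with probability `1/n`, which divides the target term by `n`.
#'
#' @param G Genome size in bp.
#' @param L Fragment length in bp.
#' @param lambda_b Background molecules per droplet.
#' @param s Window size(s) in bp.
#' @param n_loci Number of target loci sharing the pool (default 1).
#' @return Expected fold enrichment, same length as `s`.
#' @export
expected_fold_enrichment <- function(G, L, lambda_b, s, n_loci = 1) {
  .assert_scalar_number(G, "G", 1)
  .assert_scalar_number(L, "L", 1)
  .assert_scalar_number(lambda_b, "lambda_b", 0)
  if (any(s <= 0)) stop("window size s must be positive", call. = FALSE)
  bg <- lambda_b / (1 + lambda_b)
  target <- ifelse(
    s <= 2 * L,
    G * (s - s^2 / (4 * L)) / (s * (1 + lambda_b) * L),
    G / (s * (1 + lambda_b))
  )
  target / n_loci + bg
}

#' Purity--recovery dilution tradeoff curve
#'
#' Fixing the DNA composition (background:target molar ratio `r`) and varying
#' the dilution sweeps `lambda_t` with `lambda_b = r * lambda_t`. Diluting
#' lowers the background co-encapsulated with each target (higher purity) but
#' reduces the absolute number of targets recovered from a fixed number of
#' droplets.
#'
#' @param lambda_t_grid Grid of target loading rates.
#' @param ratio Background:target molar ratio `r`; for whole-genome DNA with
#'   `n` single-copy targets, `r = (G/L - n)/n`.
#' @param N Number of droplets.
#' @param pcr_failure_rate,false_sort_rate Passed to the purity/recovery
#'   formulas.
#' @return data.frame with `lambda_t`, `lambda_b`, `positive_fraction`,
#'   `purity` (molecule purity), `droplet_purity`, `recovery`.
#' @export
tradeoff_curve <- function(lambda_t_grid, ratio, N,
                           pcr_failure_rate = 0, false_sort_rate = 0) {
  if (length(lambda_t_grid) == 0L || any(lambda_t_grid < 0)) {
    stop("lambda_t_grid must be non-empty and non-negative", call. = FALSE)
  }
  .assert_scalar_number(ratio, "ratio", 0)
  data.frame(
    lambda_t = lambda_t_grid,
    lambda_b = ratio * lambda_t_grid,
    positive_fraction = positive_fraction(lambda_t_grid),
    purity = vapply(lambda_t_grid, function(lt) {
      if (lt == 0) 1 else expected_purity(lt, ratio * lt, false_sort_rate)
    }, numeric(1)),
    droplet_purity = vapply(lambda_t_grid, function(lt) {
      expected_droplet_purity(lt, false_sort_rate)
    }, numeric(1)),
    recovery = expected_recovery(lambda_t_grid, N, pcr_failure_rate)
  )
}
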