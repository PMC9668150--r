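#' Simulate sequencing reads from true mutation frequencies
#'
#' For each mutation with true cancer cell frequency \eqn{\chi_i}, the site
#' coverage is drawn as \eqn{R_i \sim Binomial(M, R/M)} and the variant read
#' count as \eqn{Z_i \sim Binomial(R_i, \chi_i/2)} (heterozygous diploid
#' sites, purity 1; purity enters only the correction formula in
#' [gamma_corrected()]).
#'
#' @param ccf Numeric vector of true mutation frequencies in `[0, 1]`.
#' @param M Number of cells in the sequenced sample.
#' @param coverage Average sequencing coverage `R` (must not exceed `M`).
#' @param seed Optional integer seed.
#' @return A `read_observation`: list with `coverage_site` (\eqn{R_i}),
#'   `alt_reads` (\eqn{Z_i}), `ccf`, `coverage` (average `R`) and `M`.
#' @examples
#' ro <- simulate_reads(c(0.5, 0.05, 0.01), M = 1e5, coverage = 200, seed = 1)
#' gamma_observed(ro, f1 = 0.01, f2 = 0.2, threshold = 2)
#' @export
simulate_reads <- function(ccf, M, coverage, seed = NULL) {
  if (any(!is.finite(ccf)) || any(ccf < 0 | ccf > 1))
    stop("'ccf' values must lie in [0, 1]")
  if (coverage > M) stop("average coverage cannot exceed the cell count M")
  if (!is.null(seed)) set.seed(seed)
  n <- length(ccf)
  Ri <- rbinom(n, size = as.integer(round(M)), prob = coverage / M)
  Zi <- rbinom(n, size = Ri, prob = ccf / 2)
  structure(list(coverage_site = Ri, alt_reads = Zi, ccf = ccf,
                 coverage = coverage, M = M),
            class = "read_observation")
}

#' Observed subclonal mutation count after read filtering
#'
#' Counts mutations whose read-derived frequency `2 Z_i / R` (average
#' coverage `R` in the denominator) lies in the closed window `[f1, f2]` and
#' that survive the post-processing filter `Z_i > threshold`.
#'
#' @param obs A [simulate_reads()] result, or a list with `alt_reads` and
#'   `coverage`.
#' @param f1,f2 Frequency window bounds.
#' @param threshold Variant-read filter `L`: mutations with `threshold` or
#'   fewer variant reads are discarded (default 2).
#' @return Integer count \eqn{\gamma_{obs}}.
#' @export
gamma_observed <- function(obs, f1, f2, threshold = 2) {
  .check_window(f1, f2)
  Z <- obs$alt_reads
  freq <- 2 * Z / obs$coverage
  sum(freq >= f1 & freq <= f2 & Z > threshold)
}

#' Correct the observed subclonal mutation count for filtered-out mutations
#'
#' Mutations with frequency below `2 * threshold / (purity * coverage)` are
#' typically removed by the variant-read filter, so the observed count in
#' `[f1, f2]` underestimates the true one when that cutoff exceeds `f1`.
#' Since the expected number of subclonal mutations between `f1` and `x`
#' scales as `1/f1 - 1/x`, the observed count can be rescaled:
#' \deqn{\gamma = \gamma_{obs} \frac{1/f_1 - 1/f_2}{pR/(2L) - 1/f_2}.}
#' When the cutoff does not exceed `f1` no mutations in the window are
#' expected to be lost and `gamma_obs` is returned unchanged.
#'
#' @param gamma_obs Observed count from [gamma_observed()].
#' @param f1,f2 Frequency window bounds.
#' @param coverage Average sequencing coverage `R`.
#' @param purity Tumor purity `p` in `(0, 1]`.
#' @param threshold Variant-read filter `L` (default 2).
#' @return Corrected count (real-valued, non-negative).
#' @examples
#' gamma_corrected(10, f1 = 0.01, f2 = 0.2, coverage = 200)  # 21.11
#' @export
gamma_corrected <- function(gamma_obs, f1, f2, coverage, purity = 1,
                            threshold = 2) {
  .check_window(f1, f2)
  if (gamma_obs < 0) stop("'gamma_obs' must be non-negative")
  if (purity <= 0 || purity > 1) stop("'purity' must lie in (0, 1]")
  cutoff <- 2 * threshold / (purity * coverage)
  if (cutoff <= f1) return(gamma_obs)
  denom <- purity * coverage / (2 * threshold) - 1 / f2
  if (denom <= 0)
    stop("filter cutoff at or above f2: no detectability window ",
         "(purity * coverage / (2 * threshold) must exceed 1/f2)")
  max(0, gamma_obs * (1 / f1 - 1 / f2) / denom)
}
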