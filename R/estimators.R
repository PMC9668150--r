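#' Exclusive (clone-specific) cancer cell fractions
#'
#' Converts cumulative driver CCFs — the fraction of cells carrying driver
#' `i`, including all descendant subclones — into exclusive fractions: the
#' fraction of cells whose most recent driver is `i`. For driver `i` the
#' exclusive fraction subtracts the cumulative fractions of its direct
#' children; the initiated clone 0 takes the remainder so that exclusive
#' fractions sum to 1.
#'
#' @param alpha Numeric vector of cumulative CCFs for drivers `1..k`.
#' @param parent Integer vector (`parent[i]` = parent clone of driver `i`).
#' @param tol Negative exclusive fractions larger than `-tol` are treated as
#'   floating-point noise and clamped to 0; anything more negative is an
#'   inconsistent-CCF error.
#' @return Numeric vector of length `k + 1` (clone 0 first).
#' @examples
#' clone_exclusive_fractions(c(0.7, 0.3), parent = c(0, 1))  # 0.3 0.4 0.3
#' clone_exclusive_fractions(c(0.5, 0.3), parent = c(0, 0))  # 0.2 0.5 0.3
#' @export
clone_exclusive_fractions <- function(alpha, parent, tol = 1e-9) {
  k <- length(alpha)
  if (length(parent) != k) stop("'parent' must have one entry per driver")
  if (any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1))
    stop("cumulative CCFs must lie in [0, 1]")
  excl <- numeric(k + 1)
  for (i in seq_len(k))
    excl[i + 1] <- alpha[i] - sum(alpha[parent == i])
  excl[1] <- 1 - sum(excl[-1])
  bad <- excl < -tol
  if (any(bad))
    stop("inconsistent CCFs: exclusive fraction of clone ",
         paste(which(bad) - 1, collapse = ", "),
         " is negative (child fractions exceed the parent's)")
  pmax(excl, 0)
}

#' Net growth rate estimates from two longitudinal measurements
#'
#' Equates each clone's measured cell count at the two timepoints to the
#' conditional expectation of a surviving birth-death process,
#' \eqn{(b_i/r_i) e^{r_i t}}, giving
#' \deqn{\hat r_i = \frac{1}{\Delta} \log\frac{\beta_i^c M_2}{\alpha_i^c M_1}}
#' for every clone, where \eqn{\alpha_i^c, \beta_i^c} are exclusive
#' fractions at the two timepoints. This general form reduces exactly to the
#' published single-, nested- and sibling-layout formulas (see
#' [growth_rates_single()] and friends).
#'
#' @param alpha1,alpha2 Cumulative driver CCFs at the first and second
#'   timepoint (length `k`).
#' @param M1,M2 Total cancer cell counts at the two timepoints.
#' @param delta Time between the two timepoints (> 0).
#' @param parent Parent map of the drivers.
#' @return Numeric vector of net growth rates for clones `0..k`, in inverse
#'   units of `delta`.
#' @examples
#' estimate_growth_rates(0.2, 0.5, 1e5, 4e5, delta = 2, parent = 0)
#' @export
estimate_growth_rates <- function(alpha1, alpha2, M1, M2, delta, parent) {
  if (delta <= 0) stop("'delta' must be positive")
  if (M1 <= 0 || M2 <= 0) stop("cell counts must be positive")
  a <- clone_exclusive_fractions(alpha1, parent)
  b <- clone_exclusive_fractions(alpha2, parent)
  if (any(a == 0) || any(b == 0))
    stop("undefined growth rate: clone ",
         paste(unique(c(which(a == 0), which(b == 0))) - 1, collapse = ", "),
         " unobserved at a timepoint")
  log(b * M2 / (a * M1)) / delta
}

#' Closed-form growth rates for the named clonal layouts
#'
#' The layout-specific growth-rate formulas: for a single driver subclone
#' \eqn{r = \log[(1-\alpha_2)M_2 / ((1-\alpha_1)M_1)]/\Delta} and
#' \eqn{r_1 = \log[\alpha_2 M_2/(\alpha_1 M_1)]/\Delta}; for two nested and
#' two sibling driver subclones the analogous expressions in terms of the
#' driver fractions at the two timepoints. These exist as independent
#' formulas mainly to cross-check [estimate_growth_rates()], which must
#' reproduce them exactly.
#'
#' @param alpha1,alpha2 For `growth_rates_single`: driver CCF at the two
#'   timepoints. For the two-driver layouts: CCFs of drivers 1 and 2 at the
#'   first timepoint.
#' @param beta1,beta2 Driver CCFs at the second timepoint (two-driver
#'   layouts).
#' @param M1,M2 Total cell counts at the two timepoints.
#' @param delta Time between timepoints.
#' @return Numeric vector `c(r0, r1)` or `c(r0, r1, r2)`.
#' @export
growth_rates_single <- function(alpha1, alpha2, M1, M2, delta) {
  c(log((1 - alpha2) * M2 / ((1 - alpha1) * M1)) / delta,
    log(alpha2 * M2 / (alpha1 * M1)) / delta)
}

#' @rdname growth_rates_single
#' @export
growth_rates_nested <- function(alpha1, alpha2, beta1, beta2, M1, M2, delta) {
  c(log((1 - beta1) * M2 / ((1 - alpha1) * M1)) / delta,
    log((beta1 - beta2) * M2 / ((alpha1 - alpha2) * M1)) / delta,
    log(beta2 * M2 / (alpha2 * M1)) / delta)
}

#' @rdname growth_rates_single
#' @export
growth_rates_sibling <- function(alpha1, alpha2, beta1, beta2, M1, M2, delta) {
  c(log((1 - beta1 - beta2) * M2 / ((1 - alpha1 - alpha2) * M1)) / delta,
    log(beta1 * M2 / (alpha1 * M1)) / delta,
    log(beta2 * M2 / (alpha2 * M1)) / delta)
}

#' Expected time for a subclone to reach its observed size
#'
#' The expected first time a surviving birth-death process reaches size
#' \eqn{n = \alpha^c M} is
#' \eqn{(\log(n\, r/b) + \gamma_E)/r} (Gumbel mean, \eqn{\gamma_E \approx
#' 0.5772}); dropping the \eqn{\log(r/b) + \gamma_E} terms — negligible
#' against \eqn{\log n \approx 19} and more for realistic tumor sizes —
#' gives the estimator \eqn{\hat\tau = \log(\alpha^c M)/r}. Supplying the
#' birth rate `b` returns the exact form instead.
#'
#' @param ccf_excl Exclusive fraction of the clone at the observation.
#' @param M Total cell count at the observation.
#' @param r Net growth rate (> 0; rates below the minimal feasible rate
#'   should be substituted first, see [minimal_growth_rate()]).
#' @param b Optional birth rate for the exact variant.
#' @return Time since the clone's founding, in inverse units of `r`.
#' @seealso [et_approximation()] for the size of the dropped term and the
#'   resulting percent error.
#' @export
time_since_driver <- function(ccf_excl, M, r, b = NULL) {
  size <- ccf_excl * M
  if (any(size < 1)) stop("clone size alpha * M must be at least 1")
  if (any(r <= 0))
    stop("non-positive growth rate: substitute the minimal growth rate ",
         "(see minimal_growth_rate()) before timing the clone")
  if (is.null(b)) log(size) / r
  else (log(size * r / b) + EULER_GAMMA) / r
}

#' Accuracy of the logarithmic time-to-size approximation
#'
#' Compares the approximate time-to-observed-size \eqn{\log(n)/r} with the
#' exact Gumbel-mean form \eqn{(\log(n) + \log(r/b) + \gamma_E)/r}. Returns
#' the dropped term \eqn{\log(r/b)} and the percent error of the
#' approximation, which shrinks as the clone size grows (e.g. 7.3% at
#' `r/b = 0.1` and size `1e11`).
#'
#' @param size Clone size `n` at observation.
#' @param r_over_b Ratio of net growth rate to birth rate, in `(0, 1]`.
#' @return List with `dropped_term` (\eqn{\log(r/b)}) and `percent_error`
#'   (signed percent error of the approximate time).
#' @examples
#' et_approximation(exp(19.11), 0.5)$dropped_term  # -0.69
#' @export
et_approximation <- function(size, r_over_b) {
  if (any(r_over_b <= 0 | r_over_b > 1)) stop("'r_over_b' must lie in (0, 1]")
  if (any(size <= 1)) stop("'size' must exceed 1")
  dropped <- log(r_over_b)
  exact <- log(size) + dropped + EULER_GAMMA
  list(dropped_term = dropped,
       percent_error = (log(size) / exact - 1) * 100)
}

#' Mutation rate from the subclonal site frequency spectrum
#'
#' In an exponentially growing clone the expected number of subclonal
#' passengers with frequency in `[f1, f2]` is \eqn{(u/r)(1/f_1 - 1/f_2)};
#' summing over clones weighted by their exclusive fractions and solving
#' for `u` gives
#' \deqn{\hat u = \frac{f_1 f_2\, \gamma}{(f_2 - f_1) \sum_i \beta_i^c / r_i}.}
#' [expected_gamma()] is the exact inverse.
#'
#' @param gamma Subclonal mutation count in `[f1, f2]` (corrected for read
#'   filtering where applicable, see [gamma_corrected()]).
#' @param beta_excl Exclusive fractions of clones `0..k` at the timepoint
#'   the count was measured.
#' @param rates Net growth rates of clones `0..k` (all > 0 after any
#'   minimal-rate substitution).
#' @param f1,f2 Frequency window bounds.
#' @return Estimated mutation rate, in inverse units of `rates`.
#' @examples
#' # single driver: alpha2 = 0.6, r = 0.5, r1 = 1
#' estimate_mutation_rate(50, c(0.4, 0.6), c(0.5, 1), 0.01, 0.2)  # 0.3759
#' @export
estimate_mutation_rate <- function(gamma, beta_excl, rates, f1, f2) {
  .check_window(f1, f2)
  if (length(beta_excl) != length(rates))
    stop("'beta_excl' and 'rates' must have one entry per clone")
  if (gamma < 0) stop("'gamma' must be non-negative")
  s <- sum(beta_excl / rates)
  if (!is.finite(s) || s <= 0)
    stop("invalid rates: sum of beta_excl / rates must be positive")
  f1 * f2 * gamma / ((f2 - f1) * s)
}

#' @rdname estimate_mutation_rate
#' @param u Mutation rate.
#' @return For `expected_gamma`: the expected subclonal mutation count in
#'   `[f1, f2]`.
#' @export
expected_gamma <- function(u, beta_excl, rates, f1, f2) {
  .check_window(f1, f2)
  u * sum(beta_excl / rates) * (1 / f1 - 1 / f2)
}

#' Closed-form mutation rate estimates for the named clonal layouts
#'
#' Layout-specific forms of the mutation-rate estimator, used to cross-check
#' the general [estimate_mutation_rate()]: single driver
#' \eqn{u = f_1 f_2 r r_1 \gamma / [(f_2-f_1)(\alpha_2 r + r_1(1-\alpha_2))]},
#' and the nested/sibling analogues in terms of the driver fractions at the
#' measurement timepoint.
#'
#' @param gamma Subclonal mutation count in the window.
#' @param alpha2 Driver CCF at the measurement timepoint (single layout).
#' @param beta1,beta2 Driver CCFs at the measurement timepoint (two-driver
#'   layouts).
#' @param r,r0,r1,r2 Net growth rates.
#' @param f1,f2 Frequency window bounds.
#' @export
mutation_rate_single <- function(gamma, alpha2, r, r1, f1, f2) {
  f1 * f2 * r * r1 * gamma / ((f2 - f1) * (alpha2 * r + r1 * (1 - alpha2)))
}

#' @rdname mutation_rate_single
#' @export
mutation_rate_nested <- function(gamma, beta1, beta2, r0, r1, r2, f1, f2) {
  f1 * f2 * gamma /
    ((f2 - f1) * ((1 - beta1) / r0 + (beta1 - beta2) / r1 + beta2 / r2))
}

#' @rdname mutation_rate_single
#' @export
mutation_rate_sibling <- function(gamma, beta1, beta2, r0, r1, r2, f1, f2) {
  f1 * f2 * gamma /
    ((f2 - f1) * ((1 - beta1 - beta2) / r0 + beta1 / r1 + beta2 / r2))
}

#' Average mutation-rate estimates across timepoints
#'
#' When bulk sequencing is available at several timepoints the mutation
#' rate is estimated at each (with that timepoint's CCFs and mutation count)
#' and the estimates are averaged arithmetically.
#'
#' @param u Numeric vector of per-timepoint mutation-rate estimates.
#' @export
average_mutation_rate <- function(u) {
  if (!length(u)) stop("need at least one mutation-rate estimate")
  mean(u)
}

#' Correct a clone's clonal mutation count for post-driver fixation
#'
#' Passengers that arise after a driver and reach fixation in its subclone
#' are indistinguishable from the passengers that were present in the
#' subclone's founder cell; an expected `u / r` of them inflate the observed
#' branch-clonal count. For a clone whose parent is itself a driver
#' subclone, an expected `u / r_parent` of the founder's passengers fix in
#' the parent clone and are mis-assigned to the parent's branch, so they are
#' added back:
#' \deqn{\hat m = m_{obs} - u/r + u/r_{parent},}
#' with the parent term omitted for clones arising directly from the
#' initiated clone 0. The result is floored at 0.
#'
#' @param m_obs Observed branch-clonal passenger count.
#' @param u Mutation rate.
#' @param r Net growth rate of the clone (> 0).
#' @param r_parent Net growth rate of the parent clone if the parent is
#'   itself a driver subclone; `NULL` (default) when the parent is clone 0.
#' @return Corrected count `m`.
#' @examples
#' correct_clonal_count(12, u = 0.5, r = 0.25)               # 10
#' correct_clonal_count(8, u = 0.5, r = 0.5, r_parent = 0.25)  # 9
#' @export
correct_clonal_count <- function(m_obs, u, r, r_parent = NULL) {
  if (u < 0) stop("'u' must be non-negative")
  if (any(r <= 0)) stop("'r' must be positive")
  m <- m_obs - u / r
  if (!is.null(r_parent)) {
    if (any(r_parent <= 0)) stop("'r_parent' must be positive")
    m <- m + u / r_parent
  }
  pmax(m, 0)
}

#' Maximum-likelihood time of a driver mutation
#'
#' The passengers present in a driver's founder cell accumulated as a
#' Poisson process with rate `u` along the founding lineage, so the MLE of
#' the elapsed time is `m / u`. For nested drivers the times are waiting
#' times between consecutive drivers; absolute ages follow by summing along
#' the phylogeny's root path (see [driver_ages()]).
#'
#' @param m Corrected clonal passenger count (see [correct_clonal_count()]).
#' @param u Mutation rate (> 0).
#' @export
driver_time_mle <- function(m, u) {
  if (u <= 0) stop("undefined time: 'u' must be positive")
  if (any(m < 0)) stop("'m' must be non-negative")
  m / u
}

#' Absolute driver ages along the phylogeny
#'
#' Sums the per-driver waiting times `t_i` along each driver's root path and
#' anchors them at the age of the most recent common ancestor (clone 0).
#'
#' @param t Per-driver waiting times (time since the parent clone's own
#'   driver, or since initiation for children of clone 0).
#' @param parent Parent map of the drivers.
#' @param mrca_age Age at initiation of clone 0 (default 0 gives times on
#'   the tumor's own clock).
#' @return Numeric vector of absolute ages for drivers `1..k`.
#' @export
driver_ages <- function(t, parent, mrca_age = 0) {
  k <- length(t)
  ages <- numeric(k)
  for (i in seq_len(k)) {
    age <- mrca_age
    node <- i
    while (node != 0) {
      age <- age + t[node]
      node <- parent[node]
    }
    ages[i] <- age
  }
  ages
}

#' Age of the most recent common ancestor from truncal mutations
#'
#' Times the initiation of the parental clone 0 by the molecular clock of
#' its truncal mutations (those clonal in all cancer cells), in direct
#' analogy to the driver timing estimator: the truncal count is corrected
#' for the expected `u / r0` passengers that fixed in the whole tumor after
#' initiation, and divided by the mutation rate. This is an interpretation —
#' the clone-0 analogue of the driver formulas — and is isolated here.
#'
#' @param m_obs0 Observed truncal mutation count.
#' @param u Mutation rate (> 0).
#' @param r0 Net growth rate of clone 0 (> 0, after any minimal-rate
#'   substitution).
#' @return Estimated time from the patient's birth to tumor initiation.
#' @export
mrca_age <- function(m_obs0, u, r0) {
  if (u <= 0) stop("'u' must be positive")
  if (r0 <= 0) stop("'r0' must be positive")
  max(0, (m_obs0 - u / r0) / u)
}

#' Selective growth advantage of a driver
#'
#' `g = (r_child / r_parent - 1) * 100%`: the percent increase in net growth
#' rate conferred by the driver relative to its parent clone.
#'
#' @param r_child,r_parent Net growth rates; `r_parent` must be positive.
#' @return Advantage in percent.
#' @export
selective_advantage <- function(r_child, r_parent) {
  if (any(r_parent <= 0)) stop("undefined advantage: parent rate must be positive")
  (r_child / r_parent - 1) * 100
}

#' Full estimator pipeline on a simulated tumor
#'
#' Applies the complete inference chain to one [simulate_tumor()] result:
#' growth rates from the two checkpoints, mutation rate from the subclonal
#' count at the second checkpoint, corrected clonal counts and driver times,
#' and time between the last driver and first observation. By default the
#' error-free mutation count is used; supplying `coverage` simulates reads
#' and uses the filtered, corrected count instead.
#'
#' @param res A [simulate_tumor()] result with at least one driver.
#' @param f1,f2 Frequency window for the subclonal count (defaults 0.01 and
#'   0.2).
#' @param coverage Optional average read coverage; when given, reads are
#'   simulated at the second checkpoint and the corrected
#'   \eqn{\gamma} feeds the mutation-rate estimate.
#' @param purity,threshold Read-filter parameters (used with `coverage`).
#' @return List with `rates`, `u`, `m` (corrected counts), `t` (driver
#'   waiting times), `tau` (time from last driver to first observation),
#'   `t_uncorrected` (driver times without the fixation correction),
#'   `gamma` (count used) and the two observations.
#' @export
estimate_from_simulation <- function(res, f1 = 0.01, f2 = 0.2,
                                     coverage = NULL, purity = 1,
                                     threshold = 2) {
  stopifnot(inherits(res, "sim_result"))
  phylo <- res$phylo
  if (phylo$k < 1) stop("estimation needs at least one driver subclone")
  obs1 <- snapshot_to_observation(res, f1, f2, checkpoint = 1)
  obs2 <- snapshot_to_observation(res, f1, f2, checkpoint = 2)
  delta <- res$schedule$delta
  rates <- estimate_growth_rates(obs1$alpha, obs2$alpha, obs1$M, obs2$M,
                                 delta, phylo$parent)
  beta_excl <- clone_exclusive_fractions(obs2$alpha, phylo$parent)
  gamma <- if (is.null(coverage)) {
    obs2$gamma
  } else {
    freqs <- mutation_frequencies(res, checkpoint = 2)
    ro <- simulate_reads(freqs$ccf, obs2$M, coverage)
    gamma_corrected(gamma_observed(ro, f1, f2, threshold), f1, f2,
                    coverage, purity, threshold)
  }
  u <- estimate_mutation_rate(gamma, beta_excl, rates, f1, f2)
  k <- phylo$k
  r_parent <- lapply(seq_len(k), function(i) {
    p <- phylo$parent[i]
    if (p == 0L) NULL else rates[p + 1L]
  })
  m_obs <- obs2$m_obs[-1L]
  m <- vapply(seq_len(k), function(i)
    correct_clonal_count(m_obs[i], u, rates[i + 1L], r_parent[[i]]),
    numeric(1))
  t_drv <- driver_time_mle(m, u)
  t_unc <- driver_time_mle(m_obs, u)
  # time from the last driver (largest origin time) to first observation
  last <- which.max(phylo$t_origin)
  a_excl1 <- clone_exclusive_fractions(obs1$alpha, phylo$parent)
  tau <- time_since_driver(a_excl1[last + 1L], obs1$M, rates[last + 1L])
  list(rates = rates, u = u, gamma = gamma, m = m, t = t_drv,
       t_uncorrected = t_unc, tau = tau, last_driver = last,
       obs1 = obs1, obs2 = obs2)
}

#' Ground truth parameters of a simulated tumor
#'
#' @param res A [simulate_tumor()] result.
#' @return List with true `rates`, `u`, per-driver waiting times `t`
#'   (time since the parent clone's driver), and `tau` (time from the last
#'   driver to the first observation).
#' @export
sim_truth <- function(res) {
  phylo <- res$phylo
  origin <- c(0, phylo$t_origin)
  t_drv <- if (phylo$k > 0)
    phylo$t_origin - origin[phylo$parent + 1L] else numeric(0)
  last <- if (phylo$k > 0) which.max(phylo$t_origin) else 0L
  list(rates = phylo$net_rate, u = phylo$mutation_rate, t = t_drv,
       tau = res$schedule$first_obs_time -
         (if (phylo$k > 0) max(phylo$t_origin) else 0))
}
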