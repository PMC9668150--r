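#' Generate a synthetic patient bundle with known ground truth
#'
#' Emulates the shape of subclonal-reconstruction output for a patient whose
#' tumor followed the branching-process model exactly, so the patient-facing
#' pipeline can be tested end to end without external data. Expected clone
#' sizes follow the surviving-process mean \eqn{(b_i/r_i) e^{r_i (age -
#' origin_i)}} with optional lognormal perturbation; CCF posterior samples
#' are Beta-distributed around the true fractions with concentration
#' `kappa`; clonal counts are Poisson with the model means (waiting time
#' plus the post-driver fixation excess `u/r`, less the portion fixing in a
#' non-root parent); the observed subclonal count is Poisson with the
#' expected site-frequency-spectrum mass surviving the variant-read filter;
#' and the WBC series is consistent with the total size and blood volume.
#'
#' With `deterministic = TRUE` all draws are replaced by their expectations
#' (counts rounded), so the pipeline must recover the truth up to
#' correction-induced rounding — the end-to-end identity check.
#'
#' @param parent Parent map of the drivers (`1..k`).
#' @param birth,death Per-clone rates (per year), clone 0 first.
#' @param u True exome mutation rate (mutations/year).
#' @param origin_ages Patient ages (years) at which each clone appeared,
#'   clone 0 first; children must postdate parents.
#' @param obs_ages Ages of the bulk-sequencing timepoints (>= 2,
#'   increasing, after all origins).
#' @param kappa Beta concentration of the CCF posterior (default 500,
#'   roughly exome-scale posterior width); `Inf` gives point posteriors.
#' @param sigma_log Lognormal standard deviation of clone-size noise
#'   (default 0.1).
#' @param coverage,purity,threshold,f1,f2 Sequencing metadata used for the
#'   observed subclonal count.
#' @param n_posterior CCF posterior samples per clone per timepoint.
#' @param blood_volume_l Blood volume used for the WBC series.
#' @param deterministic Replace all noise by expectations (see above).
#' @param seed Optional integer seed.
#' @return List with `bundle` (a [patient_bundle()]) and `truth` (rates,
#'   `u`, `origin_ages`, waiting times `t`, exclusive sizes and totals).
#' @export
generate_patient_fixture <- function(parent, birth, death, u, origin_ages,
                                     obs_ages, kappa = 500, sigma_log = 0.1,
                                     coverage = 100, purity = 1,
                                     threshold = 2, f1 = 0.01, f2 = 0.2,
                                     n_posterior = 300, blood_volume_l = 5,
                                     deterministic = FALSE, seed = NULL) {
  k <- length(parent)
  r <- birth - death
  if (length(origin_ages) != k + 1L)
    stop("'origin_ages' must cover clones 0..k")
  if (any(r <= 0)) stop("fixture truth requires positive net growth rates")
  par_origin <- c(0, origin_ages[parent + 1L])
  if (any(origin_ages < par_origin))
    stop("inconsistent ages: a clone originates before its parent")
  if (length(obs_ages) < 2 || is.unsorted(obs_ages, strictly = TRUE) ||
      obs_ages[1] <= max(origin_ages))
    stop("'obs_ages' must be increasing and after all origin ages")
  if (!is.null(seed)) set.seed(seed)
  n_tp <- length(obs_ages)
  desc <- clone_descendants(parent, k)

  sizes <- sapply(obs_ages, function(a) {
    mu <- (birth / r) * exp(r * (a - origin_ages))
    if (deterministic) mu
    else mu * exp(rnorm(k + 1L, -sigma_log^2 / 2, sigma_log))
  })
  sizes <- matrix(sizes, nrow = k + 1L)
  M <- colSums(sizes)
  cum_ccf <- sapply(seq_len(n_tp), function(j)
    vapply(seq_len(k), function(i) sum(sizes[desc[[i + 1L]] + 1L, j]) / M[j],
           numeric(1)))
  cum_ccf <- matrix(cum_ccf, nrow = k)

  observations <- do.call(rbind, lapply(seq_len(n_tp), function(j)
    data.frame(timepoint = j, age_yr = obs_ages[j], M = M[j],
               clone = seq_len(k), cumulative_ccf = cum_ccf[, j])))

  rbeta_ccf <- function(a, n) {
    if (deterministic || !is.finite(kappa)) return(rep(a, n))
    stats::rbeta(n, kappa * a, kappa * (1 - a))
  }
  ccf_posterior <- do.call(rbind, lapply(seq_len(k), function(i)
    do.call(rbind, lapply(seq_len(n_tp), function(j)
      data.frame(clone = i, timepoint = j, draw = seq_len(n_posterior),
                 ccf = rbeta_ccf(cum_ccf[i, j], n_posterior))))))
  if (k == 0)
    ccf_posterior <- data.frame(clone = integer(0), timepoint = integer(0),
                                draw = integer(0), ccf = numeric(0))

  # branch-clonal counts: waiting time + own fixation excess, less the
  # share fixing in a non-root parent (mis-assigned up the tree)
  t_wait <- origin_ages - par_origin
  mean_m <- u * t_wait + u / r
  nonroot <- c(FALSE, parent != 0L)
  mean_m[nonroot] <- mean_m[nonroot] - u / r[c(1L, parent + 1L)][nonroot]
  mean_m <- pmax(mean_m, 0)
  m_obs <- if (deterministic) round(mean_m) else rpois(k + 1L, mean_m)

  cutoff <- 2 * threshold / (purity * coverage)
  excl <- sapply(seq_len(n_tp), function(j)
    clone_exclusive_fractions(cum_ccf[, j], parent))
  excl <- matrix(excl, nrow = k + 1L)
  gamma_obs <- vapply(seq_len(n_tp), function(j) {
    cc <- u * sum(excl[, j] / r)  # SFS constant of Eq gamma(x)=c(1/f1-1/x)
    mean_g <- cc * (1 / max(f1, cutoff) - 1 / f2)
    if (deterministic) round(mean_g) else rpois(1L, mean_g)
  }, numeric(1))
  gamma <- data.frame(timepoint = seq_len(n_tp), gamma_obs = gamma_obs,
                      f1 = f1, f2 = f2, coverage = coverage,
                      purity = purity, threshold = threshold)

  wbc <- data.frame(age_yr = obs_ages,
                    wbc_per_ul = M / (blood_volume_l * 1e6))

  bundle <- patient_bundle(
    patient_id = "synthetic-fixture", parent = parent,
    observations = observations, gamma = gamma, m_obs = m_obs,
    ccf_posterior = ccf_posterior, wbc = wbc,
    diagnosis_age = obs_ages[1],
    config = list(blood_volume_l = blood_volume_l,
                  leukocytosis_per_ul = 11500,
                  parent_origin_ages = origin_ages))
  truth <- list(rates = r, u = u, origin_ages = origin_ages, t = t_wait,
                tau = obs_ages[1] - max(origin_ages), sizes = sizes, M = M)
  list(bundle = bundle, truth = truth)
}
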