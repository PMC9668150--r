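#' Point estimates of evolutionary parameters for a patient
#'
#' Runs the deterministic estimator chain on a patient bundle: per-clone
#' growth rates from exponential fits to exclusive clone sizes (exact for
#' two timepoints), the exome mutation rate averaged over timepoints (with
#' the read-filter correction applied to each observed subclonal count),
#' corrected clonal counts and driver waiting times, the MRCA age from the
#' truncal count, absolute driver ages, time between the last driver and
#' first observation, selective advantages, and the age at detectability.
#' The minimal-growth-rate substitution is applied to downstream quantities
#' whenever a fitted rate is below the minimal feasible rate; raw fitted
#' rates are reported unchanged. Confidence intervals are produced
#' separately by [ci_pipeline()].
#'
#' @param bundle A [patient_bundle()].
#' @param threshold Detectability threshold in cells; defaults to the
#'   bundle's leukocytosis configuration.
#' @return A list with `rates` (raw fitted, per year), `rates_effective`
#'   (after minimal-rate substitution), `u`, `m`, `t` (driver waiting
#'   times), `mrca_age`, `driver_ages`, `tau`, `g` (selective advantage of
#'   each driver over its parent), `detect_age`, and `substituted` (which
#'   clones used the minimal rate).
#' @export
estimate_patient <- function(bundle, threshold = NULL) {
  stopifnot(inherits(bundle, "patient_bundle"))
  k <- bundle$n_clones - 1L
  parent <- bundle$parent
  tp <- sort(unique(bundle$observations$timepoint))
  n_tp <- length(tp)
  ages <- vapply(tp, function(t)
    bundle$observations$age_yr[match(t, bundle$observations$timepoint)],
    numeric(1))
  M <- vapply(tp, function(t)
    bundle$observations$M[match(t, bundle$observations$timepoint)],
    numeric(1))
  cum <- vapply(tp, function(t) {
    d <- bundle$observations[bundle$observations$timepoint == t, ]
    d$cumulative_ccf[match(seq_len(k), d$clone)]
  }, numeric(k))
  cum <- matrix(cum, nrow = k)
  excl <- vapply(seq_len(n_tp),
                 function(j) clone_exclusive_fractions(cum[, j], parent),
                 numeric(k + 1L))
  excl <- matrix(excl, nrow = k + 1L)
  sizes <- excl * matrix(M, nrow = k + 1L, ncol = n_tp, byrow = TRUE)
  fits <- lapply(seq_len(k + 1L), function(c) fit_growth(ages, sizes[c, ]))
  rates <- vapply(fits, `[[`, numeric(1), "rate")

  point_origin <- bundle$config$parent_origin_ages %||% rep(0, k + 1L)
  par_origin <- c(0, point_origin[parent + 1L])
  r_min <- minimal_growth_rate(pmax(sizes[, n_tp], 1 + 1e-9),
                               pmax(ages[n_tp] - par_origin, 1e-6))
  r_eff <- pmax(rates, r_min)
  substituted <- rates < r_min

  gam <- bundle$gamma
  f1 <- gam$f1[1]; f2 <- gam$f2[1]
  u_tp <- vapply(seq_len(n_tp), function(j) {
    g_row <- gam[gam$timepoint == tp[j], ]
    if (!nrow(g_row) || is.na(g_row$gamma_obs[1])) return(NA_real_)
    gc <- gamma_corrected(g_row$gamma_obs[1], f1, f2, g_row$coverage[1],
                          g_row$purity[1], g_row$threshold[1])
    estimate_mutation_rate(gc, excl[, j], r_eff, f1, f2)
  }, numeric(1))
  u <- average_mutation_rate(u_tp[!is.na(u_tp)])

  m <- vapply(seq_len(k), function(i) {
    p <- parent[i]
    correct_clonal_count(bundle$m_obs[i + 1L], u, r_eff[i + 1L],
                         if (p == 0L) NULL else r_eff[p + 1L])
  }, numeric(1))
  t_drv <- driver_time_mle(m, u)
  mrca <- mrca_age(bundle$m_obs[1], u, r_eff[1])
  age_drv <- driver_ages(t_drv, parent, mrca)
  last <- if (k > 0) which.max(age_drv) + 1L else 1L
  tau <- time_since_driver(max(excl[last, 1], 1.0000001 / M[1]), M[1],
                           r_eff[last])
  g <- if (k > 0) selective_advantage(rates[-1], rates[parent + 1L])
  else numeric(0)

  if (is.null(threshold))
    threshold <- wbc_to_cell_count(
      bundle$config$leukocytosis_per_ul %||% 11500,
      bundle$config$blood_volume_l %||% 5)
  th0 <- log(sizes[, n_tp]) - r_eff * ages[n_tp]
  detect <- tryCatch(
    detectability_time(cbind(th0, r_eff), threshold,
                       interval = c(0, ages[n_tp] + 50)),
    error = function(e) NA_real_)

  list(rates = rates, rates_effective = r_eff, u = u, u_by_timepoint = u_tp,
       m = m, t = t_drv, mrca_age = mrca, driver_ages = age_drv, tau = tau,
       g = g, detect_age = detect, substituted = substituted,
       fits = fits)
}
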