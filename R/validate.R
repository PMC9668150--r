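#' Parameter-recovery study on simulated tumors
#'
#' Simulates `n_runs` tumors under a standard regime, runs the full
#' estimator pipeline on each, and returns per-run percent errors of every
#' estimate against the simulation ground truth. Percent error is
#' `(estimate - truth) / truth * 100`; its mean over runs is the mean
#' percent error (MPE) and the mean of its absolute value the MAPE.
#'
#' @param regime,layout,u Passed to [tumor_regime()].
#' @param n_runs Number of simulated tumors.
#' @param seed Optional integer seed for the whole study.
#' @param f1,f2 Frequency window for the subclonal count.
#' @param max_events Per-run event budget.
#' @return A data frame with one row per (run, parameter): columns `run`,
#'   `parameter`, `truth`, `estimate`, `pe`. Parameters are `r0..rk`, `u`,
#'   `t1..tk` (corrected), `t1_uncorrected..`, and `tau`.
#' @seealso [mpe_table()] to summarize.
#' @export
validation_study <- function(regime = "fast", layout = "single", u = 1,
                             n_runs = 50, seed = NULL, f1 = 0.01, f2 = 0.2,
                             max_events = 5e8) {
  if (!is.null(seed)) set.seed(seed)
  reg <- tumor_regime(regime, layout, u)
  k <- reg$phylo$k
  rows <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    res <- simulate_tumor(reg$phylo, reg$schedule, max_events = max_events)
    # estimates are defined for runs where every clone is extant at both
    # observations ("surviving runs")
    if (any(res$checkpoints[[1]]$N == 0L) || any(res$checkpoints[[2]]$N == 0L))
      next
    est <- estimate_from_simulation(res, f1, f2)
    tru <- sim_truth(res)
    par_names <- c(paste0("r", 0:k), "u", paste0("t", seq_len(k)),
                   paste0("t", seq_len(k), "_uncorrected"), "tau")
    truth <- c(tru$rates, tru$u, tru$t, tru$t, tru$tau)
    estimate <- c(est$rates, est$u, est$t, est$t_uncorrected, est$tau)
    rows[[run]] <- data.frame(run = run, parameter = par_names,
                              truth = truth, estimate = estimate,
                              pe = (estimate - truth) / truth * 100)
  }
  do.call(rbind, rows)
}

#' Read-filter ablation study for the subclonal mutation count
#'
#' Simulates tumors, then for each simulated tumor draws `n_reps` replicate
#' read simulations at each requested coverage, measuring the observed
#' (post-filter) subclonal count, its corrected value, and their percent
#' errors against the true count from the true mutation frequencies at the
#' same checkpoint.
#'
#' @param regime,layout,u Passed to [tumor_regime()].
#' @param n_runs Number of simulated tumors.
#' @param n_reps Read-simulation replicates per tumor and coverage.
#' @param coverage Vector of average coverages to test.
#' @param purity,threshold Read-filter parameters.
#' @param f1,f2 Frequency window.
#' @param seed Optional integer seed.
#' @return Data frame with columns `run`, `rep`, `coverage`, `gamma_true`,
#'   `gamma_obs`, `gamma_corr`, `pe_obs`, `pe_corr`. The percent errors are
#'   computed over all (run, replicate) pairs.
#' @export
gamma_study <- function(regime = "fast", layout = "single", u = 1,
                        n_runs = 50, n_reps = 100, coverage = c(200, 100),
                        purity = 1, threshold = 2, f1 = 0.01, f2 = 0.2,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reg <- tumor_regime(regime, layout, u)
  rows <- list()
  for (run in seq_len(n_runs)) {
    res <- simulate_tumor(reg$phylo, reg$schedule)
    freqs <- mutation_frequencies(res, checkpoint = 2)
    M <- res$checkpoints[[2]]$M
    g_true <- sum(freqs$ccf >= f1 & freqs$ccf <= f2)
    if (g_true == 0) next  # percent error undefined for an empty window
    for (cov in coverage) {
      # mutations far below the filter cutoff 2L/(R) cannot pass it:
      # at ccf = cutoff/100 the pass probability is ~1e-6 and the expected
      # number passing from the dropped tail is < 0.1, so skipping them
      # leaves gamma_obs unchanged while removing the (vast) singleton tail
      min_ccf <- 2 * threshold / cov / 100
      ccf_sim <- freqs$ccf[freqs$ccf >= min_ccf]
      for (rep in seq_len(n_reps)) {
        ro <- simulate_reads(ccf_sim, M, cov)
        g_obs <- gamma_observed(ro, f1, f2, threshold)
        g_corr <- gamma_corrected(g_obs, f1, f2, cov, purity, threshold)
        rows[[length(rows) + 1L]] <- data.frame(
          run = run, rep = rep, coverage = cov, gamma_true = g_true,
          gamma_obs = g_obs, gamma_corr = g_corr,
          pe_obs = (g_obs - g_true) / g_true * 100,
          pe_corr = (g_corr - g_true) / g_true * 100)
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a validation study as an MPE/MAPE table
#'
#' @param study A [validation_study()] result.
#' @return Data frame with one row per parameter: `mpe`, `mape`, the
#'   percent-error quantiles (2.5, 25, 50, 75, 97.5) and `n_runs`.
#' @export
mpe_table <- function(study) {
  .check_columns(study, c("parameter", "pe"), "study")
  out <- do.call(rbind, lapply(split(study, study$parameter), function(d) {
    q <- quantile(d$pe, c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)
    data.frame(parameter = d$parameter[1], mpe = mean(d$pe),
               mape = mean(abs(d$pe)), q2.5 = q[1], q25 = q[2], q50 = q[3],
               q75 = q[4], q97.5 = q[5], n_runs = nrow(d))
  }))
  rownames(out) <- NULL
  out[order(out$parameter), ]
}
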