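# Shared, lazily built Monte Carlo batches. Full simulation objects are
# large, so each batch keeps only the per-run summaries the tests assert
# on; the underlying runs are generated once per session.
.batches <- new.env(parent = emptyenv())

# fast-growing tumor, one driver subclone (100% advantage), u = 1/day.
# One record per run: survival flag, the estimator-pipeline output, the
# true founder passenger count and the observed clonal counts.
fast_single_batch <- function(n = 30, seed = 101) {
  key <- sprintf("fast_single_%d_%d", n, seed)
  if (is.null(.batches[[key]])) {
    set.seed(seed)
    reg <- tumor_regime("fast", "single", u = 1)
    .batches[[key]] <- lapply(seq_len(n), function(i) {
      res <- simulate_tumor(reg$phylo, reg$schedule)
      surviving <- all(res$checkpoints[[1]]$N > 0L) &&
        all(res$checkpoints[[2]]$N > 0L)
      list(surviving = surviving,
           est = if (surviving) estimate_from_simulation(res),
           m_true = res$m_true,
           m_obs2 = res$checkpoints[[2]]$m_obs,
           t_origin = reg$phylo$t_origin,
           rates_true = reg$phylo$net_rate)
    })
  }
  .batches[[key]]
}

# single-clone fast-growing population observed late; per-run summaries of
# the second checkpoint (conditioned on survival to it) and restart counts
single_clone_batch <- function(n = 60, seed = 202) {
  key <- sprintf("single_clone_%d_%d", n, seed)
  if (is.null(.batches[[key]])) {
    set.seed(seed)
    phylo <- clone_phylogeny(0.14, 0.07, mutation_rate = 1)
    sched <- sim_schedule(150, 10)
    .batches[[key]] <- do.call(rbind, lapply(seq_len(n), function(i) {
      res <- simulate_tumor(phylo, sched)
      ccf <- mutation_frequencies(res, 2)$ccf
      data.frame(N2 = res$checkpoints[[2]]$N[1],
                 restarts = res$restarts$whole,
                 gamma_win = sum(ccf >= 0.01 & ccf <= 0.2))
    }))
  }
  .batches[[key]]
}

# hand-assembled sim_result with known mutation table, for boundary tests
fake_sim_result <- function(ccf, M = 1000, alpha = 0.5, m_obs = c(0L, 0L)) {
  cp <- list(time = 1, N = c(round(M * (1 - alpha)), round(M * alpha)),
             M = M, alpha = alpha,
             mutations = data.frame(id = seq_along(ccf),
                                    ancestor = 0L,
                                    carriers = round(ccf * M), ccf = ccf),
             m_obs = m_obs)
  structure(list(phylo = clone_phylogeny(c(0.14, 0.21), c(0.07, 0.07),
                                         parent = 0, t_origin = 50,
                                         mutation_rate = 1),
                 schedule = sim_schedule(100, 10),
                 checkpoints = list(cp, cp), m_true = 0L,
                 restarts = list(whole = 0L, clone = c(0L, 0L)),
                 n_events = 0),
            class = "sim_result")
}
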