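#' Simulate tumor evolution with a per-cell Gillespie algorithm
#'
#' Runs an exact continuous-time Monte Carlo simulation of the multi-type
#' branching process defined by `phylo`: every cell divides, dies, or gains
#' a new passenger mutation at its clone's rates, and each driver subclone
#' is founded by one uniformly chosen cell of its parent clone at the
#' scheduled origin time. Runs are conditioned on survival: extinction of
#' clone 0 before the drivers are founded (or, with no drivers, before the
#' end of the schedule) restarts the whole run, and extinction of a driver
#' subclone restarts that subclone from its founder cell at its origin time.
#' The full mutation state is recorded at the two scheduled observation
#' times (immediately before the first event crossing each).
#'
#' @param phylo A [clone_phylogeny()] (rates per day).
#' @param schedule A [sim_schedule()]; `first_obs_time` must exceed all
#'   driver origin times.
#' @param seed Optional integer seed; identical seed and configuration give
#'   bit-identical results.
#' @param max_events Event budget across the whole run including restarts;
#'   exceeding it is an error (guards near-critical `d` close to `b`
#'   regimes).
#' @return An object of class `sim_result`: a list with `phylo`, `schedule`,
#'   `checkpoints` (two snapshots, each with time, per-clone sizes `N`,
#'   total `M`, cumulative driver CCFs `alpha`, mutation table, per-clone
#'   branch-clonal counts `m_obs`), `m_true` (passengers in each driver's
#'   founder cell), restart counts and the event count.
#' @examples
#' reg <- tumor_regime("fast", "single", u = 1)
#' res <- simulate_tumor(reg$phylo, reg$schedule, seed = 1)
#' res$checkpoints[[2]]$N
#' @export
simulate_tumor <- function(phylo, schedule, seed = NULL, max_events = 5e8) {
  stopifnot(inherits(phylo, "clone_phylogeny"), inherits(schedule, "sim_schedule"))
  if (phylo$k > 0 && schedule$first_obs_time <= max(phylo$t_origin))
    stop("'first_obs_time' must be after all driver origin times")
  if (!is.finite(max_events) || max_events <= 0)
    stop("'max_events' must be positive")
  if (!is.null(seed)) set.seed(seed)
  raw <- .sim_gillespie_cpp(
    parent = c(-1L, phylo$parent), b = phylo$birth, d = phylo$death,
    t_origin = c(0, phylo$t_origin), u = phylo$mutation_rate,
    t_obs1 = schedule$first_obs_time,
    t_obs2 = schedule$first_obs_time + schedule$delta,
    max_events = max_events)
  desc <- clone_descendants(phylo$parent, phylo$k)
  times <- schedule$first_obs_time + c(0, schedule$delta)
  checkpoints <- lapply(1:2, function(cp) {
    snap <- if (cp == 1) raw$snapshot1 else raw$snapshot2
    .summarize_snapshot(raw$ancestor, snap, desc, phylo$parent, times[cp])
  })
  structure(
    list(phylo = phylo, schedule = schedule, checkpoints = checkpoints,
         m_true = raw$m_true[-1L],
         founder_label = raw$founder_label,
         restarts = list(whole = raw$restart_whole,
                         clone = raw$restart_clone),
         n_events = raw$n_events),
    class = "sim_result")
}

# Tabulate one checkpoint: per-clone sizes, carrier counts per mutation,
# CCFs, cumulative driver fractions and clonal mutation counts.
.summarize_snapshot <- function(ancestor, snap, desc, parent, time) {
  k <- length(snap) - 1L
  N <- vapply(snap, length, integer(1))
  M <- sum(N)
  tal <- .tally_carriers_cpp(ancestor, snap)
  carriers <- tal$carriers
  total <- if (nrow(carriers)) rowSums(carriers) else integer(0)
  mutations <- data.frame(id = tal$id, ancestor = tal$ancestor,
                          carriers = total,
                          ccf = if (M > 0) total / M else rep(NaN, length(total)))
  # cumulative CCF of driver i: cells in clone i's clade / M
  alpha <- if (k > 0 && M > 0) {
    vapply(1:k, function(i) sum(N[desc[[i + 1L]] + 1L]) / M, numeric(1))
  } else rep(NA_real_, max(k, 0))
  # clade-clonal count C(j): passengers present in every extant cell of
  # clone j's clade (itself plus descendants)
  clade_clonal <- vapply(0:k, function(j) {
    inside <- desc[[j + 1L]] + 1L
    inside <- inside[N[inside] > 0L]
    if (!length(inside)) return(NA_integer_)
    in_ok <- rep(TRUE, nrow(carriers))
    for (c in inside) in_ok <- in_ok & carriers[, c] == N[c]
    sum(in_ok)
  }, integer(1))
  # observed clonal count of driver j: its clade-clonal count, minus the
  # parent clade's when the parent is itself a driver subclone (those
  # passengers are assigned to the parent's branch); clone 0's count is the
  # truncal count. Since clade(j) is a subset of clade(parent), the parent's
  # clade-clonal set is contained in clone j's and the difference is valid.
  m_obs <- clade_clonal
  for (j in seq_len(k)) {
    p <- parent[j]
    if (p >= 1L && !is.na(m_obs[j + 1L]) && !is.na(clade_clonal[p + 1L]))
      m_obs[j + 1L] <- m_obs[j + 1L] - clade_clonal[p + 1L]
  }
  list(time = time, N = N, M = M, alpha = alpha, mutations = mutations,
       m_obs = m_obs)
}

#' @export
print.sim_result <- function(x, ...) {
  cp <- x$checkpoints
  cat("Simulated tumor:", x$phylo$k, "driver subclone(s);",
      format(x$n_events, big.mark = ","), "events;",
      x$restarts$whole, "whole-run restart(s)\n")
  cat(sprintf("  t = %g: N = (%s), M = %d\n", cp[[1]]$time,
              paste(cp[[1]]$N, collapse = ", "), cp[[1]]$M))
  cat(sprintf("  t = %g: N = (%s), M = %d\n", cp[[2]]$time,
              paste(cp[[2]]$N, collapse = ", "), cp[[2]]$M))
  invisible(x)
}

#' Mutation carrier counts and frequencies at a checkpoint
#'
#' Carrier counts are subtree sums over the mutation ancestor vector: a cell
#' carries mutation `n` if `n` lies on the ancestor chain of the cell's most
#' recent passenger label. Mutations with no extant carriers are removed.
#'
#' @param res A [simulate_tumor()] result.
#' @param checkpoint Which observation to use (1 or 2; default 2, the
#'   timepoint at which mutation counts are measured).
#' @return A data frame with columns `id`, `ancestor`, `carriers`, `ccf`.
#' @export
mutation_frequencies <- function(res, checkpoint = 2) {
  stopifnot(inherits(res, "sim_result"), checkpoint %in% 1:2)
  cp <- res$checkpoints[[checkpoint]]
  if (cp$M == 0) stop("tumor extinct at this checkpoint")
  cp$mutations
}

#' Convert a simulation checkpoint into a bulk observation
#'
#' Measures what bulk sequencing would: the total cell count, the cumulative
#' cancer cell fraction of each driver, the number of subclonal passengers
#' with frequency in the closed window `[f1, f2]` (here the error-free
#' "true" count), and the per-clone branch-clonal mutation counts.
#'
#' @inheritParams mutation_frequencies
#' @param f1,f2 Frequency window bounds, `0 < f1 < f2 <= 1`.
#' @return A `bulk_observation`: list with `time`, `M`, `alpha`, `gamma`,
#'   `f1`, `f2`, `m_obs`, `N`.
#' @export
snapshot_to_observation <- function(res, f1, f2, checkpoint = 2) {
  stopifnot(inherits(res, "sim_result"), checkpoint %in% 1:2)
  .check_window(f1, f2)
  cp <- res$checkpoints[[checkpoint]]
  if (cp$M == 0) stop("tumor extinct at this checkpoint")
  ccf <- cp$mutations$ccf
  structure(
    list(time = cp$time, M = cp$M, alpha = cp$alpha,
         gamma = sum(ccf >= f1 & ccf <= f2), f1 = f1, f2 = f2,
         m_obs = cp$m_obs, N = cp$N),
    class = "bulk_observation")
}

.check_window <- function(f1, f2) {
  if (!is.finite(f1) || !is.finite(f2) || f1 <= 0 || f2 > 1 || f1 >= f2)
    stop("need 0 < f1 < f2 <= 1")
}

#' First-passage times of a birth-death process
#'
#' Simulates the time for a single-type birth-death process started from one
#' cell to first reach `target_n` cells, conditioned on survival. For large
#' targets these times are Gumbel-distributed with standard deviation
#' \eqn{\pi / (\sqrt{6}\, r)} regardless of the target size.
#'
#' @param b,d Birth and death rates.
#' @param target_n Target population size.
#' @param n Number of replicates.
#' @param seed Optional integer seed.
#' @return Numeric vector of `n` first-passage times.
#' @export
first_passage_times <- function(b, d, target_n, n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) .first_passage_cpp(b, d, as.integer(target_n)),
         numeric(1))
}
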