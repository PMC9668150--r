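test_that("no passenger mutations arise when u = 0", {
  phylo <- clone_phylogeny(c(1, 1.5), c(0, 0), parent = 0, t_origin = 2,
                           mutation_rate = 0)
  res <- simulate_tumor(phylo, sim_schedule(4, 0.5), seed = 1)
  expect_equal(nrow(mutation_frequencies(res, 2)), 0L)
  expect_equal(res$m_true, 0L)
  expect_equal(res$checkpoints[[2]]$m_obs, c(0L, 0L))
})

test_that("pure-birth mean population size matches exp(b t)", {
  phylo <- clone_phylogeny(1, 0, mutation_rate = 0)
  sched <- sim_schedule(8, 0.1)
  set.seed(42)
  n <- 2000
  N <- vapply(seq_len(n), function(i)
    simulate_tumor(phylo, sched)$checkpoints[[1]]$N[1], integer(1))
  se <- sd(N) / sqrt(n)
  expect_lt(abs(mean(N) - exp(8)), 3 * se)
})

test_that("surviving-run conditional mean matches (b/r) exp(r t) and the
           restart fraction matches the extinction probability d/b", {
  batch <- single_clone_batch()
  b <- 0.14; d <- 0.07; r <- b - d
  # condition on survival at the second checkpoint (t = 160)
  scaled <- batch$N2 / exp(r * 160)
  se <- sd(scaled) / sqrt(length(scaled))
  expect_lt(abs(mean(scaled) - b / r), 3 * se)

  # every extinct attempt triggered one whole-run restart
  restarts <- sum(batch$restarts)
  attempts <- restarts + nrow(batch)
  phat <- restarts / attempts
  se_p <- sqrt(phat * (1 - phat) / attempts)
  expect_lt(abs(phat - d / b), 3 * se_p)
})

test_that("windowed site frequency spectrum matches (u/r)(1/f1 - 1/f2)", {
  batch <- single_clone_batch()
  expected <- (1 / 0.07) * (1 / 0.01 - 1 / 0.2)
  se <- sd(batch$gamma_win) / sqrt(nrow(batch))
  expect_lt(abs(mean(batch$gamma_win) - expected), 3 * se)
})

test_that("carrier counts are subtree sums over the ancestor vector", {
  # two-mutation chain across three cells: carriers(p1) = 2, carriers(p2) = 1
  tal <- clonechron:::.tally_carriers_cpp(c(0L, 1L), list(c(0L, 1L, 2L)))
  expect_equal(tal$id, c(1L, 2L))
  expect_equal(as.vector(tal$carriers), c(2L, 1L))

  # all cells on the deepest label of a chain: the root carries them all
  anc <- 0:4  # chain 1 <- 2 <- ... <- 5
  tal <- clonechron:::.tally_carriers_cpp(anc, list(rep(5L, 7L)))
  expect_equal(tal$carriers[tal$id == 1L], 7L)
  expect_equal(tal$carriers[tal$id == 5L], 7L)

  # labels split across two clones are summed per clone
  tal <- clonechron:::.tally_carriers_cpp(c(0L, 1L),
                                          list(c(1L, 1L), c(2L, 2L, 2L)))
  expect_equal(tal$carriers[tal$id == 1L, ], c(2L, 3L))
  expect_equal(tal$carriers[tal$id == 2L, ], c(0L, 3L))

  # an ancestor id at or above its own id is an invalid state
  expect_error(clonechron:::.tally_carriers_cpp(c(2L, 1L), list(1L)),
               "invalid ancestor")
})

test_that("mutation frequencies are consistent with the population", {
  reg <- tumor_regime("fast", "single", u = 1)
  res <- simulate_tumor(reg$phylo, reg$schedule, seed = 303)
  for (cp in 1:2) {
    mf <- mutation_frequencies(res, cp)
    M <- res$checkpoints[[cp]]$M
    expect_true(all(mf$carriers >= 1))          # extinct mutations removed
    expect_true(all(mf$carriers <= M))          # no mutation exceeds the tumor
    expect_equal(mf$ccf, mf$carriers / M)
    expect_true(all(mf$ancestor < mf$id))       # acyclic by construction
    expect_equal(sum(res$checkpoints[[cp]]$N), M)
  }
})

test_that("gamma window is boundary-inclusive and observations validated", {
  res <- fake_sim_result(c(0.005, 0.01, 0.15, 0.25))
  obs <- snapshot_to_observation(res, f1 = 0.01, f2 = 0.2)
  expect_equal(obs$gamma, 2L)  # 0.01 and 0.15 included, bounds closed
  obs2 <- snapshot_to_observation(res, f1 = 0.0099, f2 = 0.25)
  expect_equal(obs2$gamma, 3L)
  expect_error(snapshot_to_observation(res, 0.2, 0.1), "f1 < f2")
  expect_error(snapshot_to_observation(res, 0, 0.2), "f1")
})

test_that("clonal-count excess over founder passengers averages u/r1", {
  batch <- fast_single_batch()
  keep <- vapply(batch, `[[`, logical(1), "surviving")
  excess <- vapply(batch[keep], function(s)
    s$m_obs2[2] - s$m_true[1], numeric(1))
  r1 <- 0.14
  se <- sd(excess) / sqrt(length(excess))
  expect_lt(abs(mean(excess) - 1 / r1), 3 * se)
  # founder passenger counts follow the Poisson clock u * t1
  m_true <- vapply(batch, function(s) s$m_true[1], integer(1))
  t1 <- batch[[1]]$t_origin
  expect_lt(abs(mean(m_true) - t1),
            3 * sd(m_true) / sqrt(length(m_true)))
})

test_that("identical seed and configuration give bit-identical results", {
  reg <- tumor_regime("fast", "single", u = 1)
  a <- simulate_tumor(reg$phylo, reg$schedule, seed = 123)
  b <- simulate_tumor(reg$phylo, reg$schedule, seed = 123)
  expect_identical(a$checkpoints, b$checkpoints)
  expect_identical(a$m_true, b$m_true)
  expect_identical(a$n_events, b$n_events)
  c <- simulate_tumor(reg$phylo, reg$schedule, seed = 124)
  expect_false(identical(a$checkpoints, c$checkpoints))
})

test_that("the event budget guards runaway simulations", {
  phylo <- clone_phylogeny(1, 0, mutation_rate = 0)
  expect_error(simulate_tumor(phylo, sim_schedule(20, 1), seed = 1,
                              max_events = 100), "event budget")
})
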