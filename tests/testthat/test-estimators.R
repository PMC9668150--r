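test_that("exclusive fractions subtract child clades and sum to one", {
  expect_equal(clone_exclusive_fractions(0.6, parent = 0), c(0.4, 0.6))
  expect_equal(clone_exclusive_fractions(c(0.7, 0.3), parent = c(0, 1)),
               c(0.3, 0.4, 0.3))
  expect_equal(clone_exclusive_fractions(c(0.5, 0.3), parent = c(0, 0)),
               c(0.2, 0.5, 0.3))
  # three-level chain
  expect_equal(clone_exclusive_fractions(c(0.8, 0.5, 0.2),
                                         parent = c(0, 1, 2)),
               c(0.2, 0.3, 0.3, 0.2))
  # a child larger than its parent is inconsistent
  expect_error(clone_exclusive_fractions(c(0.3, 0.5), parent = c(0, 1)),
               "inconsistent")
  # tiny negative values are floating-point noise, clamped to zero
  expect_equal(clone_exclusive_fractions(c(0.5, 0.5 + 1e-12),
                                         parent = c(0, 1))[2], 0)
})

test_that("growth-rate estimates follow the log-ratio of clone sizes", {
  r <- estimate_growth_rates(0.2, 0.5, 1e5, 4e5, delta = 2, parent = 0)
  expect_equal(r[2], log(10) / 2)
  expect_equal(r[1], log(2.5) / 2)
  # no change in composition or size: zero rates
  expect_equal(estimate_growth_rates(0.4, 0.4, 1e5, 1e5, 2, 0), c(0, 0))
  # unobserved clone at a timepoint is an error
  expect_error(estimate_growth_rates(1, 0.5, 1e5, 1e5, 2, 0), "unobserved")
})

test_that("general growth-rate estimator reproduces the layout formulas", {
  set.seed(31)
  for (i in 1:20) {
    M1 <- 10^runif(1, 4, 6); M2 <- M1 * 10^runif(1, 0.1, 1)
    delta <- runif(1, 0.5, 3)
    # single driver
    a <- runif(1, 0.1, 0.9); b <- runif(1, 0.1, 0.9)
    expect_equal(estimate_growth_rates(a, b, M1, M2, delta, 0),
                 growth_rates_single(a, b, M1, M2, delta))
    # nested: alpha2 < alpha1
    a1 <- runif(1, 0.4, 0.9); a2 <- runif(1, 0.05, a1 - 0.1)
    b1 <- runif(1, 0.4, 0.9); b2 <- runif(1, 0.05, b1 - 0.1)
    expect_equal(estimate_growth_rates(c(a1, a2), c(b1, b2), M1, M2, delta,
                                       parent = c(0, 1)),
                 growth_rates_nested(a1, a2, b1, b2, M1, M2, delta))
    # siblings: alpha1 + alpha2 < 1
    a1 <- runif(1, 0.1, 0.4); a2 <- runif(1, 0.1, 0.5)
    b1 <- runif(1, 0.1, 0.4); b2 <- runif(1, 0.1, 0.5)
    expect_equal(estimate_growth_rates(c(a1, a2), c(b1, b2), M1, M2, delta,
                                       parent = c(0, 0)),
                 growth_rates_sibling(a1, a2, b1, b2, M1, M2, delta))
  }
})

test_that("time-to-observed-size approximation and its error terms", {
  # alpha * M = 1 founds the clone now
  expect_equal(time_since_driver(1e-5, 1e5, 0.5), 0)
  expect_equal(time_since_driver(0.5, 2e5, 0.5), log(1e5) / 0.5)
  # exact variant keeps the Gumbel-mean terms
  exact <- time_since_driver(0.5, 2e5, 0.5, b = 1)
  expect_equal(exact, (log(1e5 * 0.5) - digamma(1)) / 0.5)
  expect_error(time_since_driver(0.5, 2e5, -0.1), "minimal growth rate")

  # dropped-term anchors: log(1/2) and log(0.1) against log(alpha M) = 19.11
  ap <- et_approximation(exp(19.11), 0.5)
  expect_equal(round(ap$dropped_term, 2), -0.69)
  ap2 <- et_approximation(exp(19.11), 0.1)
  expect_equal(round(ap2$dropped_term, 2), -2.30)
  # percent error of the approximation at a 1e11-cell clone, r/b = 0.1
  expect_equal(et_approximation(1e11, 0.1)$percent_error, 7.3,
               tolerance = 0.01)
  # error shrinks with clone size
  expect_lt(abs(et_approximation(1e12, 0.5)$percent_error),
            abs(et_approximation(1e9, 0.5)$percent_error))
})

test_that("mutation-rate estimator inverts the expected windowed SFS", {
  # hand evaluation of the single-driver formula
  u <- estimate_mutation_rate(50, c(0.4, 0.6), c(0.5, 1), 0.01, 0.2)
  expect_equal(u, 0.05 / (0.19 * 0.7))
  expect_equal(u, mutation_rate_single(50, 0.6, 0.5, 1, 0.01, 0.2))
  # equal rates collapse to the single-clone SFS inversion
  expect_equal(estimate_mutation_rate(50, c(0.4, 0.6), c(0.5, 0.5),
                                      0.01, 0.2),
               50 * 0.5 * 0.01 * 0.2 / (0.2 - 0.01))
  # round trip with expected_gamma is exact
  set.seed(77)
  for (i in 1:20) {
    k <- sample(1:3, 1)
    excl <- clone_exclusive_fractions(
      sort(runif(k, 0.05, 0.9), decreasing = TRUE),
      parent = c(0, seq_len(k - 1)))
    rates <- runif(k + 1, 0.05, 2)
    g <- runif(1, 1, 100)
    u <- estimate_mutation_rate(g, excl, rates, 0.01, 0.2)
    expect_equal(expected_gamma(u, excl, rates, 0.01, 0.2), g)
  }
})

test_that("general mutation-rate estimator matches the layout formulas", {
  r <- c(0.4, 0.8, 1.2); f1 <- 0.01; f2 <- 0.2; g <- 30
  # nested with beta1 = 0.7, beta2 = 0.3
  excl <- clone_exclusive_fractions(c(0.7, 0.3), c(0, 1))
  expect_equal(estimate_mutation_rate(g, excl, r, f1, f2),
               mutation_rate_nested(g, 0.7, 0.3, r[1], r[2], r[3], f1, f2))
  # siblings with beta1 = 0.5, beta2 = 0.3
  excl <- clone_exclusive_fractions(c(0.5, 0.3), c(0, 0))
  expect_equal(estimate_mutation_rate(g, excl, r, f1, f2),
               mutation_rate_sibling(g, 0.5, 0.3, r[1], r[2], r[3], f1, f2))
})

test_that("clonal-count corrections and driver times compose", {
  expect_equal(correct_clonal_count(12, u = 0.5, r = 0.25), 10)
  expect_equal(correct_clonal_count(8, u = 0.5, r = 0.5, r_parent = 0.25), 9)
  expect_equal(correct_clonal_count(5, u = 0, r = 0.3), 5)
  expect_equal(correct_clonal_count(1, u = 2, r = 0.5), 0)  # floored
  expect_equal(driver_time_mle(10, 0.5), 20)
  expect_equal(driver_time_mle(0, 0.5), 0)
  expect_error(driver_time_mle(10, 0), "positive")
  # pipeline: observed 12, u = 0.5, r = 0.25 -> t = 20
  expect_equal(driver_time_mle(correct_clonal_count(12, 0.5, 0.25), 0.5), 20)
  # nested ages accumulate along the root path
  expect_equal(driver_ages(c(10, 5), parent = c(0, 1), mrca_age = 3),
               c(13, 18))
  expect_equal(driver_ages(c(10, 5), parent = c(0, 0), mrca_age = 3),
               c(13, 8))
  expect_equal(mrca_age(10, u = 0.5, r0 = 0.25), 16)
})

test_that("selective advantage and mutation-rate averaging", {
  expect_equal(selective_advantage(0.5, 0.5), 0)
  expect_equal(selective_advantage(1, 0.5), 100)
  expect_equal(selective_advantage(0.85, 0.5), 70)
  expect_error(selective_advantage(1, 0), "positive")
  expect_equal(average_mutation_rate(0.2), 0.2)
  expect_equal(average_mutation_rate(c(0.2, 0.4)), 0.3)
  expect_error(average_mutation_rate(numeric(0)), "at least one")
})

test_that("estimator pipeline output is internally consistent", {
  batch <- fast_single_batch()
  rec <- batch[vapply(batch, `[[`, logical(1), "surviving")][[1]]
  est <- rec$est
  expect_length(est$rates, 2)
  # mutation rate inverts back to the measured count
  bexcl <- clone_exclusive_fractions(est$obs2$alpha, 0L)
  expect_equal(expected_gamma(est$u, bexcl, est$rates, 0.01, 0.2),
               est$gamma)
  # corrected time is below the uncorrected one when u, r > 0
  expect_lt(est$t[1], est$t_uncorrected[1])

  reg <- tumor_regime("fast", "single", u = 1)
  res <- simulate_tumor(clone_phylogeny(c(1, 1.5), c(0, 0), parent = 0,
                                        t_origin = 1, mutation_rate = 0),
                        sim_schedule(3, 1), seed = 5)
  tru <- sim_truth(res)
  expect_equal(tru$rates, c(1, 1.5))
  expect_equal(tru$t, 1)
  expect_equal(tru$tau, 2)
})
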