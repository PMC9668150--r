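test_that("growth fits are exact with two points and report covariance", {
  f <- fit_growth(c(0, 2), c(1e5, 4e5))
  expect_equal(f$rate, log(4) / 2)
  expect_equal(f$intercept, log(1e5))
  expect_equal(f$cov, matrix(0, 2, 2))
  # collinear log sizes: zero residual, zero covariance
  tt <- c(0, 1, 2, 3)
  f3 <- fit_growth(tt, exp(2 + 0.5 * tt))
  expect_equal(f3$rate, 0.5)
  expect_equal(max(abs(f3$cov)), 0, tolerance = 1e-12)
  expect_error(fit_growth(c(0, 1), c(-1, 10)), "positive")
  expect_error(fit_growth(1, 10), "two")
})

test_that("reported fit covariance matches the resampling distribution", {
  set.seed(99)
  tt <- c(0, 1, 2, 3, 4)
  sigma <- 0.3
  fits <- replicate(2000, {
    y <- exp(1 + 0.4 * tt + rnorm(5, 0, sigma))
    f <- fit_growth(tt, y)
    c(f$rate, f$cov[2, 2])
  })
  emp_var <- var(fits[1, ])
  mean_reported <- mean(fits[2, ])
  expect_equal(mean_reported, emp_var, tolerance = 0.15)
})

test_that("growth-parameter sampling reproduces mean and covariance", {
  f <- structure(list(intercept = 2, rate = 0.5,
                      cov = matrix(c(0.04, 0.01, 0.01, 0.02), 2),
                      n = 5), class = "growth_fit")
  d <- sample_growth_params(f, 5000, seed = 3)
  expect_equal(colMeans(d), c(intercept = 2, rate = 0.5), tolerance = 0.02)
  expect_equal(unname(cov(d)), f$cov, tolerance = 0.1)
  # degenerate covariance: every draw is the mean
  f0 <- fit_growth(c(0, 2), c(1e5, 4e5))
  d0 <- sample_growth_params(f0, 10)
  expect_true(all(d0[, "rate"] == f0$rate))
})

test_that("minimal growth rate is the log size over the available time", {
  expect_equal(minimal_growth_rate(exp(10), 20), 0.5)
  expect_lt(minimal_growth_rate(1 + 1e-9, 10), 1e-9)
  expect_error(minimal_growth_rate(0.5, 10), "exceed")
  expect_error(minimal_growth_rate(10, 0), "positive")
})

test_that("driver-time posterior is Gamma(m + 1, u)", {
  n <- 5000
  d <- sample_t1_posterior(10, 0.5, n, seed = 7)
  se <- sd(d) / sqrt(n)
  expect_lt(abs(mean(d) - 11 / 0.5), 3 * se)
  # m = 0 reduces to an exponential with rate u
  d0 <- sample_t1_posterior(0, 2, n, seed = 8)
  expect_lt(abs(mean(d0) - 0.5), 3 * sd(d0) / sqrt(n))
  expect_error(sample_t1_posterior(5, 0, 10), "positive")
})

test_that("detectability root matches closed forms", {
  # single clone: t* = (log T - theta0) / theta1
  fits <- matrix(c(log(1e6), 0.5), 1)
  t_star <- (log(5.75e10) - log(1e6)) / 0.5
  expect_equal(detectability_time(fits, tol = 1e-10), t_star,
               tolerance = 1e-8)
  # two clones with equal rates
  fits2 <- rbind(c(2, 0.4), c(5, 0.4))
  t2 <- (log(5.75e10) - log(exp(2) + exp(5))) / 0.4
  expect_equal(detectability_time(fits2, tol = 1e-10), t2, tolerance = 1e-8)
  # threshold already reached at the bracket start
  expect_equal(detectability_time(matrix(c(30, 0.5), 1), threshold = 1e10),
               0)
  expect_error(detectability_time(matrix(c(1, -0.5), 1)), "positive growth")
})

test_that("first-passage dispersion matches the Gumbel scale pi/(sqrt(6) r)", {
  tt <- first_passage_times(1, 0, target_n = 1000, n = 500, seed = 21)
  s <- sd(tt)
  gumbel_sd <- pi / sqrt(6)  # r = 1
  se_sd <- s / sqrt(2 * length(tt))
  expect_lt(abs(s - gumbel_sd), 4 * se_sd)
  # dispersion independent of target size
  tt2 <- first_passage_times(1, 0, target_n = 4000, n = 500, seed = 22)
  expect_lt(abs(sd(tt2) - s), 4 * sqrt(se_sd^2 + (sd(tt2) / sqrt(1000))^2))
})

test_that("degenerate posteriors collapse the intervals to the point", {
  fx <- generate_patient_fixture(
    parent = 0, birth = c(1, 1.7), death = c(0.5, 0.7), u = 0.5,
    origin_ages = c(5, 20), obs_ages = c(35, 37),
    deterministic = TRUE, kappa = Inf, seed = 1)
  es <- ci_pipeline(fx$bundle, n_draws = 50, seed = 2)
  # rates have no sampled uncertainty here
  expect_equal(es$lower[["r0"]], es$upper[["r0"]])
  expect_equal(unname(es$point[c("r0", "r1")]), fx$truth$rates,
               tolerance = 1e-6)
  # medians lie inside their intervals
  expect_true(all(es$point >= es$lower & es$point <= es$upper, na.rm = TRUE))
  # a single draw gives interval == draw
  es1 <- ci_pipeline(fx$bundle, n_draws = 1, seed = 3)
  expect_equal(es1$lower, es1$upper)
  expect_equal(es1$point, es1$lower)
})

test_that("percentile intervals are monotone in the nominal level", {
  fx <- generate_patient_fixture(
    parent = 0, birth = c(1, 1.7), death = c(0.5, 0.7), u = 0.5,
    origin_ages = c(5, 20), obs_ages = c(35, 37), kappa = 300, seed = 11)
  es95 <- ci_pipeline(fx$bundle, n_draws = 300, seed = 4, ci = c(2.5, 97.5))
  es80 <- ci_pipeline(fx$bundle, n_draws = 300, seed = 4, ci = c(10, 90))
  expect_true(all(es80$lower >= es95$lower, na.rm = TRUE))
  expect_true(all(es80$upper <= es95$upper, na.rm = TRUE))
})
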