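test_that("read simulation draws have the binomial means", {
  set.seed(5)
  n <- 4000
  ro <- simulate_reads(rep(1, n), M = 1e5, coverage = 200)
  # chi = 1: E Z = R/2
  se <- sd(ro$alt_reads) / sqrt(n)
  expect_lt(abs(mean(ro$alt_reads) - 100), 3 * se)
  # site coverage: E R_i = R
  se_r <- sd(ro$coverage_site) / sqrt(n)
  expect_lt(abs(mean(ro$coverage_site) - 200), 3 * se_r)
  # chi = 0 never yields variant reads
  ro0 <- simulate_reads(rep(0, 500), M = 1e4, coverage = 100)
  expect_true(all(ro0$alt_reads == 0))
  expect_error(simulate_reads(0.5, M = 100, coverage = 200), "exceed")
  expect_error(simulate_reads(1.2, M = 1e4, coverage = 100), "\\[0, 1\\]")
})

test_that("observed gamma applies the frequency window and read filter", {
  obs <- list(alt_reads = c(1, 3, 25), coverage = 200)
  # frequencies 0.01, 0.03, 0.25; Z = 1 is filtered out, 0.25 outside window
  expect_equal(gamma_observed(obs, 0.01, 0.2, threshold = 2), 1)
  # everything filtered
  expect_equal(gamma_observed(list(alt_reads = c(0, 1, 2), coverage = 100),
                              0.01, 0.2, threshold = 2), 0)
  # threshold 0 keeps any mutation with a variant read in the window
  expect_equal(gamma_observed(obs, 0.005, 1, threshold = 0), 3)
})

test_that("gamma correction rescales by the unobserved window", {
  # hand evaluation: 10 * (100 - 5) / (50 - 5)
  expect_equal(gamma_corrected(10, 0.01, 0.2, coverage = 200),
               10 * 95 / 45)
  # cutoff exactly at f1: nothing lost, count unchanged
  expect_equal(gamma_corrected(7, 0.02, 0.2, coverage = 200), 7)
  # cutoff below f1 (deep coverage): clamped, no inflation
  expect_equal(gamma_corrected(7, 0.05, 0.2, coverage = 400), 7)
  expect_equal(gamma_corrected(0, 0.01, 0.2, coverage = 200), 0)
  # correction shrinks as coverage or purity grows (window shrinks)
  g100 <- gamma_corrected(10, 0.01, 0.2, coverage = 100)
  g200 <- gamma_corrected(10, 0.01, 0.2, coverage = 200)
  expect_gt(g100, g200)
  g_p5 <- gamma_corrected(10, 0.01, 0.2, coverage = 200, purity = 0.5)
  expect_gt(g_p5, g200)
  # no detectability window when the cutoff reaches f2
  expect_error(gamma_corrected(10, 0.01, 0.2, coverage = 18),
               "detectability")
})
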