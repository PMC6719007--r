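test_that("length mixture interpolates between maternal and fetal", {
  mat <- list(mean = 166, sd = 9)
  fet <- list(mean = 143, sd = 9)
  m0 <- length_mixture(0, mat, fet)
  m1 <- length_mixture(1, mat, fet)
  expect_equal(m0, fetalfrac:::discretized_normal(166, 9))
  expect_equal(m1, fetalfrac:::discretized_normal(143, 9))
  lens <- 50:220
  means <- sapply(seq(0, 1, by = 0.1),
                  function(f) sum(lens * length_mixture(f, mat, fet)))
  expect_true(all(diff(means) < 0))
})

test_that("noise level for a target correlation follows the closed form", {
  expect_equal(noise_sd_for_target_correlation(0.04, 1), 0)
  expect_equal(noise_sd_for_target_correlation(0.04, 0.5), 0.04 * sqrt(3),
               tolerance = 1e-12)
  expect_error(noise_sd_for_target_correlation(0.04, 0), "correlation")
  set.seed(81)
  s <- rnorm(20000, sd = 0.04)
  x <- s + rnorm(20000, sd = noise_sd_for_target_correlation(0.04, 0.7))
  expect_equal(cor(x, s), 0.7, tolerance = 0.01)
})

test_that("simulated cohorts carry the calibrated statistical structure", {
  ds <- simulate_dataset(sim_config(n_samples = 2000, seed = 82))
  s <- ds$samples
  expect_true(all(s$true_ff >= 0.02 & s$true_ff <= 0.30))
  expect_equal(cor(s$seqff_value, s$true_ff), 0.877, tolerance = 0.03)
  expect_true(all(abs(rowSums(ds$profiles) - 1) < 1e-9))

  # mean fragment length decreases across FF bins
  lens <- 50:220
  mean_len <- drop(ds$profiles %*% lens)
  bin <- cut(s$true_ff, breaks = quantile(s$true_ff, 0:5 / 5),
             include.lowest = TRUE)
  expect_true(all(diff(tapply(mean_len, bin, mean)) < 0))
})

test_that("at infinite depth with no noise the FRAC statistic is a smooth deterministic function of FF", {
  ds <- simulate_dataset(sim_config(n_samples = 100,
                                    fragments_per_sample = Inf,
                                    length_signal_rho = 1,
                                    maternal_jitter_sd = 0,
                                    chry_noise_sd = 0, seed = 83))
  fv <- frac_statistic(ds$profiles, optimal_intervals())
  ord <- order(ds$samples$true_ff)
  expect_true(all(diff(fv[ord]) > 0))   # strictly monotone in FF
  ds2 <- simulate_dataset(sim_config(n_samples = 100,
                                     fragments_per_sample = Inf,
                                     length_signal_rho = 1,
                                     maternal_jitter_sd = 0,
                                     chry_noise_sd = 0, seed = 83))
  expect_identical(ds$profiles, ds2$profiles)
})

test_that("fixtures round-trip and are byte-deterministic given the seed", {
  ds <- quick_cohort(n = 20, seed = 84)
  d1 <- tempfile(); d2 <- tempfile()
  write_fixture(ds, d1)
  back <- load_profile_table(file.path(d1, "profiles.tsv"))
  expect_equal(back$profiles, ds$profiles, tolerance = 1e-12)
  expect_equal(back$samples$true_ff, ds$samples$true_ff,
               tolerance = 1e-12)
  ds2 <- quick_cohort(n = 20, seed = 84)
  write_fixture(ds2, d2)
  expect_identical(readLines(file.path(d1, "profiles.tsv")),
                   readLines(file.path(d2, "profiles.tsv")))
  expect_true(file.exists(file.path(d1, "config.yaml")))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(fetal_mean = 170), "shorter")
  expect_error(sim_config(seqff_rho = 1.2), "correlations")
  expect_error(sim_config(ff_bounds = c(0.3, 0.1)), "bounds")
})
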