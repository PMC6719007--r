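test_that("metric definitions and degenerate-input errors", {
  a <- c(0.1, 0.2, 0.3)
  expect_equal(pearson(a, a), 1)
  expect_equal(mse(a, a), 0)
  expect_equal(mae(a, a), 0)
  expect_equal(pearson(a, -a), -1)
  expect_equal(mse(c(0, 1), c(0.1, 0.9)), 0.01)
  expect_equal(mae(c(0, 1), c(0.1, 0.9)), 0.1)
  expect_error(pearson(a, rep(1, 3)), "zero variance")
  expect_error(pearson(a, a[1:2]), "aligned")
})

test_that("metrics are permutation invariant", {
  set.seed(71)
  a <- runif(30); b <- runif(30)
  p <- sample(30)
  expect_equal(pearson(a, b), pearson(a[p], b[p]))
  expect_equal(mse(a, b), mse(a[p], b[p]))
  expect_equal(mae(a, b), mae(a[p], b[p]))
})

test_that("repeated splits use the documented fold sizes and are paired", {
  ds <- quick_cohort(n = 2454, seed = 72)
  res <- repeated_split_evaluate(ds, method_seqff(), n_repeats = 2,
                                 seed = 7)
  expect_equal(res$config$n_train, 1963)
  expect_equal(res$config$n_test, 491)
  expect_equal(unique(res$metrics$n_train), 1963)
  expect_equal(unique(res$metrics$n_test), 491)
})

test_that("evaluation is deterministic and a leaked predictor is perfect", {
  ds <- quick_cohort(n = 150, seed = 73)
  leak <- ds
  leak$samples$seqff_value <- leak$samples$reference_ff
  res1 <- repeated_split_evaluate(leak, list(method_seqff(),
                                             method_frac()),
                                  n_repeats = 5, seed = 9)
  res2 <- repeated_split_evaluate(leak, list(method_seqff(),
                                             method_frac()),
                                  n_repeats = 5, seed = 9)
  expect_identical(res1$metrics, res2$metrics)
  sq <- res1$metrics[res1$metrics$method == "seqff", ]
  expect_equal(sq$pearson, rep(1, 5))
  expect_equal(sq$mse, rep(0, 5))
})

test_that("a failing method is recorded without aborting the run", {
  ds <- quick_cohort(n = 80, seed = 74)
  ds$samples$seqff_value <- NA_real_
  res <- repeated_split_evaluate(ds, list(method_seqff(), method_lrm()),
                                 n_repeats = 2, seed = 5)
  sq <- res$metrics[res$metrics$method == "seqff", ]
  expect_true(all(!is.na(sq$error)))
  lr <- res$metrics[res$metrics$method == "lrm", ]
  expect_true(all(is.na(lr$error)))
})

test_that("attribute correlations are recovered and degenerate ones omitted", {
  ds <- simulate_dataset(sim_config(n_samples = 5000, seed = 75,
                                    fragments_per_sample = Inf))
  tab <- attribute_correlations(ds)
  r <- setNames(tab$r, tab$attribute)
  expect_lt(abs(r["ga"] - 0.1), 0.04)
  expect_lt(abs(r["bmi"] + 0.33), 0.04)
  expect_lt(abs(r["lc"] + 0.22), 0.04)

  ds2 <- simulate_dataset(sim_config(n_samples = 5000, seed = 76,
                                     fragments_per_sample = Inf,
                                     ga_rho = 0))
  tab2 <- attribute_correlations(ds2)
  expect_lt(abs(tab2$r[tab2$attribute == "ga"]), 0.05)

  ds2$samples$bmi <- 25               # constant -> omitted with a note
  tab3 <- attribute_correlations(ds2)
  expect_false("bmi" %in% tab3$attribute)
  expect_equal(attr(tab3, "omitted"), "bmi")
})

test_that("weighting with multiplier 1 reproduces the unweighted run", {
  ds <- quick_cohort(n = 150, seed = 77)
  we <- weighting_experiment(ds, multipliers = c(1, 2), n_repeats = 3,
                             seed = 11, method = method_frac())
  ev <- repeated_split_evaluate(ds, method_frac(), n_repeats = 3,
                                seed = 11)
  m1 <- we$metrics[we$metrics$multiplier == 1, ]
  expect_equal(m1$mae_low, ev$metrics$mae_low)
  expect_equal(m1$mae_high, ev$metrics$mae_high)
})

test_that("length-method comparison shows search improving on the published ratio", {
  ds <- simulate_dataset(sim_config(n_samples = 600, seed = 78))
  y <- ds$samples$reference_ff
  sr <- search_best_intervals(ds$profiles, y, stride = 4, min_width = 4)
  expect_gt(sr$correlation,
            cor(frac_statistic(ds$profiles, published_intervals()), y))
  res <- repeated_split_evaluate(
    ds, list(method_frac(published_intervals(), name = "frac_pub"),
             method_frac(sr$intervals), method_lrm()),
    n_repeats = 10, seed = 13)
  w <- reshape(res$metrics[, c("repeat_", "method", "pearson")],
               direction = "wide", idvar = "repeat_", timevar = "method")
  names(w) <- sub("pearson[.]", "", names(w))
  # the searched ratio beats the fixed published intervals in most splits
  expect_gte(sum(w$frac >= w$frac_pub), 8)
  # all length-based estimators correlate strongly with the reference
  expect_true(all(res$metrics$pearson > 0.5))
})
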