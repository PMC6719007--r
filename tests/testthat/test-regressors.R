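test_that("linear model recovers exact linear targets and handles rank deficiency", {
  x <- rand_profiles(60, seed = 51)
  set.seed(52)
  beta <- rnorm(171, sd = 0.05)
  y <- 0.1 + drop(x %*% beta)
  fit <- fit_lrm(x, y)
  expect_lt(max(abs(predict(fit, x) - y)), 1e-10)

  # duplicated feature columns: minimum-norm solution stays well-defined
  xd <- cbind(x, x[, 1:10])
  colnames(xd) <- make.unique(colnames(xd))
  fit2 <- fit_lrm(xd, y)
  expect_true(all(is.finite(c(fit2$intercept, fit2$coef))))
  expect_lt(max(abs(predict(fit2, xd) - y)), 1e-8)

  # constant features -> intercept-only -> mean of targets
  xc <- matrix(0.3, 20, 4)
  yc <- runif(20)
  fit3 <- fit_lrm(xc, yc)
  expect_equal(unname(predict(fit3, xc)), rep(mean(yc), 20),
               tolerance = 1e-10)
})

test_that("SVR learns a noiseless profile-linear signal", {
  ds <- simulate_dataset(sim_config(n_samples = 300,
                                    fragments_per_sample = Inf,
                                    length_signal_rho = 1,
                                    maternal_jitter_sd = 0,
                                    chry_noise_sd = 0, seed = 53))
  y <- ds$samples$true_ff
  std <- fit_standardizer(ds$profiles[1:200, ])
  m <- fit_svr(apply_standardizer(std, ds$profiles[1:200, ]), y[1:200])
  held <- predict(m, apply_standardizer(std, ds$profiles[201:300, ]))
  expect_gte(cor(held, y[201:300]), 0.99)
})

test_that("an epsilon tube wider than the target range flattens the fit", {
  set.seed(54)
  x <- scale(matrix(rnorm(100 * 20), 100, 20))
  y <- runif(100, 0.05, 0.25)
  m <- fit_svr(x, y, epsilon = 1)
  expect_equal(sd(predict(m, x)), 0, tolerance = 1e-12)
})

test_that("SVR predictions are insensitive to sample order", {
  set.seed(55)
  x <- scale(matrix(rnorm(150 * 30), 150, 30))
  y <- 0.1 + 0.03 * x[, 1] + rnorm(150, sd = 0.005)
  m1 <- fit_svr(x, y)
  p <- sample(150)
  m2 <- fit_svr(x[p, ], y[p])
  xnew <- matrix(rnorm(20 * 30), 20, 30)
  expect_lt(max(abs(predict(m1, xnew) - predict(m2, xnew))), 2e-3)
})

test_that("SVR warns on visibly unstandardized input", {
  set.seed(56)
  x <- matrix(rnorm(50 * 5, sd = 40), 50, 5)
  expect_warning(fit_svr(x, runif(50)), "standardize")
})

test_that("SVR agrees with an exact reference solver", {
  skip_if_not_installed("e1071")
  ds <- simulate_dataset(sim_config(n_samples = 300, seed = 57))
  y <- ds$samples$reference_ff
  std <- fit_standardizer(ds$profiles)
  xs <- apply_standardizer(std, ds$profiles)
  mine <- fit_svr(xs, y, max_sweeps = 100000)   # run to full convergence
  ref <- e1071::svm(xs, y, type = "eps-regression", kernel = "linear",
                    epsilon = 0.01, tolerance = 0.001, cost = 1,
                    scale = FALSE)
  pm <- predict(mine, xs)
  pr <- unname(predict(ref, xs))
  expect_true(mine$converged)
  # residual disagreement reflects the regularized-vs-free intercept and
  # libsvm's own stopping tolerance
  expect_gte(cor(pm, pr), 0.998)
  expect_lt(max(abs(pm - pr)), 0.01)
})

test_that("the MLP learns a noiseless linear signal on profile features", {
  ds <- simulate_dataset(sim_config(n_samples = 500,
                                    fragments_per_sample = Inf,
                                    length_signal_rho = 1,
                                    maternal_jitter_sd = 0.5,
                                    chry_noise_sd = 0, seed = 58))
  std <- fit_standardizer(ds$profiles[1:400, ])
  xs <- apply_standardizer(std, ds$profiles[1:400, ])
  xt <- apply_standardizer(std, ds$profiles[401:500, ])
  set.seed(59)
  beta <- rnorm(171, sd = 0.01)
  y <- 0.1 + drop(xs %*% beta)
  yt <- 0.1 + drop(xt %*% beta)
  m <- fit_mlp(xs, y, seed = 11)
  expect_gte(cor(predict(m, xt), yt), 0.95)

  # determinism: same seed, same data -> bit-identical predictions
  m2 <- fit_mlp(xs, y, seed = 11)
  expect_identical(predict(m, xt), predict(m2, xt))

  # constant targets -> constant predictions
  mc <- fit_mlp(xs, rep(0.15, 400), seed = 11)
  expect_lt(max(abs(predict(mc, xs) - 0.15)), 1e-3)
})
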