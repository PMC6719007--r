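#' Linear regression on the full length profile
#'
#' Least-squares fit of fetal fraction on all 171 length proportions plus an
#' intercept. The solution is the minimum-norm one when the design is
#' rank-deficient (the profile columns sum to one, so the design always has
#' at least one exact collinearity with the intercept).
#'
#' @param x Matrix of length profiles (samples x features).
#' @param y Fetal-fraction targets.
#' @return An `lrm_params` with `intercept` and `coef`.
#' @export
fit_lrm <- function(x, y) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need at least 2 samples")
  assert_that(nrow(x) == length(y), "targets must align with rows")
  sol <- lstsq_minnorm(cbind(1, x), y)
  structure(list(intercept = sol$coef[1],
                 coef = setNames(sol$coef[-1], colnames(x)),
                 rank = sol$rank),
            class = "lrm_params")
}

#' Predict from a fitted length-profile linear model
#' @param object An `lrm_params`.
#' @param x Matrix (or single profile vector) of features.
#' @param ... Unused.
#' @return FF estimates.
#' @export
predict.lrm_params <- function(object, x, ...) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  drop(object$intercept + m %*% object$coef)
}

#' Linear epsilon-insensitive support vector regression
#'
#' Linear-kernel SVR with the epsilon-insensitive loss, solved by
#' deterministic dual coordinate descent. Defaults follow the
#' grid-searched NIPT setting: epsilon 0.01, penalty C = 1, stopping
#' tolerance 0.001. Inputs are expected to be standardized (see
#' [fit_standardizer()]); a warning is issued when column variances look
#' unstandardized.
#'
#' @param x Standardized feature matrix (samples x features).
#' @param y Fetal-fraction targets.
#' @param epsilon Half-width of the insensitive tube (default 0.01).
#' @param cost Penalty parameter C (default 1).
#' @param tol Stopping tolerance on the projected gradient (default 0.001).
#' @param max_sweeps Hard cap on coordinate sweeps (default 2000). The
#'   dual of this problem has near-flat directions (cfDNA profiles are
#'   strongly collinear), so the duality gap closes slowly after held-out
#'   predictions have stabilized; the cap trades exactness of the dual
#'   optimum for speed while leaving predictions within noise of an exact
#'   solver's (see the package tests for the cross-check).
#' @return An `svr_model` with weight vector `w`, intercept `b`, and
#'   convergence info.
#' @export
fit_svr <- function(x, y, epsilon = 0.01, cost = 1, tol = 0.001,
                    max_sweeps = 2000L) {
  x <- as.matrix(x)
  assert_that(nrow(x) == length(y), "targets must align with rows")
  v <- apply(x, 2, var)
  nondeg <- v > 1e-12
  if (any(nondeg) && (mean(v[nondeg]) > 2 || mean(v[nondeg]) < 0.5))
    warning("feature variances far from 1; did you standardize the input?",
            call. = FALSE)
  ybar <- mean(y)
  fit <- .svr_dcd(t(cbind(x, 1)), y - ybar, cost, epsilon, tol,
                  as.integer(max_sweeps))
  d <- ncol(x)
  structure(list(w = setNames(fit$w[seq_len(d)], colnames(x)),
                 b = fit$w[d + 1] + ybar,
                 epsilon = epsilon, cost = cost, tol = tol,
                 sweeps = fit$sweeps, converged = fit$converged,
                 n_sv = sum(fit$beta != 0)),
            class = "svr_model")
}

#' @export
print.svr_model <- function(x, ...) {
  cat("<svr_model> linear kernel, eps", x$epsilon, "C", x$cost, "-",
      x$n_sv, "support vectors,", x$sweeps, "sweeps\n")
  invisible(x)
}

#' Predict from a fitted linear SVR
#' @param object An `svr_model`.
#' @param x Standardized feature matrix (or single row).
#' @param ... Unused.
#' @return FF estimates.
#' @export
predict.svr_model <- function(object, x, ...) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  drop(m %*% object$w + object$b)
}

#' Multilayer-perceptron regression on standardized profiles
#'
#' Fully connected regressor with two hidden layers of 25 units each,
#' hyperbolic-tangent activations, a linear output, mean squared loss, and
#' full-batch Adagrad updates. Training is seeded and bit-reproducible.
#' Targets are centred/scaled internally for conditioning and mapped back
#' at prediction time.
#'
#' @param x Standardized feature matrix (samples x features).
#' @param y Fetal-fraction targets.
#' @param hidden Hidden layer widths (default `c(25, 25)`).
#' @param learning_rate Adagrad learning rate (default 0.15).
#' @param epochs Full-batch epochs (default 1500).
#' @param seed RNG seed for weight initialization (default 17).
#' @return An `mlp_model`.
#' @export
fit_mlp <- function(x, y, hidden = c(25L, 25L), learning_rate = 0.15,
                    epochs = 1500L, seed = 17L) {
  x <- as.matrix(x)
  assert_that(nrow(x) == length(y), "targets must align with rows")
  n <- nrow(x)
  mu_y <- mean(y); sd_y <- sd(y)
  degenerate <- !is.finite(sd_y) || sd_y < 1e-12
  if (degenerate) sd_y <- 1
  yt <- (y - mu_y) / sd_y
  sizes <- c(ncol(x), hidden, 1L)
  nl <- length(sizes) - 1L
  weights <- vector("list", nl); biases <- vector("list", nl)
  with_preserved_rng({
    set.seed(seed)
    for (l in seq_len(nl)) {
      sdw <- sqrt(2 / (sizes[l] + sizes[l + 1]))  # Xavier
      weights[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sdw),
                             sizes[l], sizes[l + 1])
      biases[[l]] <- numeric(sizes[l + 1])
    }
  })
  if (degenerate) {             # nothing to learn; predict the mean exactly
    weights[[nl]][] <- 0
    epochs <- 0L
  }
  gw <- lapply(weights, function(w) w * 0)
  gb <- lapply(biases, function(b) b * 0)
  loss <- 0
  for (ep in seq_len(epochs)) {
    acts <- vector("list", nl + 1L); acts[[1]] <- x
    for (l in seq_len(nl)) {
      z <- sweep(acts[[l]] %*% weights[[l]], 2, biases[[l]], "+")
      acts[[l + 1]] <- if (l < nl) tanh(z) else z
    }
    out <- drop(acts[[nl + 1]])
    loss <- mean((out - yt)^2)
    if (!is.finite(loss))
      stop_ff("MLP training diverged (non-finite loss at epoch ", ep, ")",
              class = "ff_nonconvergence_error")
    delta <- matrix(2 * (out - yt) / n, ncol = 1)
    for (l in rev(seq_len(nl))) {
      dw <- crossprod(acts[[l]], delta)
      db <- colSums(delta)
      if (l > 1) delta <- (delta %*% t(weights[[l]])) *
          (1 - acts[[l]]^2)  # tanh'
      gw[[l]] <- gw[[l]] + dw^2
      gb[[l]] <- gb[[l]] + db^2
      weights[[l]] <- weights[[l]] - learning_rate * dw / sqrt(gw[[l]] + 1e-8)
      biases[[l]] <- biases[[l]] - learning_rate * db / sqrt(gb[[l]] + 1e-8)
    }
  }
  structure(list(weights = weights, biases = biases, mu_y = mu_y,
                 sd_y = sd_y, hidden = hidden, seed = seed,
                 epochs = epochs, learning_rate = learning_rate,
                 final_loss = loss),
            class = "mlp_model")
}

#' @export
print.mlp_model <- function(x, ...) {
  cat("<mlp_model> tanh layers", paste(x$hidden, collapse = "+"),
      "- final training MSE", format(x$final_loss * x$sd_y^2), "\n")
  invisible(x)
}

#' Predict from a fitted MLP
#' @param object An `mlp_model`.
#' @param x Standardized feature matrix (or single row).
#' @param ... Unused.
#' @return FF estimates.
#' @export
predict.mlp_model <- function(object, x, ...) {
  a <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  nl <- length(object$weights)
  for (l in seq_len(nl)) {
    z <- sweep(a %*% object$weights[[l]], 2, object$biases[[l]], "+")
    a <- if (l < nl) tanh(z) else z
  }
  drop(a) * object$sd_y + object$mu_y
}
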