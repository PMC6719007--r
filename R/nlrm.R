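#' Nonlinear ratio-regression parameters
#'
#' Weights of the nonlinear ratio model: fetal fraction is modelled as a
#' weighted sum of numerator-interval proportions over a weighted sum of
#' denominator-interval proportions. The ratio is invariant to a common
#' rescaling of all weights, so for identifiability the first denominator
#' weight is fixed at 1.
#'
#' @param m_weights Numerator weights, one per length in `intervals$i1`.
#' @param n_weights Denominator weights, one per length in `intervals$i2`;
#'   the first must be 1.
#' @param intervals An [interval_pair()].
#' @return An `nlrm_params` object.
#' @export
nlrm_params <- function(m_weights, n_weights, intervals) {
  stopifnot(inherits(intervals, "interval_pair"))
  k1 <- diff(intervals$i1) + 1L; k2 <- diff(intervals$i2) + 1L
  assert_that(length(m_weights) == k1 && length(n_weights) == k2,
              "weight lengths must match the intervals")
  assert_that(all(is.finite(m_weights)) && all(is.finite(n_weights)),
              "weights must be finite")
  assert_that(isTRUE(all.equal(n_weights[1], 1)),
              "first denominator weight must be 1 (identifiability)")
  structure(list(m_weights = setNames(m_weights, interval_cols(intervals$i1)),
                 n_weights = setNames(n_weights, interval_cols(intervals$i2)),
                 intervals = intervals),
            class = "nlrm_params")
}

#' @export
print.nlrm_params <- function(x, ...) {
  cat("<nlrm_params>", length(x$m_weights), "numerator +",
      length(x$n_weights), "denominator weights on ")
  print(x$intervals)
  invisible(x)
}

nlrm_ratio <- function(l1, l2, m_w, n_w) {
  num <- drop(l1 %*% m_w)
  den <- drop(l2 %*% n_w)
  list(num = num, den = den, pred = num / den)
}

#' Fit the nonlinear ratio regression model
#'
#' Minimizes the sum of squared residuals of the weighted-ratio model by a
#' Newton-type iteration (\code{\link[stats]{nlm}}) with analytic
#' gradients, starting from all weights equal to 1 (the plain FRAC
#' statistic). A quadratic penalty keeps every sample's weighted
#' denominator away from zero (below `1e-6` of its initial value), and a
#' microscopic Tikhonov term (`1e-8`, centred at the starting weights)
#' anchors the near-flat overall-scale direction of the ratio
#' parameterization, which is otherwise only weakly pinned by the fixed
#' first denominator weight.
#'
#' @param profiles Matrix of length profiles (samples x `L50`-`L220`).
#' @param targets Fetal-fraction targets aligned to the rows.
#' @param intervals An [interval_pair()]; defaults to the clinical optimum
#'   [optimal_intervals()].
#' @param init Optional `nlrm_params` starting point.
#' @param iterlim Maximum iterations (default 2000; the ridge-shaped
#'   objective typically needs ~1000).
#' @param gradtol Gradient tolerance (default 1e-8).
#' @return An `nlrm_params` with attributes `sse`, `converged`,
#'   `iterations`, `code`. Non-convergence raises a condition of class
#'   `ff_nonconvergence_error` carrying the best-so-far parameters in its
#'   `params` field.
#' @export
fit_nlrm <- function(profiles, targets, intervals = optimal_intervals(),
                     init = NULL, iterlim = 2000L, gradtol = 1e-8) {
  profiles <- as.matrix(profiles)
  k1 <- diff(intervals$i1) + 1L; k2 <- diff(intervals$i2) + 1L
  n_free <- k1 + k2 - 1L
  assert_that(nrow(profiles) > n_free,
              "need more samples (", nrow(profiles),
              ") than free parameters (", n_free, ")")
  assert_that(nrow(profiles) == length(targets),
              "targets must align with profiles")
  l1 <- profiles[, interval_cols(intervals$i1), drop = FALSE]
  l2 <- profiles[, interval_cols(intervals$i2), drop = FALSE]
  den0 <- rowSums(l2)
  tau <- 1e-6 * den0
  kappa <- 1e6
  ridge <- 1e-8
  split_theta <- function(theta)
    list(m = theta[seq_len(k1)], n = c(1, theta[k1 + seq_len(k2 - 1L)]))
  objective <- function(theta) {
    w <- split_theta(theta)
    r <- nlrm_ratio(l1, l2, w$m, w$n)
    resid <- targets - r$pred
    short <- pmax(0, tau - r$den)
    val <- sum(resid^2) + kappa * sum(short^2) +
      ridge * sum((theta - theta0)^2)
    g_pred_m <- -2 * crossprod(l1, resid / r$den)            # k1
    g_pred_n <- 2 * crossprod(l2, resid * r$num / r$den^2)   # k2
    g_pen_n <- -2 * kappa * crossprod(l2, short)             # k2
    grad <- c(g_pred_m, (g_pred_n + g_pen_n)[-1]) +
      2 * ridge * (theta - theta0)
    attr(val, "gradient") <- as.numeric(grad)
    val
  }
  theta0 <- if (is.null(init)) rep(1, n_free)
            else unname(c(init$m_weights, init$n_weights[-1]))
  res <- suppressWarnings(
    nlm(objective, theta0, gradtol = gradtol, iterlim = iterlim,
        check.analyticals = FALSE))
  w <- split_theta(res$estimate)
  params <- nlrm_params(w$m, w$n, intervals)
  attr(params, "sse") <- sum((targets - nlrm_ratio(l1, l2, w$m,
                                                   w$n)$pred)^2)
  attr(params, "converged") <- res$code %in% 1:3
  attr(params, "iterations") <- res$iterations
  attr(params, "code") <- res$code
  if (!res$code %in% 1:3) {
    cond <- structure(
      class = c("ff_nonconvergence_error", "fetalfrac_error", "error",
                "condition"),
      list(message = paste0("nonlinear ratio fit did not converge (nlm code ",
                            res$code, " after ", res$iterations,
                            " iterations)"),
           call = sys.call(-1), params = params))
    stop(cond)
  }
  params
}

#' Predict fetal fraction with fitted ratio weights
#' @param profile A length profile or matrix of profiles.
#' @param params An `nlrm_params` object.
#' @return FF estimate(s).
#' @export
predict_nlrm <- function(profile, params) {
  stopifnot(inherits(params, "nlrm_params"))
  m <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1,
        dimnames = list(NULL, names(profile)))
  r <- nlrm_ratio(m[, interval_cols(params$intervals$i1), drop = FALSE],
                  m[, interval_cols(params$intervals$i2), drop = FALSE],
                  params$m_weights, params$n_weights)
  if (any(r$den == 0))
    stop_ff("zero weighted denominator", class = "ff_validation_error")
  r$pred
}
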