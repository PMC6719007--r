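`%||%` <- function(x, y) if (is.null(x)) y else x

stop_ff <- function(..., class) {
  stop(structure(class = c(class, "fetalfrac_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_ff(..., class = "ff_validation_error")
  invisible(TRUE)
}

is_fraction <- function(x) is.numeric(x) && all(is.na(x) | (x >= 0 & x <= 1))

# Population (divide-by-N) standard deviation per column.
col_sd_pop <- function(x) {
  n <- nrow(x)
  mu <- colMeans(x)
  sqrt(colMeans(x^2) - mu^2) * sqrt(n / max(n, 1))
}

# Minimum-norm least squares via SVD; X already includes any intercept column.
lstsq_minnorm <- function(x, y) {
  sv <- svd(x)
  tol <- max(dim(x)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  coef <- sv$v[, pos, drop = FALSE] %*%
    ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos])
  list(coef = drop(coef), rank = sum(pos))
}

# Derive a stream of per-repeat seeds from one master seed without
# disturbing the caller's RNG state.
spawn_seeds <- function(seed, n) {
  with_preserved_rng({
    set.seed(seed)
    sample.int(.Machine$integer.max - 1L, n)
  })
}

with_preserved_rng <- function(expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}
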