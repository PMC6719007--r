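# Shared fixtures, all generated in code.

LEN_NAMES <- paste0("L", 50:220)

# Random strictly positive profiles (rows sum to 1).
rand_profiles <- function(n, seed = 1, lo = 0.1, hi = 1) {
  set.seed(seed)
  m <- matrix(runif(n * 171, lo, hi), n, 171,
              dimnames = list(NULL, LEN_NAMES))
  m / rowSums(m)
}

# Naive quadruple-loop interval-pair search, mirroring the fast path's
# enumeration and tie-breaking exactly.
brute_search_oracle <- function(profiles, targets, bounds,
                                min_width = 1L, stride = 1L) {
  grid <- seq.int(bounds[1], bounds[2], by = stride)
  iv <- list()
  for (a in grid) for (b in grid)
    if (b >= a && (b - a + 1L) >= min_width)
      iv[[length(iv) + 1L]] <- as.integer(c(a, b))
  cols <- function(k) paste0("L", seq.int(iv[[k]][1], iv[[k]][2]))
  sums <- sapply(seq_along(iv),
                 function(k) rowSums(profiles[, cols(k), drop = FALSE]))
  best <- NULL; bestcor <- -Inf
  width <- vapply(iv, function(v) v[2] - v[1] + 1L, integer(1))
  for (j in seq_along(iv)) {
    if (any(sums[, j] <= 0)) next
    for (i in seq_along(iv)) {
      if (i == j) next
      r <- sums[, i] / sums[, j]
      if (stats::var(r) <= 1e-300) next
      cc <- stats::cor(r, targets)
      if (!is.finite(cc)) next
      take <- FALSE
      if (cc > bestcor) take <- TRUE
      else if (cc == bestcor && !is.null(best)) {
        wn <- width[i] + width[j]; wo <- width[best[1]] + width[best[2]]
        if (wn < wo) take <- TRUE
        else if (wn == wo &&
                 (iv[[i]][1] < iv[[best[1]]][1] ||
                  (iv[[i]][1] == iv[[best[1]]][1] &&
                   iv[[j]][1] < iv[[best[2]]][1]))) take <- TRUE
      }
      if (take) { bestcor <- cc; best <- c(i, j) }
    }
  }
  if (is.null(best)) return(NULL)
  list(i1 = iv[[best[1]]], i2 = iv[[best[2]]], cor = bestcor)
}

# Synthetic GC bin table: counts follow `expected(gc)` times a bias, plus
# optional noise; one pseudo-chromosome per `chroms` entry.
make_gc_bins <- function(n_per_chrom = 120,
                         chroms = c("chr1", "chr2", "chrX", "chrY"),
                         expected = function(gc) rep(100, length(gc)),
                         bias = function(gc) rep(1, length(gc)),
                         seed = 1) {
  set.seed(seed)
  out <- do.call(rbind, lapply(chroms, function(ch) {
    gc <- runif(n_per_chrom, 0.3, 0.6)
    data.frame(chrom = ch,
               start = (seq_len(n_per_chrom) - 1L) * 20000L,
               end = seq_len(n_per_chrom) * 20000L,
               gc = gc, gc_valid = TRUE,
               true_count = expected(gc))
  }))
  out$raw_count <- out$true_count * bias(out$gc)
  out
}

# Tiny simulated cohort shared by harness tests (analytic profiles: fast).
quick_cohort <- function(n = 120, seed = 3, ...) {
  simulate_dataset(sim_config(n_samples = n, fragments_per_sample = Inf,
                              seed = seed, ...))
}
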