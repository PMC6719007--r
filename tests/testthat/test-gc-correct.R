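test_that("per-bin GC is computed from the reference with N masking", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 test", "GGCCATATNNNNATGC"), fa)
  bins <- data.frame(chrom = "chr1", start = c(0, 4, 8),
                     end = c(4, 8, 16))
  out <- compute_bin_gc(fa, bins)
  expect_equal(out$gc, c(1, 0, 0.5))            # GGCC, ATAT, NNNNATGC
  expect_true(all(out$gc_valid))                # 50% N is still usable
  bins2 <- data.frame(chrom = "chr1", start = 8, end = 15)  # 5/7 N
  expect_false(compute_bin_gc(fa, bins2)$gc_valid)
  expect_error(compute_bin_gc(fa, data.frame(chrom = "chr9", start = 0,
                                             end = 4)), "chr9")
})

test_that("flat counts give a flat fitted curve and unit weights", {
  bins <- make_gc_bins(expected = function(gc) rep(10, length(gc)))
  model <- fit_gc_model(bins)
  expect_equal(model$m, 10)
  expect_equal(predict(model, c(0.35, 0.45, 0.55)), rep(10, 3),
               tolerance = 1e-6)
  res <- apply_gc_weights(bins, model)
  expect_equal(res$bins$corrected_count, bins$raw_count, tolerance = 1e-6)
})

test_that("noiseless linear count-GC trend is recovered within 2%", {
  bins <- make_gc_bins(expected = function(gc) 100 * gc)
  model <- fit_gc_model(bins)
  interior <- seq(0.35, 0.55, by = 0.05)
  expect_equal(predict(model, interior), 100 * interior,
               tolerance = 0.02)
})

test_that("invalid-GC bins are excluded from fitting and totals", {
  bins <- make_gc_bins(expected = function(gc) rep(50, length(gc)))
  bins$gc_valid[1:10] <- FALSE
  bins$raw_count[1:10] <- 1e6           # would wreck the fit if used
  model <- fit_gc_model(bins)
  expect_equal(model$m, 50, tolerance = 1e-9)
  res <- apply_gc_weights(bins, model)
  # invalid bins pass through unweighted but are excluded from totals
  expect_equal(res$bins$corrected_count[1:10], bins$raw_count[1:10])
  expect_equal(unname(res$chrom_totals["chr1"]),
               sum(res$bins$corrected_count[bins$chrom == "chr1" &
                                              bins$gc_valid]))
})

test_that("a known smooth GC bias is inverted and chrY passes through raw", {
  # correction normalizes to the global mean count, so the absolute scale
  # is recoverable only for a bias that is mean-one over the cohort; a
  # non-mean-one bias must still be equalized up to one common factor
  raw_bias <- function(gc) 1 + 1 / (1 + exp(-40 * (gc - 0.5)))
  set.seed(5); gc_pool <- runif(4 * 120, 0.3, 0.6)
  scale1 <- mean(raw_bias(gc_pool[1:240]))   # autosomal bins set the mean
  bins <- make_gc_bins(expected = function(gc) rep(80, length(gc)),
                       bias = function(gc) raw_bias(gc) / scale1, seed = 5)
  model <- fit_gc_model(bins)
  res <- apply_gc_weights(bins, model)
  for (ch in c("chr1", "chr2", "chrX")) {
    sel <- bins$chrom == ch
    expect_equal(unname(res$chrom_totals[ch]) / sum(bins$true_count[sel]),
                 1, tolerance = 0.01)
  }
  expect_equal(unname(res$chrom_totals["chrY"]),
               sum(bins$raw_count[bins$chrom == "chrY"]))

  # non-normalized bias: per-chromosome ratios agree to a common factor
  bins2 <- make_gc_bins(expected = function(gc) rep(80, length(gc)),
                        bias = raw_bias, seed = 6)
  res2 <- apply_gc_weights(bins2, fit_gc_model(bins2))
  ratios <- sapply(c("chr1", "chr2", "chrX"), function(ch)
    unname(res2$chrom_totals[ch]) /
      sum(bins2$true_count[bins2$chrom == ch]))
  expect_lt(diff(range(ratios)) / mean(ratios), 0.01)
})

test_that("mean corrected count equals m and correction is near idempotent", {
  bias <- function(gc) 0.7 + gc
  bins <- make_gc_bins(expected = function(gc) rep(60, length(gc)),
                       bias = bias)
  model <- fit_gc_model(bins)
  res <- apply_gc_weights(bins, model)
  usable <- model$usable
  expect_equal(mean(res$bins$corrected_count[usable]), model$m,
               tolerance = 0.005 * model$m)
  # refit on corrected counts: weights should be ~1
  bins2 <- res$bins
  bins2$raw_count <- bins2$corrected_count
  model2 <- fit_gc_model(bins2)
  w <- model2$m / predict(model2, bins2$gc[usable])
  expect_true(all(abs(w - 1) < 0.01))
})
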