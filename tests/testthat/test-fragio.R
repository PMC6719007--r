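test_that("read_fragments counts proper pairs once with MAPQ filtering", {
  sam <- tempfile(fileext = ".sam")
  write_sam_fixture(sam, lengths = c(166L, 166L, 143L),
                    chroms = c("chr1", "chr1", "chrY"), mapq = 60L)
  fs <- read_fragments(sam, min_mapq = 40)
  expect_equal(fs$length_histogram, c(`143` = 1L, `166` = 2L))
  expect_equal(fs$per_chrom_fragments[c("chr1", "chrY")],
               c(chr1 = 2L, chrY = 1L))
  expect_equal(fs$total_fragments, 3L)
  expect_equal(chry_fraction(fs), 1 / 3)

  empty <- read_fragments(sam, min_mapq = 61)
  expect_equal(empty$total_fragments, 0L)
})

test_that("read_fragments matches the fixture generator's emitted tally", {
  set.seed(20)
  lens <- sample(60:200, 1000, replace = TRUE)
  chroms <- sample(c("chr1", "chr2", "chrY"), 1000, replace = TRUE,
                   prob = c(0.6, 0.39, 0.01))
  sam <- tempfile(fileext = ".sam")
  tally <- write_sam_fixture(sam, lens, chroms)
  fs <- read_fragments(sam)
  expect_equal(fs$length_histogram[names(tally)], tally)
  expect_equal(fs$total_fragments, 1000L)

  # record order must not matter
  lines <- readLines(sam)
  hdr <- grepl("^@", lines)
  set.seed(21)
  shuf <- c(lines[hdr], sample(lines[!hdr]))
  sam2 <- tempfile(fileext = ".sam")
  writeLines(shuf, sam2)
  fs2 <- read_fragments(sam2)
  expect_equal(fs2$length_histogram, fs$length_histogram)
})

test_that("read_fragments errors on unreadable or pair-free input", {
  expect_error(read_fragments(tempfile()), "not found")
  sam <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted", "@SQ\tSN:chr1\tLN:1000"), sam)
  expect_error(read_fragments(sam), "properly paired")
})

test_that("length profiles normalize over the in-range window only", {
  p <- build_length_profile(c(`166` = 3, `143` = 1))
  expect_equal(unname(p["L166"]), 0.75)
  expect_equal(unname(p["L143"]), 0.25)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  p2 <- build_length_profile(c(`40` = 5, `166` = 5))
  expect_equal(unname(p2["L166"]), 1)

  uni <- setNames(rep(1, 171), as.character(50:220))
  p3 <- build_length_profile(uni)
  expect_equal(unname(as.numeric(p3)), rep(1 / 171, 171))

  expect_error(build_length_profile(c(`40` = 5)), "undefined")
})

test_that("profile tables load, validate, and round-trip", {
  ds <- quick_cohort(n = 3)
  counts <- round(ds$profiles * 5e5)
  df <- data.frame(sample_id = ds$samples$sample_id, counts,
                   check.names = FALSE)
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  loaded <- load_profile_table(path)
  expect_equal(n_samples(loaded), 3)
  expect_equal(unname(rowSums(loaded$profiles)), rep(1, 3))

  # proportions summing to 0.5 are rejected with the sample named
  bad <- df
  bad[1, -1] <- as.numeric(ds$profiles[1, ]) * 0.5
  write.table(bad, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_profile_table(path), bad$sample_id[1])

  # write -> load round-trip at 1e-12
  rt <- tempfile(fileext = ".tsv")
  write_profile_table(ds, rt)
  back <- load_profile_table(rt)
  expect_equal(back$profiles, ds$profiles, tolerance = 1e-12)
  expect_equal(back$samples$reference_ff, ds$samples$reference_ff,
               tolerance = 1e-12)

  # missing length columns are reported as a schema error
  write.table(df[, 1:100], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  expect_error(load_profile_table(path), "length column")
})

test_that("standardizer uses the population convention and training set only", {
  x <- matrix(c(0.2, 0.4), 2, 1, dimnames = list(NULL, "L50"))
  std <- fit_standardizer(x)
  expect_equal(unname(apply_standardizer(std, x)[, 1]), c(-1, 1))

  xc <- cbind(x, L51 = c(0.3, 0.3))       # constant feature
  std2 <- fit_standardizer(xc)
  expect_equal(unname(apply_standardizer(std2, xc)[, 2]), c(0, 0))

  # held-out profile equal to the training mean maps to zero
  held <- matrix(colMeans(xc), 1)
  expect_equal(unname(apply_standardizer(std2, held)[1, ]), c(0, 0))

  expect_error(fit_standardizer(x[1, , drop = FALSE]), "at least 2")
})

test_that("standardizer gives exact zero mean unit variance on its fit set", {
  x <- rand_profiles(40, seed = 9)
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  expect_true(all(abs(colMeans(z)) < 1e-10))
  v <- colMeans(z^2) - colMeans(z)^2
  expect_true(all(abs(v[!std$degenerate] - 1) < 1e-10))
})
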