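#' Read paired-end fragments from a BAM/SAM file
#'
#' Extracts sequenced cfDNA fragments from a coordinate-level alignment file
#' and tallies them by length and by chromosome. A fragment is counted once,
#' from its first-in-pair record, and must be properly paired, primary,
#' non-duplicate, with both mates mapped and a mapping quality of at least
#' `min_mapq`. The fragment length is the absolute template length, i.e. the
#' span between the outermost mapped bases of the pair (rightmost minus
#' leftmost plus one in 1-based coordinates).
#'
#' The returned histogram keeps every observed length; restriction to the
#' 50-220 bp window happens later in [build_length_profile()].
#'
#' @param path Path to a BAM or SAM file of paired-end alignments. SAM input
#'   is converted on the fly via [Rsamtools::asBam()].
#' @param min_mapq Minimum mapping quality of the first-in-pair record
#'   (default 40).
#' @param length_bounds Inclusive length window recorded on the object and
#'   used as the downstream default (default `c(50, 220)`).
#' @param sample_id Sample identifier; defaults to the file name.
#' @return A `fragment_set`: list with `sample_id`, `length_histogram`
#'   (named counts by fragment length), `per_chrom_fragments`,
#'   `total_fragments`.
#' @export
read_fragments <- function(path, min_mapq = 40L,
                           length_bounds = FF_LENGTH_RANGE,
                           sample_id = NULL) {
  assert_that(is.character(path) && length(path) == 1 && file.exists(path),
              "alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE,
                                             indexDestination = FALSE))
  }
  flags <- Rsamtools::scanBamFlag(
    isPaired = TRUE, isProperPair = TRUE, isFirstMateRead = TRUE,
    isUnmappedQuery = FALSE, hasUnmappedMate = FALSE,
    isSecondaryAlignment = FALSE, isDuplicate = FALSE,
    isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(flag = flags,
                                   what = c("rname", "mapq", "isize"))
  rec <- tryCatch(Rsamtools::scanBam(bam, param = param)[[1]],
                  error = function(e)
                    stop_ff("failed to read alignments from '", path, "': ",
                            conditionMessage(e), class = "ff_io_error"))
  if (length(rec$rname) == 0)
    stop_ff("no properly paired reads in '", path, "'",
            class = "ff_io_error")
  keep <- !is.na(rec$mapq) & rec$mapq >= min_mapq &
    !is.na(rec$isize) & rec$isize != 0L
  lens <- abs(rec$isize[keep])
  chroms <- as.character(rec$rname[keep])
  new_fragment_set(
    sample_id = sample_id %||% basename(path),
    length_histogram = tabulate_named(lens),
    per_chrom_fragments = if (length(chroms)) table_to_vector(table(chroms))
                          else integer(0),
    length_bounds = as.integer(length_bounds))
}

tabulate_named <- function(lens) {
  if (!length(lens)) return(integer(0))
  table_to_vector(table(lens))
}

table_to_vector <- function(tab) {
  v <- as.integer(tab)
  names(v) <- names(tab)
  v
}

new_fragment_set <- function(sample_id, length_histogram,
                             per_chrom_fragments,
                             length_bounds = FF_LENGTH_RANGE) {
  total <- sum(per_chrom_fragments)
  assert_that(sum(length_histogram) == total,
              "fragment histogram and per-chromosome counts disagree")
  assert_that(all(length_histogram >= 0) && all(per_chrom_fragments >= 0),
              "fragment counts must be non-negative")
  structure(list(sample_id = sample_id,
                 length_histogram = length_histogram,
                 per_chrom_fragments = per_chrom_fragments,
                 total_fragments = as.integer(total),
                 length_bounds = as.integer(length_bounds)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("<fragment_set>", x$sample_id, "-", x$total_fragments, "fragments on",
      length(x$per_chrom_fragments), "chromosomes\n")
  invisible(x)
}

#' Fraction of fragments on chromosome Y
#'
#' Both "chrY" and "Y" naming conventions are accepted. The denominator is
#' all retained fragments by default, or autosomal fragments only.
#'
#' @param fragments A `fragment_set`.
#' @param denominator `"all"` (default) or `"autosomal"`.
#' @return Fraction in \[0, 1\].
#' @export
chry_fraction <- function(fragments, denominator = c("all", "autosomal")) {
  denominator <- match.arg(denominator)
  pc <- fragments$per_chrom_fragments
  ny <- sum(pc[names(pc) %in% c("chrY", "Y")])
  den <- if (denominator == "all") sum(pc)
         else sum(pc[is_autosome(names(pc))])
  assert_that(den > 0, "no fragments in %chrY denominator")
  ny / den
}

is_autosome <- function(chrom) grepl("^(chr)?[0-9]+$", chrom)

#' Build a fragment-length profile
#'
#' Converts a fragment-length histogram into the vector of per-length
#' proportions over the inclusive window `length_range` (171 values for the
#' default 50-220 bp). Out-of-range lengths are excluded from both numerator
#' and denominator, so the profile always sums to one.
#'
#' @param fragments A `fragment_set`, or a named numeric vector mapping
#'   length (bp) to count.
#' @param length_range Inclusive length window (default `c(50, 220)`).
#' @return A `length_profile`: named numeric vector `L<range>` of
#'   proportions, with the sample id as attribute.
#' @export
build_length_profile <- function(fragments, length_range = FF_LENGTH_RANGE) {
  if (inherits(fragments, "fragment_set")) {
    hist <- fragments$length_histogram
    id <- fragments$sample_id
  } else {
    hist <- fragments
    id <- attr(fragments, "sample_id") %||% NA_character_
  }
  assert_that(!is.null(names(hist)), "histogram must be named by length")
  lens <- seq.int(length_range[1], length_range[2])
  counts <- setNames(numeric(length(lens)), as.character(lens))
  inr <- names(hist)[as.integer(names(hist)) >= length_range[1] &
                     as.integer(names(hist)) <= length_range[2]]
  counts[inr] <- hist[inr]
  total <- sum(counts)
  if (total <= 0)
    stop_ff("no fragments within ", length_range[1], "-", length_range[2],
            " bp; profile undefined", class = "ff_validation_error")
  p <- counts / total
  names(p) <- paste0("L", lens)
  structure(p, sample_id = id, class = c("length_profile", "numeric"))
}

#' @export
print.length_profile <- function(x, ...) {
  cat("<length_profile>", attr(x, "sample_id"), "-", length(x),
      "lengths, modal", sub("^L", "", names(x)[which.max(x)]), "bp\n")
  invisible(x)
}

# ---- dataset container -----------------------------------------------------

SAMPLE_ATTR_COLS <- c("chry_fraction", "ga", "bmi", "lc", "seqff_value",
                      "reference_ff", "true_ff")

#' Construct an NIPT sample dataset
#'
#' Couples an N x 171 matrix of fragment-length proportions with per-sample
#' attributes (chrY read fraction, gestational age, BMI, library
#' concentration, external SeqFF value, reference and/or true fetal
#' fraction; all optional).
#'
#' @param profiles Numeric matrix, one row per sample, columns `L50`-`L220`
#'   summing to one per row.
#' @param samples Data frame with column `sample_id` (unique, matching
#'   `rownames(profiles)`) and any of `chry_fraction`, `ga`, `bmi`, `lc`,
#'   `seqff_value`, `reference_ff`, `true_ff`.
#' @return An object of class `nipt_dataset`.
#' @export
nipt_dataset <- function(profiles, samples) {
  profiles <- as.matrix(profiles)
  assert_that(!anyDuplicated(samples$sample_id), "sample_ids must be unique")
  assert_that(nrow(profiles) == nrow(samples),
              "profiles and samples disagree on N")
  bad <- which(abs(rowSums(profiles) - 1) > 1e-9)
  assert_that(length(bad) == 0, "profile rows do not sum to 1: sample(s) ",
              paste(samples$sample_id[head(bad, 3)], collapse = ", "))
  assert_that(all(profiles >= 0), "profile proportions must be non-negative")
  rownames(profiles) <- samples$sample_id
  for (col in SAMPLE_ATTR_COLS) {
    if (!col %in% names(samples)) samples[[col]] <- NA_real_
    if (col %in% c("chry_fraction", "reference_ff", "true_ff", "seqff_value")) {
      v <- samples[[col]]
      # reference/y-based values may legitimately stray outside [0,1] for
      # noisy inputs; only hard impossibilities are rejected
      if (col == "chry_fraction")
        assert_that(is_fraction(v[!is.na(v)]), col, " must lie in [0,1]")
    }
  }
  assert_that(all(is.na(samples$bmi) | samples$bmi > 0),
              "bmi must be positive when present")
  structure(list(profiles = profiles,
                 samples = as.data.frame(samples,
                                         stringsAsFactors = FALSE)),
            class = "nipt_dataset")
}

#' @export
print.nipt_dataset <- function(x, ...) {
  present <- SAMPLE_ATTR_COLS[vapply(SAMPLE_ATTR_COLS, function(cn)
    any(!is.na(x$samples[[cn]])), logical(1))]
  cat("<nipt_dataset> ", nrow(x$profiles), " samples x ",
      ncol(x$profiles), " lengths; attributes: ",
      if (length(present)) paste(present, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Number of samples in a dataset
#' @param ds An `nipt_dataset`.
#' @return Integer sample count.
#' @export
n_samples <- function(ds) nrow(ds$profiles)

#' Subset a dataset by sample index
#' @param ds An `nipt_dataset`.
#' @param idx Integer indices (duplicates allowed, e.g. for sample
#'   weighting by replication).
#' @return An `nipt_dataset` with the selected rows, in the given order.
#' @export
ds_subset <- function(ds, idx) {
  samples <- ds$samples[idx, , drop = FALSE]
  if (anyDuplicated(idx))
    samples$sample_id <- make.unique(as.character(samples$sample_id))
  rownames(samples) <- NULL
  nipt_dataset(ds$profiles[idx, , drop = FALSE], samples)
}

# ---- profile tables --------------------------------------------------------

#' Read a per-sample length-profile table
#'
#' Tab-separated table with columns `sample_id`, `L50` ... `L220` (counts or
#' proportions; bare numeric column names `50`...`220` are also accepted)
#' and optionally `chry_fraction`, `ga`, `bmi`, `lc`, `seqff_value`,
#' `reference_ff`, `true_ff`. Count rows are normalized to proportions;
#' proportion rows must sum to 1 within 1e-6.
#'
#' @param path TSV file path.
#' @return An [nipt_dataset()].
#' @export
load_profile_table <- function(path) {
  assert_that(file.exists(path), "profile table not found: ", path)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  assert_that("sample_id" %in% names(df), "missing column: sample_id")
  want <- ff_length_names()
  have <- names(df)
  bare <- as.character(seq.int(FF_LENGTH_RANGE[1], FF_LENGTH_RANGE[2]))
  if (all(bare %in% have)) names(df)[match(bare, names(df))] <- want
  missing <- setdiff(want, names(df))
  if (length(missing))
    stop_ff("profile table lacks length column(s): ",
            paste(head(missing, 5), collapse = ", "),
            if (length(missing) > 5) ", ...", class = "ff_schema_error")
  m <- as.matrix(df[, want])
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg))
    stop_ff("negative length values for sample(s): ",
            paste(df$sample_id[head(neg, 3)], collapse = ", "),
            class = "ff_validation_error")
  rs <- rowSums(m)
  for (i in seq_len(nrow(m))) {
    if (abs(rs[i] - 1) <= 1e-6) next           # proportions
    if (rs[i] > 1 + 1e-6) m[i, ] <- m[i, ] / rs[i]  # counts -> proportions
    else stop_ff("profile of sample '", df$sample_id[i], "' sums to ",
                 format(rs[i]), ", neither counts nor proportions",
                 class = "ff_validation_error")
  }
  samples <- df[, c("sample_id", intersect(SAMPLE_ATTR_COLS, names(df))),
                drop = FALSE]
  nipt_dataset(m, samples)
}

#' Write a per-sample length-profile table
#'
#' Inverse of [load_profile_table()]; values round-trip losslessly.
#'
#' @param ds An `nipt_dataset`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_profile_table <- function(ds, path) {
  keep <- SAMPLE_ATTR_COLS[vapply(SAMPLE_ATTR_COLS, function(cn)
    any(!is.na(ds$samples[[cn]])), logical(1))]
  df <- cbind(ds$samples["sample_id"],
              as.data.frame(ds$profiles, check.names = FALSE),
              ds$samples[keep])
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- standardization -------------------------------------------------------

#' Fit a feature standardizer on training profiles
#'
#' Centres and scales each length feature to zero mean and unit variance
#' (population, divide-by-N convention), using the training set only.
#' Zero-variance features get scale 1 so they map to 0 instead of dividing
#' by zero.
#'
#' @param x Numeric matrix of training profiles (samples x features).
#' @return A `ff_standardizer` with `$mean` and `$scale`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  assert_that(nrow(x) >= 2, "need at least 2 profiles to standardize")
  s <- col_sd_pop(x)
  degenerate <- s <= 0 | !is.finite(s)
  s[degenerate] <- 1
  structure(list(mean = colMeans(x), scale = s, degenerate = degenerate),
            class = "ff_standardizer")
}

#' Apply a fitted standardizer
#' @param std A `ff_standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same features as the training set.
#' @return Matrix of standardized features.
#' @export
apply_standardizer <- function(std, x) {
  x <- as.matrix(x)
  assert_that(ncol(x) == length(std$mean),
              "feature count differs from the fitted standardizer")
  sweep(sweep(x, 2, std$mean, "-"), 2, std$scale, "/")
}
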