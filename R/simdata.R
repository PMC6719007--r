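#' Configuration for the synthetic NIPT sample simulator
#'
#' The simulator emulates the statistical structure that fetal-fraction
#' estimators rely on: per-sample fragment-length profiles drawn from a
#' mixture of a shorter fetal and a longer maternal length distribution, a
#' chrY read fraction linear in the true FF, a SeqFF-like external
#' predictor with a configurable correlation to FF, and weakly correlated
#' sample attributes (gestational age, BMI, library concentration).
#'
#' Two knobs control how informative the length profile is about FF.
#' Library preparation involves bead-based size selection whose efficiency
#' varies between libraries, so the short-fragment enrichment seen in a
#' profile reflects the true FF only up to a sample-specific offset: the
#' mixture is built at an *apparent* FF correlated `length_signal_rho`
#' with the true FF (default 0.87, the regime in which length-based
#' estimators top out around r 0.83 against the Y-based reference, as on
#' clinical cohorts). Independently, `maternal_jitter_sd` wobbles the
#' maternal mean length per sample (benign shape variability that a
#' flexible regressor can separate from the FF signal).
#'
#' Defaults: FF prior truncated normal mean 0.10, sd 0.04 on
#' \[0.02, 0.30\]; maternal lengths about 166 +/- 9 bp and fetal about
#' 143 +/- 9 bp (discretized truncated normals on 50-220); chrY baselines
#' 0.0002 (female) and 0.0020 (male); SeqFF surrogate correlation 0.877;
#' attribute correlations 0.1 (GA), -0.33 (BMI), -0.22 (LC) with marginals
#' 14 +/- 2 weeks, 25 +/- 4 kg/m2, 10 +/- 3 units. Per-sample library
#' variability is modelled as a Gaussian jitter of the maternal mean
#' length (`maternal_jitter_sd`); it is the main reason length-based
#' estimators are imperfect even at high depth, mirroring clinical data. An
#' optional 10-bp ripple below 150 bp (nucleosome-related periodicity) is
#' off by default.
#'
#' @param n_samples Number of samples.
#' @param fragments_per_sample Sequencing depth per sample (default 5e5;
#'   use `Inf` for the analytic infinite-depth profile).
#' @param ff_mean,ff_sd,ff_bounds Truncated-normal FF prior.
#' @param maternal_mean,maternal_sd,fetal_mean,fetal_sd Length
#'   distributions (bp).
#' @param maternal_jitter_sd Per-sample sd of the maternal mean length
#'   (bp, default 1).
#' @param length_signal_rho Target correlation between the apparent FF
#'   driving the length mixture and the true FF (default 0.87; 1 = the
#'   profile reflects the true FF exactly).
#' @param ripple_amplitude Amplitude of the optional 10-bp periodicity
#'   below 150 bp in the fetal length distribution (nucleosome-protection
#'   ladder; default 0 = off).
#' @param female_baseline,male_baseline chrY read-fraction baselines.
#' @param chry_noise_sd Additive noise on the chrY fraction
#'   (default 2e-5).
#' @param seqff_rho Target correlation of the SeqFF surrogate with true FF
#'   (default 0.877).
#' @param ga_rho,bmi_rho,lc_rho Target attribute correlations with FF.
#' @param ga_mean,ga_sd,bmi_mean,bmi_sd,lc_mean,lc_sd Attribute marginals.
#' @param seed RNG seed (default 17).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 1000L,
                       fragments_per_sample = 5e5,
                       ff_mean = 0.10, ff_sd = 0.04,
                       ff_bounds = c(0.02, 0.30),
                       maternal_mean = 166, maternal_sd = 9,
                       fetal_mean = 143, fetal_sd = 9,
                       maternal_jitter_sd = 1.0,
                       length_signal_rho = 0.87,
                       ripple_amplitude = 0,
                       female_baseline = 0.0002, male_baseline = 0.0020,
                       chry_noise_sd = 2e-5,
                       seqff_rho = 0.877,
                       ga_rho = 0.1, bmi_rho = -0.33, lc_rho = -0.22,
                       ga_mean = 14, ga_sd = 2,
                       bmi_mean = 25, bmi_sd = 4,
                       lc_mean = 10, lc_sd = 3,
                       seed = 17L) {
  cfg <- as.list(environment())
  assert_that(fetal_mean < maternal_mean,
              "fetal fragments must be shorter than maternal on average")
  for (rho in c(seqff_rho, length_signal_rho, ga_rho, bmi_rho, lc_rho))
    assert_that(abs(rho) < 1 || identical(rho, 1),
                "target correlations must lie in (-1,1): got ", rho)
  assert_that(ff_bounds[1] < ff_bounds[2] && ff_bounds[1] >= 0 &&
                ff_bounds[2] <= 1, "invalid FF prior bounds")
  structure(cfg, class = "sim_config")
}

# Discretized, truncated normal over the integer length grid.
discretized_normal <- function(mean, sd, range = FF_LENGTH_RANGE) {
  lens <- seq.int(range[1], range[2])
  p <- dnorm(lens, mean, sd)
  setNames(p / sum(p), paste0("L", lens))
}

#' Fragment-length mixture at a given fetal fraction
#'
#' Pointwise mixture `ff * fetal + (1 - ff) * maternal`, renormalized over
#' the 50-220 bp grid. With the fetal mean below the maternal mean, the
#' mixture's mean length decreases strictly in `ff`.
#'
#' @param ff Fetal fraction in \[0, 1\].
#' @param maternal,fetal Probability vectors over the length grid (e.g.
#'   from the simulator's discretized normals), or `list(mean=, sd=)`
#'   specs.
#' @return Probability vector over lengths 50-220.
#' @export
length_mixture <- function(ff, maternal, fetal) {
  assert_that(ff >= 0 && ff <= 1, "ff must lie in [0,1]")
  if (is.list(maternal))
    maternal <- discretized_normal(maternal$mean, maternal$sd)
  if (is.list(fetal)) fetal <- discretized_normal(fetal$mean, fetal$sd)
  p <- ff * fetal + (1 - ff) * maternal
  p / sum(p)
}

#' Noise level achieving a target correlation
#'
#' For `x = signal + noise` with independent Gaussian noise, returns the
#' noise sd such that `cor(x, signal) = rho`:
#' `sd_signal * sqrt(1 / rho^2 - 1)`.
#'
#' @param sd_signal Standard deviation of the signal.
#' @param rho Target correlation in (0, 1\].
#' @return Noise standard deviation.
#' @export
noise_sd_for_target_correlation <- function(sd_signal, rho) {
  assert_that(sd_signal > 0, "sd_signal must be positive")
  if (rho <= 0 || rho > 1)
    stop_ff("target correlation must lie in (0,1], got ", rho,
            class = "ff_validation_error")
  sd_signal * sqrt(1 / rho^2 - 1)
}

rnorm_trunc <- function(n, mean, sd, bounds) {
  lo <- pnorm(bounds[1], mean, sd)
  hi <- pnorm(bounds[2], mean, sd)
  qnorm(lo + runif(n) * (hi - lo), mean, sd)
}

apply_ripple <- function(p, amplitude) {
  if (amplitude == 0) return(p)
  lens <- as.integer(sub("^L", "", names(p)))
  mod <- ifelse(lens < 150, 1 + amplitude * sin(2 * pi * lens / 10), 1)
  p <- p * mod
  p / sum(p)
}

#' Simulate a synthetic NIPT dataset
#'
#' Draws per-sample true fetal fractions from the prior, samples fragment
#' lengths multinomially from the fetal/maternal mixture (or uses the
#' analytic mixture when depth is infinite), sets the chrY fraction from
#' the linear chrY model plus noise, generates the SeqFF surrogate and the
#' sample attributes at their target correlations, and computes the
#' Y-based `reference_ff` from the noisy chrY fraction using the true
#' baselines. All randomness derives from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return An [nipt_dataset()] with `true_ff` populated.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples
  set.seed(config$seed)
  ff <- rnorm_trunc(n, config$ff_mean, config$ff_sd, config$ff_bounds)
  ff_apparent <- if (config$length_signal_rho < 1)
    pmin(pmax(ff + rnorm(n, 0, noise_sd_for_target_correlation(
      sd(ff), config$length_signal_rho)), 0), 1)
    else ff
  jitter <- rnorm(n, 0, config$maternal_jitter_sd)
  # the 10-bp periodicity below ~150 bp is characteristic of the fetal
  # (nucleosome-protected) fragments; maternal lengths stay smooth
  fetal <- apply_ripple(discretized_normal(config$fetal_mean,
                                           config$fetal_sd),
                        config$ripple_amplitude)
  lens <- seq.int(FF_LENGTH_RANGE[1], FF_LENGTH_RANGE[2])
  profiles <- matrix(0, n, length(lens),
                     dimnames = list(NULL, paste0("L", lens)))
  for (i in seq_len(n)) {
    maternal <- discretized_normal(config$maternal_mean + jitter[i],
                                   config$maternal_sd)
    p <- length_mixture(ff_apparent[i], maternal, fetal)
    profiles[i, ] <- if (is.infinite(config$fragments_per_sample)) p
      else {
        cnt <- rmultinom(1, config$fragments_per_sample, p)
        cnt / sum(cnt)
      }
  }
  params <- ybase_params(config$female_baseline, config$male_baseline)
  chry <- pmax(0, config$female_baseline +
                 ff * (config$male_baseline - config$female_baseline) +
                 if (config$chry_noise_sd > 0)
                   rnorm(n, 0, config$chry_noise_sd) else 0)
  sd_ff <- sd(ff)
  seqff <- ff + if (config$seqff_rho < 1)
    rnorm(n, 0, noise_sd_for_target_correlation(sd_ff, config$seqff_rho))
    else 0
  z <- (ff - mean(ff)) / sd_ff
  gen_attr <- function(mu, sdv, rho)
    mu + rho * sdv * z + rnorm(n, 0, sdv * sqrt(1 - rho^2))
  samples <- data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    chry_fraction = chry,
    ga = gen_attr(config$ga_mean, config$ga_sd, config$ga_rho),
    bmi = gen_attr(config$bmi_mean, config$bmi_sd, config$bmi_rho),
    lc = gen_attr(config$lc_mean, config$lc_sd, config$lc_rho),
    seqff_value = seqff,
    reference_ff = as.numeric(estimate_y_based(chry, params)),
    true_ff = ff,
    stringsAsFactors = FALSE)
  ds <- nipt_dataset(profiles, samples)
  attr(ds, "config") <- config
  ds
}

#' Write a simulated dataset as plain-text fixtures
#'
#' Writes `profiles.tsv` (full profile-table schema, round-trips through
#' [load_profile_table()]), `attributes.tsv`, `truth.tsv` and a
#' `config.yaml` echo into `dir`.
#'
#' @param ds An [nipt_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_profile_table(ds, file.path(dir, "profiles.tsv"))
  attrs <- ds$samples[, c("sample_id", "chry_fraction", "ga", "bmi", "lc",
                          "seqff_value", "reference_ff")]
  write.table(format(attrs, digits = 17, trim = TRUE, scientific = FALSE),
              file.path(dir, "attributes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(format(ds$samples[, c("sample_id", "true_ff")], digits = 17,
                     trim = TRUE, scientific = FALSE),
              file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  cfg <- attr(ds, "config")
  if (!is.null(cfg))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Write a small paired-end SAM fixture with known fragment lengths
#'
#' Emits one properly paired read pair per requested fragment (flags
#' 99/147, MAPQ as given, placeholder sequence), so that alignment-reading
#' code can be validated against the exact emitted length tally.
#'
#' @param path Output SAM path.
#' @param lengths Integer fragment lengths, one pair each.
#' @param chroms Chromosome per fragment (recycled; default `"chr1"`).
#' @param mapq Mapping quality per fragment (recycled; default 60).
#' @param read_len Read length in bp (default 35).
#' @param chrom_len Declared chromosome length in the header.
#' @return Named count vector: the emitted per-length tally.
#' @export
write_sam_fixture <- function(path, lengths, chroms = "chr1", mapq = 60L,
                              read_len = 35L, chrom_len = 1000000L) {
  n <- length(lengths)
  chroms <- rep_len(chroms, n)
  mapq <- rep_len(as.integer(mapq), n)
  pos <- ((seq_len(n) - 1L) * 503L) %% (chrom_len - max(lengths) -
                                          read_len) + 1L
  sq <- unique(chroms)
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           paste0("@SQ\tSN:", sq, "\tLN:", chrom_len))
  mpos <- pos + lengths - read_len
  rec1 <- paste("frag", seq_len(n), sep = "")
  lines <- c(hdr,
    paste(rec1, 99L, chroms, pos, mapq, paste0(read_len, "M"), "=",
          mpos, lengths, "*", "*", sep = "\t"),
    paste(rec1, 147L, chroms, mpos, mapq, paste0(read_len, "M"), "=",
          pos, -lengths, "*", "*", sep = "\t"))
  writeLines(lines, path)
  tab <- table(lengths)
  setNames(as.integer(tab), names(tab))
}
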