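#' Y-based fetal fraction parameters
#'
#' Baselines for the chromosome-Y reference estimator: the mean chrY read
#' fraction of pregnancies with euploid female fetuses (no fetal chrY, so
#' pure mismapping background) and of adult male plasma (a "100% fetal
#' fraction" genome).
#'
#' @param female_baseline Mean %chrY of euploid-female-fetus pregnancies.
#' @param male_baseline Mean %chrY of adult male plasma samples.
#' @return A `ybase_params` object.
#' @export
ybase_params <- function(female_baseline, male_baseline) {
  assert_that(is.numeric(female_baseline) && is.numeric(male_baseline),
              "baselines must be numeric")
  assert_that(female_baseline >= 0 && male_baseline <= 1 &&
                female_baseline < male_baseline,
              "need 0 <= female_baseline < male_baseline <= 1")
  structure(list(female_baseline = female_baseline,
                 male_baseline = male_baseline),
            class = "ybase_params")
}

#' @export
print.ybase_params <- function(x, ...) {
  cat("<ybase_params> female %chrY", format(x$female_baseline),
      "male %chrY", format(x$male_baseline), "\n")
  invisible(x)
}

#' Calibrate Y-based baselines from reference cohorts
#'
#' Baselines are the arithmetic means of the chrY read fractions of the two
#' cohorts (adult males, and pregnancies with euploid female fetuses).
#'
#' @param male_chry_fractions chrY read fractions of adult male plasma.
#' @param female_fetus_chry_fractions chrY read fractions of euploid
#'   female-fetus pregnancies.
#' @return A [ybase_params()] object.
#' @export
calibrate_y_params <- function(male_chry_fractions,
                               female_fetus_chry_fractions) {
  assert_that(length(male_chry_fractions) >= 1 &&
                length(female_fetus_chry_fractions) >= 1,
              "both cohorts must be non-empty")
  m <- mean(male_chry_fractions)
  f <- mean(female_fetus_chry_fractions)
  if (m <= f)
    stop_ff("male %chrY mean (", format(m),
            ") must exceed female mean (", format(f), ")",
            class = "ff_calibration_error")
  ybase_params(f, m)
}

#' Y-based fetal fraction estimate
#'
#' For a male-fetus pregnancy the fetal fraction is read off the chrY signal
#' linearly: FF = (%chrY - female baseline) / (male baseline - female
#' baseline). Estimates outside \[0, 1\] (possible for noisy inputs) are
#' returned unclipped, with an `out_of_range` attribute, so that downstream
#' regression targets are not censored.
#'
#' @param chry_fraction Numeric vector of chrY read fractions.
#' @param params A [ybase_params()] object.
#' @return Numeric vector of FF estimates with attribute `out_of_range`.
#' @export
estimate_y_based <- function(chry_fraction, params) {
  stopifnot(inherits(params, "ybase_params"))
  den <- params$male_baseline - params$female_baseline
  if (den == 0)
    stop_ff("male and female baselines coincide; estimator undefined",
            class = "ff_validation_error")
  ff <- (chry_fraction - params$female_baseline) / den
  attr(ff, "out_of_range") <- !is.na(ff) & (ff < 0 | ff > 1)
  ff
}

#' Filter a dataset to informative samples
#'
#' Aneuploidy calling is only reliable above a minimum fetal fraction; the
#' conventional cutoff is 4%. Samples below it (on the chosen FF column)
#' are dropped.
#'
#' @param ds An [nipt_dataset()].
#' @param min_ff Informative threshold (default 0.04).
#' @param using Sample column holding the FF used for the decision
#'   (default `"reference_ff"`).
#' @return Filtered `nipt_dataset`.
#' @export
filter_informative <- function(ds, min_ff = 0.04, using = "reference_ff") {
  ff <- ds$samples[[using]]
  assert_that(!is.null(ff) && any(!is.na(ff)),
              "column '", using, "' absent from dataset")
  ds_subset(ds, which(!is.na(ff) & ff >= min_ff))
}
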