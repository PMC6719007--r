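# Canonical combiner feature names (internal -> reporting)
COMBINER_FEATURES <- c(svm_ff = "SVM", seqff = "SeqFF", bmi = "BMI",
                       lc = "LC", ga = "GA")

#' Fit the multi-predictor linear combiner
#'
#' Ordinary least squares of the Y-based fetal fraction on any subset of
#' the five predictors: the SVR length-profile estimate (`svm_ff`), the
#' externally computed SeqFF value (`seqff`), and the sample attributes
#' BMI, library concentration (`lc`) and gestational age (`ga`). Supports
#' the four standard subsets (SeqFF+SA, SVM+SA, SVM+SeqFF, SeqFF+SVM+SA)
#' as well as any other combination.
#'
#' @param features Data frame whose columns are a subset of
#'   `c("svm_ff", "seqff", "bmi", "lc", "ga")`, no missing values.
#' @param targets Y-based FF targets.
#' @return A `combiner_params` with named coefficients and intercept.
#' @export
fit_combiner <- function(features, targets) {
  features <- as.data.frame(features)
  unknown <- setdiff(names(features), names(COMBINER_FEATURES))
  assert_that(length(unknown) == 0, "unknown combiner feature(s): ",
              paste(unknown, collapse = ", "))
  assert_that(ncol(features) >= 1, "need at least one feature")
  assert_that(!anyNA(features), "combiner features contain missing values")
  assert_that(nrow(features) > ncol(features) + 1,
              "need more samples than features + 1")
  x <- cbind(1, as.matrix(features))
  sol <- lstsq_minnorm(x, targets)
  if (sol$rank < ncol(x))
    warning("collinear combiner features; minimum-norm solution returned",
            call. = FALSE)
  structure(list(coefficients = setNames(sol$coef[-1], names(features)),
                 intercept = sol$coef[1]),
            class = "combiner_params")
}

#' @export
print.combiner_params <- function(x, ...) {
  cat("<combiner_params>\n")
  lab <- c(COMBINER_FEATURES[names(x$coefficients)], Intercept = "Intercept")
  print(setNames(c(x$coefficients, x$intercept), lab))
  invisible(x)
}

#' Predict fetal fraction from combined features
#'
#' Linear score over the features named in the params. Values outside
#' \[0, 1\] are returned unclipped with an `out_of_range` attribute.
#'
#' @param features Data frame (or named list/vector for one sample)
#'   providing every feature the params require.
#' @param params A `combiner_params` from [fit_combiner()].
#' @return FF estimates.
#' @export
predict_combined <- function(features, params) {
  stopifnot(inherits(params, "combiner_params"))
  if (!is.data.frame(features)) features <- as.data.frame(as.list(features))
  need <- names(params$coefficients)
  absent <- need[!need %in% names(features)]
  if (length(absent) == 0)
    absent <- need[vapply(features[need], anyNA, logical(1))]
  if (length(absent))
    stop_ff("required combiner feature(s) absent: ",
            paste(COMBINER_FEATURES[absent], collapse = ", "),
            class = "ff_validation_error")
  ff <- drop(as.matrix(features[need]) %*% params$coefficients) +
    params$intercept
  attr(ff, "out_of_range") <- !is.na(ff) & (ff < 0 | ff > 1)
  ff
}

#' Serialize combiner parameters to JSON
#'
#' Uses the conventional reporting names (SVM, SeqFF, BMI, LC, GA,
#' Intercept) so that parameter tables round-trip exactly.
#'
#' @param params A `combiner_params`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
combiner_to_json <- function(params, path = NULL) {
  obj <- as.list(setNames(params$coefficients,
                          COMBINER_FEATURES[names(params$coefficients)]))
  obj$Intercept <- params$intercept
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname combiner_to_json
#' @param json JSON string or file path produced by [combiner_to_json()].
#' @export
combiner_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  stopifnot("Intercept" %in% names(obj))
  coefs <- obj[setdiff(names(obj), "Intercept")]
  internal <- names(COMBINER_FEATURES)[match(names(coefs),
                                             COMBINER_FEATURES)]
  assert_that(!anyNA(internal), "unknown feature name in JSON")
  structure(list(coefficients = setNames(unlist(coefs), internal),
                 intercept = obj$Intercept),
            class = "combiner_params")
}

#' Replicate low-fetal-fraction samples for training
#'
#' Returns training indices in which every sample whose target is below
#' `threshold` appears `multiplier` times (originals first, in order, then
#' the extra copies appended in order). Estimators that accept per-sample
#' weights can use the returned `weights` vector on the original rows
#' instead; the two representations give identical least-squares fits.
#'
#' @param targets Fetal-fraction targets used for the stratum decision
#'   (conventionally the Y-based estimates).
#' @param threshold Low-FF cutoff (default 0.10).
#' @param multiplier Number of copies for low-FF samples (integer >= 1).
#' @return List with `indices` (integer vector) and `weights` (one per
#'   original sample).
#' @export
weight_training_set <- function(targets, threshold = 0.10, multiplier = 1L) {
  assert_that(multiplier >= 1 && multiplier == as.integer(multiplier),
              "multiplier must be a positive integer")
  assert_that(threshold > 0 && threshold < 1, "threshold must be in (0,1)")
  low <- which(!is.na(targets) & targets < threshold)
  extra <- rep(low, times = multiplier - 1L)
  weights <- rep(1L, length(targets))
  weights[low] <- as.integer(multiplier)
  list(indices = c(seq_along(targets), sort(extra)), weights = weights)
}
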