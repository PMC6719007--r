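#' Pearson correlation, mean squared error, mean absolute error
#'
#' Standard metrics used to score fetal-fraction predictions against the
#' Y-based reference.
#'
#' @param a,b Aligned numeric vectors (length >= 2).
#' @return A single number.
#' @export
pearson <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 2,
              "need two aligned vectors of length >= 2")
  if (sd(a) == 0 || sd(b) == 0)
    stop_ff("zero variance; correlation undefined",
            class = "ff_validation_error")
  cor(a, b)
}

#' @rdname pearson
#' @export
mse <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 1, "length mismatch")
  mean((a - b)^2)
}

#' @rdname pearson
#' @export
mae <- function(a, b) {
  assert_that(length(a) == length(b) && length(a) >= 1, "length mismatch")
  mean(abs(a - b))
}

# ---- method registry -------------------------------------------------------

new_ff_method <- function(name, fit, predict, min_n = 2L) {
  structure(list(name = name, fit = fit, predict = predict, min_n = min_n),
            class = "ff_method")
}

#' @export
print.ff_method <- function(x, ...) {
  cat("<ff_method>", x$name, "\n")
  invisible(x)
}

#' Built-in fetal-fraction estimation methods
#'
#' Method objects plug into [repeated_split_evaluate()] and
#' [weighting_experiment()]. Each carries a `fit(ds, targets, seed)` and a
#' `predict(model, ds)` function; within an evaluation repeat every method
#' sees identical train/test folds.
#'
#' * `method_frac()` - interval ratio statistic, calibrated to FF units by
#'   least squares.
#' * `method_nlrm()` - nonlinear weighted-ratio regression on the same
#'   intervals.
#' * `method_lrm()` - linear regression on all 171 length proportions.
#' * `method_svr()` - linear epsilon-SVR on standardized proportions.
#' * `method_mlp()` - tanh multilayer perceptron on standardized
#'   proportions.
#' * `method_seqff()` - passthrough of the externally computed SeqFF value.
#' * `method_combined()` - linear combination of predictors and sample
#'   attributes; when `svm_ff` is among the features, the combiner is
#'   trained on out-of-fold SVR predictions (`oof_folds`) to avoid
#'   leakage, or naively in-fold when `oof_folds = 0`.
#'
#' @param intervals An [interval_pair()] for ratio-based methods.
#' @param name Label used in result tables (lets two variants of the same
#'   method, e.g. published vs searched intervals, be compared side by
#'   side).
#' @name ff_methods
#' @export
method_frac <- function(intervals = optimal_intervals(), name = "frac") {
  new_ff_method(
    name,
    fit = function(ds, targets, seed) {
      fv <- frac_statistic(ds$profiles, intervals)
      list(intervals = intervals, calib = fit_frac_calibration(fv, targets))
    },
    predict = function(model, ds)
      predict(model$calib, frac_statistic(ds$profiles, model$intervals)),
    min_n = 3L)
}

#' @rdname ff_methods
#' @param ... Passed on to the underlying fitter.
#' @export
method_nlrm <- function(intervals = optimal_intervals(), ...) {
  args <- list(...)
  new_ff_method(
    "nlrm",
    fit = function(ds, targets, seed)
      do.call(fit_nlrm, c(list(ds$profiles, targets, intervals), args)),
    predict = function(model, ds) predict_nlrm(ds$profiles, model),
    min_n = (diff(intervals$i1) + 1L) + (diff(intervals$i2) + 1L))
}

#' @rdname ff_methods
#' @export
method_lrm <- function() {
  new_ff_method(
    "lrm",
    fit = function(ds, targets, seed) fit_lrm(ds$profiles, targets),
    predict = function(model, ds) predict(model, ds$profiles))
}

#' @rdname ff_methods
#' @export
method_svr <- function(...) {
  args <- list(...)
  new_ff_method(
    "svm",
    fit = function(ds, targets, seed) {
      std <- fit_standardizer(ds$profiles)
      model <- do.call(fit_svr,
                       c(list(apply_standardizer(std, ds$profiles), targets),
                         args))
      list(std = std, model = model)
    },
    predict = function(model, ds)
      predict(model$model, apply_standardizer(model$std, ds$profiles)))
}

#' @rdname ff_methods
#' @export
method_mlp <- function(...) {
  args <- list(...)
  new_ff_method(
    "nn",
    fit = function(ds, targets, seed) {
      std <- fit_standardizer(ds$profiles)
      fixed <- c(list(apply_standardizer(std, ds$profiles), targets), args)
      if (!"seed" %in% names(args)) fixed$seed <- seed
      list(std = std, model = do.call(fit_mlp, fixed))
    },
    predict = function(model, ds)
      predict(model$model, apply_standardizer(model$std, ds$profiles)))
}

#' @rdname ff_methods
#' @export
method_seqff <- function() {
  new_ff_method(
    "seqff",
    fit = function(ds, targets, seed) {
      assert_that(all(!is.na(ds$samples$seqff_value)),
                  "seqff_value absent for some samples")
      list()
    },
    predict = function(model, ds) ds$samples$seqff_value)
}

#' @rdname ff_methods
#' @param features Combiner features, a subset of
#'   `c("svm_ff", "seqff", "bmi", "lc", "ga")`.
#' @param oof_folds Folds for out-of-fold SVR predictions feeding the
#'   combiner (default 5; 0 = naive in-fold predictions).
#' @param svr_args Arguments passed to [fit_svr()] for the base model.
#' @export
method_combined <- function(features = c("svm_ff", "seqff"),
                            oof_folds = 5L, svr_args = list()) {
  name <- paste0("combined:",
                 paste(COMBINER_FEATURES[features], collapse = "+"))
  col_of <- c(seqff = "seqff_value", bmi = "bmi", lc = "lc", ga = "ga")
  collect <- function(ds, svm_ff = NULL) {
    out <- list()
    for (f in features) {
      v <- if (f == "svm_ff") svm_ff else ds$samples[[col_of[[f]]]]
      assert_that(!is.null(v) && all(!is.na(v)),
                  "combiner feature '", f, "' absent from dataset")
      out[[f]] <- v
    }
    as.data.frame(out)
  }
  new_ff_method(
    name,
    fit = function(ds, targets, seed) {
      svm_model <- NULL
      svm_oof <- NULL
      if ("svm_ff" %in% features) {
        std <- fit_standardizer(ds$profiles)
        xs <- apply_standardizer(std, ds$profiles)
        svm_model <- list(std = std,
                          model = do.call(fit_svr,
                                          c(list(xs, targets), svr_args)))
        if (oof_folds >= 2L) {
          n <- nrow(xs)
          fold <- with_preserved_rng({
            set.seed(seed)
            sample(rep_len(seq_len(oof_folds), n))
          })
          svm_oof <- numeric(n)
          for (k in seq_len(oof_folds)) {
            hold <- fold == k
            stdk <- fit_standardizer(ds$profiles[!hold, , drop = FALSE])
            mk <- do.call(fit_svr, c(list(
              apply_standardizer(stdk, ds$profiles[!hold, , drop = FALSE]),
              targets[!hold]), svr_args))
            svm_oof[hold] <- predict(mk,
              apply_standardizer(stdk, ds$profiles[hold, , drop = FALSE]))
          }
        } else {
          svm_oof <- predict(svm_model$model, xs)
        }
      }
      params <- fit_combiner(collect(ds, svm_oof), targets)
      list(params = params, svm = svm_model)
    },
    predict = function(model, ds) {
      svm_ff <- if (!is.null(model$svm))
        predict(model$svm$model,
                apply_standardizer(model$svm$std, ds$profiles))
      as.numeric(predict_combined(collect(ds, svm_ff), model$params))
    },
    min_n = length(features) + 2L)
}

# ---- repeated evaluation ---------------------------------------------------

eval_targets <- function(ds, targets) {
  if (!is.null(targets)) return(targets)
  t <- ds$samples$reference_ff
  assert_that(any(!is.na(t)),
              "dataset has no reference_ff; supply targets explicitly")
  t
}

#' Repeated 80/20 train/test evaluation
#'
#' The standard protocol for comparing fetal-fraction estimators: the
#' dataset is split at random into `train_frac` training and the rest
#' testing, each method is fitted on the training fold only (including any
#' standardization or calibration) and scored on the test fold, and the
#' split is repeated `n_repeats` times. All methods see identical folds
#' within a repeat, so comparisons are paired. Targets default to the
#' dataset's Y-based `reference_ff`.
#'
#' @param ds An [nipt_dataset()].
#' @param methods List of [ff_methods] objects (named or not).
#' @param targets Optional explicit targets (defaults to `reference_ff`).
#' @param n_repeats Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.8; fold sizes are
#'   `floor(train_frac * N)` and the remainder).
#' @param seed Master seed; spawns one seed per repeat.
#' @param stratum_threshold FF cutoff separating the low/high strata for
#'   stratified MAE (default 0.10; values at the cutoff count as low).
#' @return An `ff_evaluation`: `$metrics` has one row per repeat x method
#'   with `pearson`, `mse`, `mae`, `mae_low`, `mae_high` (per-method
#'   failures are recorded in `error` and the run continues).
#' @export
repeated_split_evaluate <- function(ds, methods, targets = NULL,
                                    n_repeats = 100L, train_frac = 0.8,
                                    seed = 17L, stratum_threshold = 0.10) {
  targets <- eval_targets(ds, targets)
  assert_that(length(targets) == n_samples(ds), "targets must align")
  if (inherits(methods, "ff_method")) methods <- list(methods)
  names(methods) <- vapply(methods, `[[`, "", "name")
  n <- n_samples(ds)
  n_train <- floor(train_frac * n)
  assert_that(n_train >= 2 && n_train < n, "degenerate fold sizes")
  seeds <- spawn_seeds(seed, n_repeats)
  rows <- vector("list", n_repeats * length(methods))
  r <- 0L
  for (t in seq_len(n_repeats)) {
    set.seed(seeds[t])
    perm <- sample.int(n)
    tr <- perm[seq_len(n_train)]
    te <- perm[(n_train + 1L):n]
    ds_tr <- ds_subset(ds, tr); ds_te <- ds_subset(ds, te)
    y_tr <- targets[tr]; y_te <- targets[te]
    low <- y_te <= stratum_threshold
    for (m in methods) {
      r <- r + 1L
      res <- tryCatch({
        if (length(tr) < m$min_n) stop("training fold smaller than method minimum")
        model <- m$fit(ds_tr, y_tr, seeds[t])
        pred <- m$predict(model, ds_te)
        data.frame(repeat_ = t, method = m$name,
                   n_train = length(tr), n_test = length(te),
                   pearson = pearson(pred, y_te), mse = mse(pred, y_te),
                   mae = mae(pred, y_te),
                   mae_low = if (any(low)) mae(pred[low], y_te[low])
                             else NA_real_,
                   mae_high = if (any(!low)) mae(pred[!low], y_te[!low])
                              else NA_real_,
                   error = NA_character_)
      }, error = function(e)
        data.frame(repeat_ = t, method = m$name, n_train = length(tr),
                   n_test = length(te), pearson = NA_real_, mse = NA_real_,
                   mae = NA_real_, mae_low = NA_real_, mae_high = NA_real_,
                   error = conditionMessage(e)))
      rows[[r]] <- res
    }
  }
  structure(list(metrics = do.call(rbind, rows),
                 config = list(n_repeats = n_repeats,
                               train_frac = train_frac, seed = seed,
                               n = n, n_train = n_train,
                               n_test = n - n_train,
                               stratum_threshold = stratum_threshold)),
            class = "ff_evaluation")
}

#' @export
print.ff_evaluation <- function(x, ...) {
  cat("<ff_evaluation>", x$config$n_repeats, "repeats,",
      x$config$n_train, "/", x$config$n_test, "train/test\n")
  print(summary(x))
  invisible(x)
}

#' Summarize an evaluation into boxplot-style statistics
#'
#' Median, quartiles and 1.5 IQR whiskers of Pearson r and MSE per method.
#'
#' @param object An `ff_evaluation`.
#' @param ... Unused.
#' @return Data frame, one row per method and metric.
#' @export
summary.ff_evaluation <- function(object, ...) {
  m <- object$metrics[is.na(object$metrics$error), ]
  out <- list()
  for (metric in c("pearson", "mse", "mae")) {
    agg <- tapply(m[[metric]], m$method, function(v) {
      v <- v[!is.na(v)]
      q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      iqr <- q[3] - q[1]
      c(median = q[2], q1 = q[1], q3 = q[3],
        whisker_lo = min(v[v >= q[1] - 1.5 * iqr]),
        whisker_hi = max(v[v <= q[3] + 1.5 * iqr]))
    })
    out[[metric]] <- data.frame(method = names(agg), metric = metric,
                                do.call(rbind, agg), row.names = NULL)
  }
  do.call(rbind, out)
}

#' Write evaluation metrics as a tidy TSV
#' @param x An `ff_evaluation` or `ff_weighting` result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation <- function(x, path) {
  tab <- if (inherits(x, "ff_evaluation")) x$metrics else x$metrics
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Correlation of sample attributes with the reference fetal fraction
#'
#' Pearson correlation of gestational age, BMI and library concentration
#' with the reference FF. Attributes that are absent or constant are
#' omitted, with a note in the `omitted` attribute.
#'
#' @param ds An [nipt_dataset()].
#' @param against Sample column to correlate with (default
#'   `"reference_ff"`, falling back to `"true_ff"`).
#' @return Data frame with `attribute`, `r`, `n`.
#' @export
attribute_correlations <- function(ds, against = "reference_ff") {
  ff <- ds$samples[[against]]
  if (all(is.na(ff))) ff <- ds$samples$true_ff
  assert_that(any(!is.na(ff)), "no reference or true FF in dataset")
  rows <- list(); omitted <- character()
  for (a in c("ga", "bmi", "lc")) {
    v <- ds$samples[[a]]
    ok <- !is.na(v) & !is.na(ff)
    if (sum(ok) < 3 || sd(v[ok]) == 0) {
      omitted <- c(omitted, a)
      next
    }
    rows[[a]] <- data.frame(attribute = a, r = cor(v[ok], ff[ok]),
                            n = sum(ok))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Low-fetal-fraction sample-weighting experiment
#'
#' Repeats the 80/20 protocol while replicating low-FF training samples
#' (target below `threshold`) 1x, 2x, 3x and 4x, and reports test MAE
#' separately for the low stratum (FF at or below the threshold) and the
#' high stratum. Folds are shared across multipliers within a repeat, and
#' multiplier 1 reproduces the unweighted evaluation exactly.
#'
#' @param ds An [nipt_dataset()].
#' @param multipliers Integer vector of replication factors (default 1:4).
#' @param threshold Low-FF cutoff (default 0.10).
#' @param n_repeats Number of random splits (default 100).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Master seed.
#' @param method The estimator under study (default [method_svr()]).
#' @param targets Optional explicit targets (defaults to `reference_ff`).
#' @return An `ff_weighting`: `$metrics` has one row per repeat x
#'   multiplier with `mae_low`, `mae_high` (NA when a stratum is empty in
#'   the test fold), plus a `summary` of per-multiplier medians.
#' @export
weighting_experiment <- function(ds, multipliers = 1:4, threshold = 0.10,
                                 n_repeats = 100L, train_frac = 0.8,
                                 seed = 17L, method = method_svr(),
                                 targets = NULL) {
  targets <- eval_targets(ds, targets)
  n <- n_samples(ds)
  n_train <- floor(train_frac * n)
  seeds <- spawn_seeds(seed, n_repeats)
  rows <- list()
  for (t in seq_len(n_repeats)) {
    set.seed(seeds[t])
    perm <- sample.int(n)
    tr <- perm[seq_len(n_train)]
    te <- perm[(n_train + 1L):n]
    ds_te <- ds_subset(ds, te)
    y_tr <- targets[tr]; y_te <- targets[te]
    low <- y_te <= threshold
    for (mult in multipliers) {
      w <- weight_training_set(y_tr, threshold, mult)
      ds_w <- ds_subset(ds, tr[w$indices])
      model <- method$fit(ds_w, y_tr[w$indices], seeds[t])
      pred <- method$predict(model, ds_te)
      rows[[length(rows) + 1L]] <- data.frame(
        repeat_ = t, multiplier = mult,
        n_train_rows = length(w$indices),
        mae_low = if (any(low)) mae(pred[low], y_te[low]) else NA_real_,
        mae_high = if (any(!low)) mae(pred[!low], y_te[!low]) else NA_real_,
        n_low = sum(low), n_high = sum(!low))
    }
  }
  metrics <- do.call(rbind, rows)
  med <- function(col) tapply(metrics[[col]], metrics$multiplier,
                              median, na.rm = TRUE)
  structure(list(metrics = metrics,
                 summary = data.frame(multiplier = as.integer(
                                        names(med("mae_low"))),
                                      median_mae_low = as.numeric(
                                        med("mae_low")),
                                      median_mae_high = as.numeric(
                                        med("mae_high"))),
                 config = list(threshold = threshold, seed = seed,
                               n_repeats = n_repeats,
                               method = method$name)),
            class = "ff_weighting")
}

#' @export
print.ff_weighting <- function(x, ...) {
  cat("<ff_weighting>", x$config$method, "-", x$config$n_repeats,
      "repeats, threshold", x$config$threshold, "\n")
  print(x$summary)
  invisible(x)
}
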