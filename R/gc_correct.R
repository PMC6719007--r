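#' Per-bin GC content from a reference genome
#'
#' Computes GC = (G+C)/(A+C+G+T) for each genomic bin. Bins in which more
#' than half of the reference bases are N are flagged invalid and take no
#' part in GC model fitting or corrected totals.
#'
#' @param reference FASTA path or a [Biostrings::DNAStringSet].
#' @param bins Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @return `bins` with columns `gc` and `gc_valid` appended.
#' @export
compute_bin_gc <- function(reference, bins) {
  seqs <- if (inherits(reference, "DNAStringSet")) reference
          else Biostrings::readDNAStringSet(reference)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  absent <- setdiff(unique(bins$chrom), names(seqs))
  if (length(absent))
    stop_ff("chromosome(s) absent from reference: ",
            paste(absent, collapse = ", "), class = "ff_validation_error")
  gc <- numeric(nrow(bins)); valid <- logical(nrow(bins))
  for (chrom in unique(bins$chrom)) {
    i <- which(bins$chrom == chrom)
    sub <- Biostrings::subseq(rep(seqs[chrom], length(i)),
                              start = bins$start[i] + 1L, end = bins$end[i])
    freq <- Biostrings::alphabetFrequency(sub, baseOnly = TRUE)
    acgt <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    width <- bins$end[i] - bins$start[i]
    n_frac <- 1 - acgt / width
    gc[i] <- ifelse(acgt > 0,
                    rowSums(freq[, c("G", "C"), drop = FALSE]) / acgt, NA_real_)
    valid[i] <- n_frac <= 0.5 & acgt > 0
  }
  bins$gc <- gc
  bins$gc_valid <- valid
  bins
}

#' Fit a LOESS GC-bias model on binned counts
#'
#' Locally weighted regression of per-bin read count on per-bin GC fraction
#' over usable autosomal bins (valid GC, finite count). The model stores the
#' global mean usable count `m`; bin weights are later `m / fitted(gc)`.
#'
#' @param bins Data frame with `chrom`, `gc`, `gc_valid`, `raw_count`.
#' @param span LOESS span (default 0.3).
#' @param min_bins Minimum usable autosomal bins (default 50).
#' @return A `gc_model` with the fitted curve, global mean `m`, and the
#'   usable-bin mask used for fitting.
#' @export
fit_gc_model <- function(bins, span = 0.3, min_bins = 50L) {
  usable <- bins$gc_valid & is_autosome(bins$chrom) &
    is.finite(bins$raw_count) & bins$raw_count > 0
  if (sum(usable) < min_bins)
    stop_ff("only ", sum(usable), " usable autosomal bins (need ",
            min_bins, ")", class = "ff_validation_error")
  dat <- data.frame(gc = bins$gc[usable], count = bins$raw_count[usable])
  fit <- loess(count ~ gc, data = dat, span = span, degree = 2,
               surface = "direct", family = "gaussian")
  structure(list(fit = fit, m = mean(dat$count), span = span,
                 gc_range = range(dat$gc), usable = usable),
            class = "gc_model")
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model> span", x$span, "- mean usable count", format(x$m),
      "over", sum(x$usable), "bins\n")
  invisible(x)
}

#' Predict expected count at given GC fractions
#' @param object A `gc_model`.
#' @param gc Numeric vector of GC fractions.
#' @param ... Unused.
#' @return Expected counts.
#' @export
predict.gc_model <- function(object, gc, ...) {
  as.numeric(predict(object$fit, newdata = data.frame(gc = gc)))
}

#' Apply GC-bias weights to binned counts
#'
#' Corrected count = raw count x m / fitted(gc) for usable bins. Invalid-GC
#' bins pass through unweighted but are excluded from per-chromosome totals.
#' Chromosome Y is never corrected: its mappable portion carries too few
#' reads for a stable fit, so its total is the raw sum over all chrY bins.
#'
#' @param bins Data frame with `chrom`, `gc`, `gc_valid`, `raw_count`.
#' @param model A `gc_model` from [fit_gc_model()].
#' @return List with `bins` (column `corrected_count` appended) and
#'   `chrom_totals` (named vector of corrected per-chromosome totals; raw
#'   for chrY).
#' @export
apply_gc_weights <- function(bins, model) {
  is_y <- bins$chrom %in% c("chrY", "Y")
  usable <- bins$gc_valid & !is_y
  fitted <- rep(NA_real_, nrow(bins))
  fitted[usable] <- predict(model, bins$gc[usable])
  if (any(usable & (!is.finite(fitted) | fitted <= 0)))
    stop_ff("GC model predicts non-positive expected count; model misfit",
            class = "ff_validation_error")
  corrected <- bins$raw_count
  corrected[usable] <- bins$raw_count[usable] * model$m / fitted[usable]
  bins$corrected_count <- corrected
  in_total <- usable | is_y
  totals <- tapply(ifelse(is_y, bins$raw_count, corrected)[in_total],
                   bins$chrom[in_total], sum)
  list(bins = bins, chrom_totals = setNames(as.numeric(totals),
                                            names(totals)))
}

#' Read/write BED-like GC bin tables
#'
#' Columns: `chrom`, `start`, `end`, `gc`, `gc_valid`, `raw_count` and,
#' after correction, `corrected_count`.
#'
#' @param path TSV path.
#' @return Data frame of bins.
#' @export
read_bin_table <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname read_bin_table
#' @param bins Bin data frame.
#' @export
write_bin_table <- function(bins, path) {
  write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
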