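#' VCF concordance: TP/FP/FN classification
#'
#' Compares two variant call sets on exact (contig, pos, ref, alt) keys:
#' true positives are keys called in both sets, false positives are keys
#' only in the test set, false negatives keys only in the baseline.
#' Multi-allelic lines contribute one key per alternate allele; duplicate
#' keys within a set count once. Matching is exact, not haplotype-aware:
#' complex loci that a haplotype-resolving comparator would reconcile (e.g.
#' the same change expressed as different ref/alt spellings) count as
#' discordant here.
#'
#' @param test variant keys of the pipeline under evaluation: a data.frame
#'   with `contig`, `pos`, `ref`, `alt` columns (see [read_vcf_variants()])
#'   or a VCF path.
#' @param baseline variant keys of the baseline pipeline, same forms.
#' @return Named integer vector `c(tp=, fp=, fn=)`.
#' @examples
#' test <- data.frame(contig = "c", pos = 1:3, ref = "A", alt = "T")
#' base <- data.frame(contig = "c", pos = 2:4, ref = "A", alt = "T")
#' classify_variants(test, base)  # tp 2, fp 1, fn 1
#' @export
classify_variants <- function(test, baseline) {
  kt <- unique(variant_keys(test))
  kb <- unique(variant_keys(baseline))
  tp <- sum(kt %in% kb)
  c(tp = tp, fp = length(kt) - tp, fn = length(kb) - tp)
}

variant_keys <- function(x) {
  if (is.character(x) && length(x) == 1L) x <- read_vcf_variants(x)
  stopifnot(is.data.frame(x),
            all(c("contig", "pos", "ref", "alt") %in% names(x)))
  paste(x$contig, x$pos, x$ref, x$alt, sep = "\r")
}

#' Sensitivity (recall) as a percentage
#'
#' `100 * TP / (TP + FN)`, reported to two decimals: the share of baseline
#' variants the test pipeline recovered.
#'
#' @param tp true positives (>= 0).
#' @param fn false negatives (>= 0).
#' @return Numeric percentage in `[0, 100]`, rounded to two decimals.
#' @examples
#' sensitivity(109411, 6363)  # 94.50
#' @export
sensitivity <- function(tp, fn) {
  check_counts(tp, fn)
  if (tp + fn == 0) {
    stop("sensitivity undefined: no baseline variants (TP + FN = 0)",
         call. = FALSE)
  }
  round(100 * tp / (tp + fn), 2)
}

#' Precision as a percentage
#'
#' `100 * TP / (TP + FP)`, reported to two decimals: the share of test-set
#' calls confirmed by the baseline.
#'
#' @param tp true positives (>= 0).
#' @param fp false positives (>= 0).
#' @return Numeric percentage in `[0, 100]`, rounded to two decimals.
#' @examples
#' precision(109411, 6886)  # 94.08
#' @export
precision <- function(tp, fp) {
  check_counts(tp, fp)
  if (tp + fp == 0) {
    stop("precision undefined: no test variants (TP + FP = 0)",
         call. = FALSE)
  }
  round(100 * tp / (tp + fp), 2)
}

check_counts <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L || is.na(a) || is.na(b) ||
      a < 0 || b < 0 || a != floor(a) || b != floor(b)) {
    stop("counts must be single non-negative integers", call. = FALSE)
  }
  invisible(TRUE)
}

#' Full concordance report between two VCFs
#'
#' Classifies variants with [classify_variants()] and derives
#' [sensitivity()] and [precision()].
#'
#' @inheritParams classify_variants
#' @return An `AccuracyReport`: list with `tp`, `fp`, `fn`, `sensitivity`,
#'   `precision` (percentages; `NA` where undefined).
#' @export
evaluate_concordance <- function(test, baseline) {
  k <- classify_variants(test, baseline)
  structure(
    list(tp = unname(k["tp"]), fp = unname(k["fp"]), fn = unname(k["fn"]),
         sensitivity = if (k["tp"] + k["fn"] > 0)
           unname(sensitivity(k[["tp"]], k[["fn"]])) else NA_real_,
         precision = if (k["tp"] + k["fp"] > 0)
           unname(precision(k[["tp"]], k[["fp"]])) else NA_real_),
    class = "AccuracyReport"
  )
}

#' @export
print.AccuracyReport <- function(x, ...) {
  cat(sprintf("AccuracyReport: TP %d, FP %d, FN %d; sensitivity %.2f%%, precision %.2f%%\n",
              x$tp, x$fp, x$fn, x$sensitivity, x$precision))
  invisible(x)
}

#' Write an AccuracyReport as JSON
#' @param report an [evaluate_concordance()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_accuracy_json <- function(report, path) {
  stopifnot(inherits(report, "AccuracyReport"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an AccuracyReport as one-line TSV
#' @inheritParams write_accuracy_json
#' @return `path`, invisibly.
#' @export
write_accuracy_tsv <- function(report, path) {
  stopifnot(inherits(report, "AccuracyReport"))
  writeLines(c("tp\tfp\tfn\tsensitivity\tprecision",
               sprintf("%d\t%d\t%d\t%.2f\t%.2f", report$tp, report$fp,
                       report$fn, report$sensitivity, report$precision)),
             path)
  invisible(path)
}
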