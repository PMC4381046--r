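#' Exon-level quality-control thresholds
#'
#' Defaults follow the recommended whole-exome practice of excluding targets
#' that (i) have median read depth across samples below 20 (mostly capture
#' failure), (ii) are shorter than 20 bp, (iii) have mappability below 0.9,
#' or (iv) have GC content outside 20--80%. Thresholds are inclusive on the
#' passing side: a median of exactly 20 or a GC of exactly 0.20 passes.
#'
#' @param min_median_depth minimum median read depth across samples.
#' @param min_length minimum target length in bp.
#' @param min_mappability minimum mean mappability.
#' @param gc_range length-2 numeric, allowed GC fraction range (inclusive).
#' @return a `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_median_depth = 20, min_length = 20,
                          min_mappability = 0.9, gc_range = c(0.20, 0.80)) {
  stopifnot(
    is.finite(min_median_depth), is.finite(min_length),
    is.finite(min_mappability), length(gc_range) == 2,
    all(is.finite(gc_range)), gc_range[1] < gc_range[2]
  )
  structure(
    list(min_median_depth = min_median_depth, min_length = min_length,
         min_mappability = min_mappability, gc_range = gc_range),
    class = "qc_thresholds"
  )
}

#' Filter exon targets by depth, length, mappability and GC
#'
#' Applies the four exon-level filters and returns the reduced matrix plus a
#' per-target audit table listing every rule each excluded target failed.
#' Filtering is idempotent. The function also warns when any sample's total
#' read count deviates from the cohort median by more than 5-fold, a crude
#' flag for samples from a different platform or failed library.
#'
#' @param cov a [coverage_matrix()] whose targets carry `gc` and
#'   `mappability`.
#' @param thresholds a [qc_thresholds()].
#' @return A list with `cov` (the filtered `coverage_matrix`) and `report`
#'   (tibble: chrom, start, end, median_depth, length, mappability, gc,
#'   pass, reasons).
#' @export
filter_targets <- function(cov, thresholds = qc_thresholds()) {
  stopifnot(inherits(cov, "coverage_matrix"),
            inherits(thresholds, "qc_thresholds"))
  tg <- cov$targets
  if (anyNA(tg$gc)) stop("targets have unset gc; run compute_gc() first")
  if (anyNA(tg$mappability))
    stop("targets have unset mappability; run add_mappability() first")

  med <- apply(cov$Y, 1, stats::median)
  fail <- tibble::tibble(
    depth = med < thresholds$min_median_depth,
    length = tg$length < thresholds$min_length,
    mappability = tg$mappability < thresholds$min_mappability,
    gc = tg$gc < thresholds$gc_range[1] | tg$gc > thresholds$gc_range[2]
  )
  pass <- !apply(as.matrix(fail), 1, any)
  reasons <- apply(as.matrix(fail), 1, function(f)
    paste(names(fail)[f], collapse = ";"))
  report <- tibble::tibble(
    chrom = tg$chrom, start = tg$start, end = tg$end,
    median_depth = med, length = tg$length,
    mappability = tg$mappability, gc = tg$gc,
    pass = pass, reasons = reasons
  )
  if (!any(pass)) stop("all targets filtered")

  ratio <- cov$N / stats::median(cov$N)
  off <- ratio > 5 | ratio < 1 / 5
  if (any(off))
    warning("sample(s) with total reads >5x from cohort median: ",
            paste(cov$sample_ids[off], collapse = ", "))

  list(cov = cov[pass, ], report = report)
}
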