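#' Count exon read depth for one sample from a BAM file
#'
#' A read contributes one count to every target its aligned span overlaps by
#' at least one base, so a read straddling two adjacent exons is counted in
#' both. By default only primary, mapped, non-duplicate alignments with
#' mapping quality >= 20 are retained; the same filter defines the sample's
#' genome-wide total `N` of mapped reads (not the sum over targets). All
#' filters are exposed as arguments.
#'
#' @param targets tibble from [read_targets()].
#' @param bam path to a coordinate-sorted, indexed BAM file.
#' @param min_mapq minimum mapping quality (default 20).
#' @param drop_duplicates drop duplicate-flagged reads (default TRUE).
#' @param primary_only drop secondary/supplementary alignments (default TRUE).
#' @return A list with `counts` (integer vector, one per target) and `N`
#'   (total retained mapped reads in the file).
#' @export
count_coverage <- function(targets, bam, min_mapq = 20,
                           drop_duplicates = TRUE, primary_only = TRUE) {
  targets <- validate_targets(targets)
  if (!file.exists(bam)) stop("no such file: ", bam)
  if (!file.exists(paste0(bam, ".bai")) && !file.exists(sub("\\.bam$", ".bai", bam)))
    stop("BAM index (.bai) not found for ", bam)
  flag <- Rsamtools::scanBamFlag(
    isUnmappedQuery = FALSE,
    isDuplicate = if (drop_duplicates) FALSE else NA,
    isSecondaryAlignment = if (primary_only) FALSE else NA,
    isSupplementaryAlignment = if (primary_only) FALSE else NA
  )
  param <- Rsamtools::ScanBamParam(flag = flag, mapqFilter = min_mapq)
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  N <- length(aln)
  if (N == 0) stop("no retained mapped reads in ", bam)
  gr <- GenomicRanges::GRanges(
    targets$chrom, IRanges::IRanges(targets$start + 1L, targets$end))
  counts <- GenomicRanges::countOverlaps(gr, aln, minoverlap = 1L,
                                         ignore.strand = TRUE)
  list(counts = as.integer(counts), N = N)
}

#' Build a coverage matrix from a set of BAM files
#'
#' Runs [count_coverage()] over each BAM and assembles the result.
#'
#' @inheritParams count_coverage
#' @param bams character vector of BAM paths.
#' @param sample_ids labels; defaults to BAM basenames without extension.
#' @param ... passed to [count_coverage()].
#' @return a [coverage_matrix()].
#' @export
coverage_from_bams <- function(targets, bams,
                               sample_ids = sub("\\.bam$", "", basename(bams)),
                               ...) {
  targets <- validate_targets(targets)
  cols <- lapply(bams, function(b) count_coverage(targets, b, ...))
  Y <- vapply(cols, `[[`, numeric(nrow(targets)), "counts")
  N <- vapply(cols, `[[`, numeric(1), "N")
  coverage_matrix(Y, targets, sample_ids, N)
}
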