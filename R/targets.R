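#' Read exon capture targets from a BED file
#'
#' Reads a 3+ column BED file of capture intervals. Coordinates are kept in
#' the BED convention (0-based, half-open) internally; only human-readable
#' reports use 1-based positions. Targets are sorted by (chrom, start) and
#' duplicated intervals are rejected.
#'
#' @param path path to a BED file.
#' @return A tibble with columns `chrom`, `start`, `end`, `length` and
#'   placeholder columns `gc`, `mappability` (`NA` until filled by
#'   [compute_gc()] / [add_mappability()]).
#' @seealso [compute_gc()], [add_mappability()], [count_coverage()]
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (!length(lines)) stop("no intervals in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    bad <- which(nf < 3)[1]
    stop("malformed BED line ", bad, ": fewer than 3 columns")
  }
  starts <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ends <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(starts) || anyNA(ends)) {
    bad <- which(is.na(starts) | is.na(ends))[1]
    stop("malformed BED line ", bad, ": non-integer coordinates")
  }
  if (any(ends <= starts)) {
    bad <- which(ends <= starts)[1]
    stop("malformed BED line ", bad, ": end <= start")
  }
  tg <- tibble::tibble(
    chrom = vapply(fields, `[[`, "", 1L),
    start = starts, end = ends
  )
  if (anyDuplicated(tg[, c("chrom", "start", "end")]))
    stop("duplicate target in ", path)
  tg <- dplyr::arrange(tg, .data$chrom, .data$start, .data$end)
  tg$length <- tg$end - tg$start
  tg$gc <- NA_real_
  tg$mappability <- NA_real_
  tg
}

validate_targets <- function(targets) {
  targets <- tibble::as_tibble(targets)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(targets)))
    stop("targets must have columns chrom, start, end")
  if (any(targets$end <= targets$start)) stop("target with end <= start")
  if (anyDuplicated(targets[, need])) stop("duplicate target")
  ord <- order(targets$chrom, targets$start, targets$end)
  if (!identical(ord, seq_len(nrow(targets))))
    stop("targets must be sorted by (chrom, start)")
  if (!"length" %in% names(targets))
    targets$length <- targets$end - targets$start
  for (col in c("gc", "mappability")) {
    if (col %in% names(targets)) {
      v <- targets[[col]]
      if (any(!is.na(v) & (v < 0 | v > 1)))
        stop(col, " must lie in [0, 1]")
    }
  }
  targets
}

#' Compute per-target GC content from a reference FASTA
#'
#' GC content is (#G + #C) / (#A + #C + #G + #T) over the target interval;
#' ambiguous bases (N etc.) are excluded from both numerator and denominator
#' so that hard-masked stretches do not bias the estimate toward zero.
#'
#' @param targets tibble from [read_targets()].
#' @param fasta path to an indexed reference FASTA (a `.fai` sidecar is
#'   created with `Rsamtools::indexFa()` if absent).
#' @return `targets` with the `gc` column filled (NA where a target contains
#'   no unambiguous base).
#' @export
compute_gc <- function(targets, fasta) {
  targets <- validate_targets(targets)
  if (!file.exists(paste0(fasta, ".fai"))) Rsamtools::indexFa(fasta)
  fa <- Rsamtools::FaFile(fasta)
  info <- Rsamtools::seqinfo(fa)
  missing <- setdiff(unique(targets$chrom), GenomeInfoDb_seqnames(info))
  if (length(missing))
    stop("chromosome(s) absent from reference: ",
         paste(missing, collapse = ", "))
  gr <- GenomicRanges::GRanges(
    targets$chrom,
    IRanges::IRanges(targets$start + 1L, targets$end)
  )
  seqs <- Rsamtools::getSeq(fa, gr)
  freq <- Biostrings::letterFrequency(seqs, c("A", "C", "G", "T"))
  acgt <- rowSums(freq)
  gc <- ifelse(acgt > 0, (freq[, "C"] + freq[, "G"]) / acgt, NA_real_)
  targets$gc <- as.numeric(gc)
  targets
}

# seqnames of a Seqinfo without importing GenomeInfoDb explicitly
GenomeInfoDb_seqnames <- function(info) {
  as.character(methods::slot(info, "seqnames"))
}

#' Attach per-target mappability
#'
#' Mappability is consumed from a user-supplied track: either a bigWig file
#' (mean signal over the target) or a 4-column TSV (`chrom`, `start`, `end`,
#' `mappability` on matching 0-based half-open intervals). When no track is
#' given every target gets mappability 1.0, with a warning, so that the QC
#' mappability filter becomes a no-op.
#'
#' @param targets tibble from [read_targets()].
#' @param track path to a bigWig or TSV mappability track, or `NULL`.
#' @return `targets` with the `mappability` column filled.
#' @export
add_mappability <- function(targets, track = NULL) {
  targets <- validate_targets(targets)
  if (is.null(track)) {
    warning("no mappability track supplied; defaulting all targets to 1.0")
    targets$mappability <- 1.0
    return(targets)
  }
  if (grepl("\\.(bw|bigwig)$", track, ignore.case = TRUE)) {
    gr <- GenomicRanges::GRanges(
      targets$chrom, IRanges::IRanges(targets$start + 1L, targets$end))
    sig <- rtracklayer::import(track, which = gr)
    hits <- GenomicRanges::findOverlaps(gr, sig)
    ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                    sig[S4Vectors::subjectHits(hits)])
    w <- GenomicRanges::width(ov)
    s <- sig$score[S4Vectors::subjectHits(hits)] * w
    num <- tapply(s, S4Vectors::queryHits(hits), sum)
    den <- tapply(w, S4Vectors::queryHits(hits), sum)
    mapp <- rep(NA_real_, length(gr))
    mapp[as.integer(names(num))] <- as.numeric(num / den)
    targets$mappability <- mapp
  } else {
    tab <- readr::read_tsv(track, show_col_types = FALSE, progress = FALSE,
                           col_names = c("chrom", "start", "end", "mappability"),
                           comment = "#")
    key <- paste(targets$chrom, targets$start, targets$end)
    idx <- match(key, paste(tab$chrom, tab$start, tab$end))
    if (anyNA(idx))
      stop(sum(is.na(idx)), " target(s) missing from mappability TSV")
    targets$mappability <- tab$mappability[idx]
  }
  if (any(!is.na(targets$mappability) &
          (targets$mappability < 0 | targets$mappability > 1)))
    stop("mappability values must lie in [0, 1]")
  targets
}
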