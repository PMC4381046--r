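# fixtures built in code: tiny references, alignments and cohorts

# a fit with lambda known exactly, for exercising the callers without a
# model fit
fake_fit <- function(Y, lam, chrom = "chr1") {
  n <- nrow(Y); m <- ncol(Y)
  start <- seq(0L, by = 200L, length.out = n)
  structure(
    list(Y = Y, lam = lam, K = 0,
         targets = tibble::tibble(chrom = chrom, start = start,
                                  end = start + 100L, length = 100L,
                                  gc = runif(n, 0.3, 0.7), mappability = 1),
         sample_ids = sprintf("S%02d", seq_len(m)),
         N = rep(1e6, m)),
    class = "null_model_fit"
  )
}

quiet_fit <- function(...) suppressWarnings(fit_null_model(...))

# independent Poisson deviance (reference implementation for cross-checks)
poisson_dev_ref <- function(Y, mu) {
  term <- ifelse(Y > 0, Y * log(Y / mu), 0)
  2 * sum(term - (Y - mu))
}

# write a tiny FASTA reference and return its path
write_test_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "ref.fa")
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- names(seqs)
  Biostrings::writeXStringSet(dna, path)
  path
}

# write a SAM file (then BAM + index) from a tibble of alignments
write_test_bam <- function(reads, seqlens,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "sample.sam")
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqlens), seqlens))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                  reads$qname, reads$flag, reads$rname, reads$pos,
                  reads$mapq, reads$cigar, reads$seq,
                  strrep("I", nchar(reads$seq)))
  writeLines(c(hdr, body), sam)
  bam <- Rsamtools::asBam(sam, file.path(dir, "sample"),
                          overwrite = TRUE, indexDestination = TRUE)
  bam
}

# an 8-exon coverage fixture hitting every QC failure mode exactly once
qc_fixture <- function() {
  targets <- tibble::tibble(
    chrom = "chr1",
    start = c(0L, 1000L, 2000L, 3000L, 4000L, 5000L, 6000L, 7000L),
    end = c(100L, 1100L, 2010L, 3100L, 4100L, 5100L, 6100L, 7100L),
    gc = c(0.5, 0.5, 0.5, 0.10, 0.90, 0.5, 0.20, 0.80),
    mappability = c(1, 1, 1, 1, 1, 0.85, 1, 1)
  )
  targets$length <- targets$end - targets$start
  # exon 2: low median depth; exon 3: short; exon 4: low gc; exon 5: high gc;
  # exon 6: low mappability; exons 1, 7, 8 pass (7/8 on the gc boundary)
  Y <- matrix(50L, 8, 3)
  Y[2, ] <- c(19L, 19L, 21L)   # median 19 < 20
  cov <- coverage_matrix(Y, targets, c("a", "b", "c"), N = rep(1e6, 3))
  cov
}
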