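#' Assemble an exon-by-sample coverage matrix
#'
#' Bundles a non-negative integer read-count matrix with its row-aligned
#' exon targets, sample identifiers and per-sample genome-wide totals of
#' mapped reads. This is the central container consumed by [filter_targets()],
#' [fit_null_model()] and [call_cnvs()].
#'
#' @param Y integer matrix, `n` exons by `m` samples, of read counts.
#' @param targets tibble of exon targets as returned by [read_targets()]
#'   (columns `chrom`, `start`, `end`, `length` and optionally `gc`,
#'   `mappability`), row-aligned with `Y`.
#' @param sample_ids character vector of `m` sample labels. Defaults to the
#'   column names of `Y`.
#' @param N numeric vector of `m` per-sample totals of mapped reads. This is
#'   the genome-wide total for the sample, not the column sum of `Y`.
#'
#' @return An object of class `coverage_matrix`: a list with elements `Y`,
#'   `targets`, `sample_ids`, `N`.
#' @export
coverage_matrix <- function(Y, targets, sample_ids = colnames(Y), N) {
  Y <- as.matrix(Y)
  if (any(!is.finite(Y)) || any(Y < 0) || any(Y != round(Y)))
    stop("Y must contain finite non-negative integer counts")
  storage.mode(Y) <- "double"
  targets <- validate_targets(targets)
  if (nrow(targets) != nrow(Y))
    stop("targets rows (", nrow(targets), ") != matrix rows (", nrow(Y), ")")
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(Y)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(Y))
    stop("sample_ids length != matrix columns")
  if (anyDuplicated(sample_ids)) stop("duplicate sample ids")
  N <- as.numeric(N)
  if (length(N) != ncol(Y)) stop("N length != matrix columns")
  if (any(!is.finite(N)) || any(N <= 0))
    stop("all per-sample read totals N must be finite and > 0")
  dimnames(Y) <- list(NULL, sample_ids)
  structure(
    list(Y = Y, targets = targets, sample_ids = sample_ids, N = N),
    class = "coverage_matrix"
  )
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("<coverage_matrix> ", nrow(x$Y), " exons x ", ncol(x$Y), " samples\n",
      sep = "")
  cat("  chromosomes: ", paste(unique(x$targets$chrom), collapse = ", "),
      "\n", sep = "")
  cat("  median depth: ", stats::median(x$Y), "; median N: ",
      format(stats::median(x$N), big.mark = ","), "\n", sep = "")
  invisible(x)
}

#' @export
dim.coverage_matrix <- function(x) dim(x$Y)

#' Subset a coverage matrix by exon and/or sample
#'
#' @param x a `coverage_matrix`.
#' @param i exon (row) index. @param j sample (column) index.
#' @param ... ignored.
#' @return a `coverage_matrix` restricted to the selected exons/samples.
#' @export
`[.coverage_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$Y))
  if (missing(j)) j <- seq_len(ncol(x$Y))
  coverage_matrix(x$Y[i, j, drop = FALSE], x$targets[i, , drop = FALSE],
                  x$sample_ids[j], x$N[j])
}

#' @describeIn coverage_matrix long-format view: one row per exon x sample
#'   with columns `chrom`, `start`, `end`, `sample`, `count`.
#' @param x a `coverage_matrix`.
#' @param ... passed on.
#' @export
tidy.coverage_matrix <- function(x, ...) {
  tibble::tibble(
    chrom = rep(x$targets$chrom, times = ncol(x$Y)),
    start = rep(x$targets$start, times = ncol(x$Y)),
    end = rep(x$targets$end, times = ncol(x$Y)),
    sample = rep(x$sample_ids, each = nrow(x$Y)),
    count = as.vector(x$Y)
  )
}

#' Write / read a coverage matrix as TSV
#'
#' The on-disk layout is a plain TSV with columns `chrom`, `start`, `end`
#' (0-based half-open), then one integer column per sample, plus a sidecar
#' `<path>.totals.tsv` holding per-sample genome-wide mapped-read totals
#' (and, when present, a `<path>.targets.tsv` sidecar with per-exon gc and
#' mappability).
#'
#' @param cov a `coverage_matrix`.
#' @param path output TSV path.
#' @return `write_matrix()` returns `path` invisibly; `read_matrix()` returns
#'   a `coverage_matrix`.
#' @export
write_matrix <- function(cov, path) {
  df <- dplyr::bind_cols(
    cov$targets[, c("chrom", "start", "end")],
    tibble::as_tibble(cov$Y)
  )
  readr::write_tsv(df, path)
  readr::write_tsv(
    tibble::tibble(sample = cov$sample_ids, total_reads = cov$N),
    paste0(path, ".totals.tsv")
  )
  extra <- intersect(c("gc", "mappability"), names(cov$targets))
  if (length(extra)) {
    readr::write_tsv(
      cov$targets[, c("chrom", "start", "end", extra)],
      paste0(path, ".targets.tsv")
    )
  }
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("chrom", "start", "end") %in% names(df)[1:3]))
    stop("coverage TSV must start with chrom/start/end columns")
  samples <- names(df)[-(1:3)]
  Y <- as.matrix(df[, samples])
  tot <- readr::read_tsv(paste0(path, ".totals.tsv"),
                         show_col_types = FALSE, progress = FALSE)
  if (!identical(as.character(tot$sample), samples))
    stop("totals sidecar sample ids do not match matrix header")
  targets <- tibble::tibble(
    chrom = as.character(df$chrom), start = as.integer(df$start),
    end = as.integer(df$end)
  )
  targets$length <- targets$end - targets$start
  side <- paste0(path, ".targets.tsv")
  if (file.exists(side)) {
    ann <- readr::read_tsv(side, show_col_types = FALSE, progress = FALSE)
    for (col in intersect(c("gc", "mappability"), names(ann)))
      targets[[col]] <- ann[[col]]
  }
  coverage_matrix(Y, targets, samples, tot$total_reads)
}
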