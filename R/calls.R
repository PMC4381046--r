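#' Call CNVs from a fitted null model
#'
#' Segments every sample on every chromosome with [cbs_segment()] against
#' the fitted control coverage and reports segments whose copy-number
#' estimate departs from the diploid state. In `"fraction"` mode the copy
#' number is `2 * y_sum / lam_sum` and a segment is called a deletion when
#' `copy < del_thr` or a duplication when `copy > dup_thr`; in `"integer"`
#' mode the copy number is rounded to the nearest non-negative integer and
#' every segment with rounded copy != 2 is called. For CNVs spanning only
#' one or two exons, the exon-level ratio caller [ratio_calls()] is the
#' sharper tool.
#'
#' @param fit a `null_model_fit` (from [fit_null_model()] or
#'   [fit_case_control()]).
#' @param mode `"fraction"` (default; suits samples of heterogeneous genetic
#'   composition) or `"integer"` (germline genotypes).
#' @param del_thr,dup_thr fraction-mode calling thresholds on the copy
#'   number (defaults 1.7 and 2.3; tune with [tune_threshold()]).
#' @param all_segments also return copy-neutral segments (`call = "neutral"`).
#' @param ... passed to [cbs_segment()].
#' @return A tibble of segment calls: `sample`, `chrom`, `exon_lo`,
#'   `exon_hi` (row indices into the fitted matrix), `start`, `end`
#'   (genomic, 0-based half-open span from first to last exon), `n_exons`,
#'   `y_sum`, `lam_sum`, `U`, `fold`, `copy`, `call`.
#' @export
call_cnvs <- function(fit, mode = c("fraction", "integer"),
                      del_thr = 1.7, dup_thr = 2.3,
                      all_segments = FALSE, ...) {
  stopifnot(inherits(fit, "null_model_fit"))
  mode <- match.arg(mode)
  tg <- fit$targets
  chroms <- unique(tg$chrom)
  out <- list()
  for (j in seq_along(fit$sample_ids)) {
    for (chr in chroms) {
      idx <- which(tg$chrom == chr)
      cp <- cbs_segment(fit$Y[idx, j], fit$lam[idx, j], ...)
      seg <- cp$segments
      seg$sample <- fit$sample_ids[j]
      seg$chrom <- chr
      seg$exon_lo <- idx[seg$s]
      seg$exon_hi <- idx[seg$t]
      seg$start <- tg$start[seg$exon_lo]
      seg$end <- tg$end[seg$exon_hi]
      out[[length(out) + 1]] <- seg
    }
  }
  calls <- dplyr::bind_rows(out)
  if (mode == "integer") {
    calls$copy <- pmax(round(calls$copy), 0)
    calls$call <- dplyr::case_when(
      calls$copy < 2 ~ "del", calls$copy > 2 ~ "dup", TRUE ~ "neutral")
  } else {
    calls$call <- dplyr::case_when(
      calls$copy < del_thr ~ "del", calls$copy > dup_thr ~ "dup",
      TRUE ~ "neutral")
  }
  calls <- calls[, c("sample", "chrom", "exon_lo", "exon_hi", "start", "end",
                     "n_exons", "y_sum", "lam_sum", "U", "fold", "copy",
                     "call")]
  if (!all_segments) calls <- calls[calls$call != "neutral", ]
  tibble::as_tibble(calls)
}

#' Exon-level ratio calling for very short CNVs
#'
#' Thresholds the per-cell log fold change `log2(Y / lam)` directly, the
#' appropriate caller for events extending over only one or two exons where
#' segmentation has little to gain. Zeros in `Y` are floored at 0.5 before
#' the log.
#'
#' @param fit a `null_model_fit`.
#' @param del_thr,dup_thr thresholds on the copy number `2 * Y / lam`
#'   (defaults as in [call_cnvs()]).
#' @return tibble: `sample`, `chrom`, `exon`, `start`, `end`, `log2_ratio`,
#'   `copy`, `call` for every non-neutral exon-sample cell.
#' @export
ratio_calls <- function(fit, del_thr = 1.7, dup_thr = 2.3) {
  stopifnot(inherits(fit, "null_model_fit"))
  Yp <- pmax(fit$Y, 0.5)
  copy <- 2 * fit$Y / fit$lam
  lr <- log2(Yp / fit$lam)
  state <- ifelse(copy < del_thr, "del",
                  ifelse(copy > dup_thr, "dup", "neutral"))
  hit <- which(state != "neutral", arr.ind = TRUE)
  tibble::tibble(
    sample = fit$sample_ids[hit[, 2]],
    chrom = fit$targets$chrom[hit[, 1]],
    exon = hit[, 1],
    start = fit$targets$start[hit[, 1]],
    end = fit$targets$end[hit[, 1]],
    log2_ratio = lr[hit],
    copy = copy[hit],
    call = state[hit]
  )
}

#' Per-exon normalized residuals
#'
#' `(Y - lam) / sqrt(lam)`, the Pearson residual track used for heatmap
#' inspection of normalized coverage.
#'
#' @param fit a `null_model_fit`.
#' @return n x m matrix of normalized residuals.
#' @export
normalized_residuals <- function(fit) {
  stopifnot(inherits(fit, "null_model_fit"))
  (fit$Y - fit$lam) / sqrt(fit$lam)
}

#' @describeIn call_cnvs residual heatmap of a fitted model
#'   (exons x samples, Pearson residual scale).
#' @param object a `null_model_fit`.
#' @export
autoplot.null_model_fit <- function(object, ...) {
  R <- normalized_residuals(object)
  df <- tibble::tibble(
    exon = rep(seq_len(nrow(R)), times = ncol(R)),
    sample = rep(object$sample_ids, each = nrow(R)),
    residual = as.vector(R)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exon, y = .data$sample,
                                   fill = .data$residual)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-4, 4), oob = scales_squish) +
    ggplot2::labs(x = "exon index", y = NULL, fill = "(Y - λ)/√λ",
                  title = "Normalized coverage residuals") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

# minimal squish to avoid a scales:: import for one helper
scales_squish <- function(x, range = c(0, 1)) {
  pmin(pmax(x, range[1]), range[2])
}

#' @describeIn fit_null_model one-row fit summary.
#' @param x a `null_model_fit`. @param ... ignored.
#' @export
glance.null_model_fit <- function(x, ...) {
  tibble::tibble(
    n_exons = nrow(x$Y), n_samples = ncol(x$Y), K = x$K,
    loglik = x$loglik, deviance = x$deviance, converged = x$converged,
    outer_iterations = nrow(x$trace)
  )
}

#' @describeIn fit_null_model long tibble of observed and control coverage
#'   with normalized residuals.
#' @export
tidy.null_model_fit <- function(x, ...) {
  R <- normalized_residuals(x)
  tibble::tibble(
    chrom = rep(x$targets$chrom, times = ncol(x$Y)),
    start = rep(x$targets$start, times = ncol(x$Y)),
    end = rep(x$targets$end, times = ncol(x$Y)),
    sample = rep(x$sample_ids, each = nrow(x$Y)),
    count = as.vector(x$Y),
    lambda = as.vector(x$lam),
    residual = as.vector(R)
  )
}
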