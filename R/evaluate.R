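#' Expand segment calls to a per-cell state or copy matrix
#'
#' @param calls tibble from [call_cnvs()] (with `all_segments = TRUE` for
#'   full coverage of the matrix).
#' @param truth a `spike_truth` (supplies dimensions and sample ids).
#' @return `calls_to_states()`: character n x m matrix of
#'   "del"/"dup"/"neutral"; `calls_to_copy()`: numeric n x m matrix of
#'   per-cell copy estimates (NA where no segment covers a cell).
#' @keywords internal
calls_to_states <- function(calls, truth) {
  st <- matrix("neutral", truth$n, truth$m)
  j <- match(calls$sample, truth$sample_ids)
  if (anyNA(j)) stop("calls contain samples absent from truth")
  hit <- calls$call != "neutral"
  for (r in which(hit))
    st[calls$exon_lo[r]:calls$exon_hi[r], j[r]] <- calls$call[r]
  st
}

#' @rdname calls_to_states
#' @keywords internal
calls_to_copy <- function(calls, truth) {
  cp <- matrix(NA_real_, truth$n, truth$m)
  j <- match(calls$sample, truth$sample_ids)
  if (anyNA(j)) stop("calls contain samples absent from truth")
  for (r in seq_len(nrow(calls)))
    cp[calls$exon_lo[r]:calls$exon_hi[r], j[r]] <- calls$copy[r]
  cp
}

# effective per-cell truth after referring states to the population average:
# events with p > 0.5 are absorbed into the null, so carriers appear neutral
# and non-carriers appear as the opposite state; carrier cells of such
# events are ambiguous and excluded from the specificity denominator.
effective_truth <- function(truth, mirror_common = TRUE) {
  expect <- matrix("neutral", truth$n, truth$m)
  countable <- matrix(TRUE, truth$n, truth$m)
  state_of <- c(het_del = "del", hom_del = "del", dup = "dup")
  flip <- c(del = "dup", dup = "del")
  ev <- truth$events
  for (e in seq_len(nrow(ev))) {
    exons <- ev$exon_lo[e]:ev$exon_hi[e]
    carriers <- ev$carriers[[e]]
    st <- state_of[[ev$type[e]]]
    if (!mirror_common || ev$p[e] <= 0.5) {
      expect[exons, carriers] <- st
    } else {
      non <- setdiff(seq_len(truth$m), carriers)
      expect[exons, non] <- flip[[st]]
      countable[exons, carriers] <- FALSE
    }
  }
  list(expect = expect, countable = countable)
}

#' Evaluate CNV calls against spike-in truth
#'
#' Computes the exon-by-sample confusion between called and true states.
#' Truth is referred to the population average: for events with frequency
#' above 50% the spiked state becomes the cohort norm, so detection is
#' counted on the mirrored state of the non-carriers (and carrier cells of
#' such events, being ambiguous, are excluded from the specificity
#' denominator). Sensitivity is the fraction of true variant cells called
#' with the correct direction; specificity is the fraction of truth-neutral
#' cells left uncalled.
#'
#' @param calls tibble from [call_cnvs()] or [ratio_calls()] (needs columns
#'   `sample`, `exon_lo`/`exon_hi` or `exon`, `call`).
#' @param truth a `spike_truth` from [spike_in()].
#' @param mirror_common refer truth to the population average (default
#'   TRUE).
#' @return An object of class `cnv_evaluation`: list with `sensitivity`,
#'   `specificity`, `confusion` (tibble), `by_event` and `by_group`
#'   (per-(p, length, type) power table).
#' @export
evaluate_calls <- function(calls, truth, mirror_common = TRUE) {
  stopifnot(inherits(truth, "spike_truth"))
  if (!"exon_lo" %in% names(calls) && "exon" %in% names(calls)) {
    calls$exon_lo <- calls$exon
    calls$exon_hi <- calls$exon
  }
  st <- calls_to_states(calls, truth)
  eff <- effective_truth(truth, mirror_common)
  expect <- eff$expect; countable <- eff$countable

  is_var <- expect != "neutral"
  tp <- sum(is_var & st == expect)
  fn <- sum(is_var & st != expect)
  neg <- !is_var & countable
  tn <- sum(neg & st == "neutral")
  fp <- sum(neg & st != "neutral")

  ev <- truth$events
  by_event <- ev
  by_event$sensitivity <- vapply(seq_len(nrow(ev)), function(e) {
    exons <- ev$exon_lo[e]:ev$exon_hi[e]
    cells_var <- is_var[exons, , drop = FALSE]
    if (!sum(cells_var)) return(NA_real_)
    sum(cells_var & (st == expect)[exons, , drop = FALSE]) / sum(cells_var)
  }, numeric(1))
  by_group <- by_event |>
    dplyr::group_by(.data$p, .data$length, .data$type) |>
    dplyr::summarise(sensitivity = mean(.data$sensitivity, na.rm = TRUE),
                     n_events = dplyr::n(), .groups = "drop")

  structure(
    list(
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
      confusion = tibble::tibble(tp = tp, fn = fn, fp = fp, tn = tn),
      by_event = by_event[, setdiff(names(by_event), "carriers")],
      by_group = by_group
    ),
    class = "cnv_evaluation"
  )
}

#' @export
print.cnv_evaluation <- function(x, ...) {
  cat("<cnv_evaluation> exon-level sensitivity ",
      sprintf("%.3f", x$sensitivity), ", specificity ",
      sprintf("%.4f", x$specificity), "\n", sep = "")
  print(x$by_group)
  invisible(x)
}

#' @describeIn evaluate_calls per-frequency power table.
#' @param x a `cnv_evaluation`. @param ... ignored.
#' @export
tidy.cnv_evaluation <- function(x, ...) x$by_group

#' @describeIn evaluate_calls one-row summary.
#' @export
glance.cnv_evaluation <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sensitivity = x$sensitivity,
                   specificity = x$specificity),
    x$confusion
  )
}

#' Tune the fraction-mode calling threshold to a specificity target
#'
#' Sweeps a symmetric copy-number margin delta (deletion if
#' `copy < 2 - delta`, duplication if `copy > 2 + delta`) over the per-cell
#' copy estimates implied by the segmentation, computing exon-level
#' sensitivity and specificity at each value against the spike-in truth,
#' and returns the loosest margin (smallest delta) whose specificity meets
#' the target. The sweep doubles as an ROC curve.
#'
#' @param calls segment table from `call_cnvs(..., all_segments = TRUE)`.
#' @param truth a `spike_truth`.
#' @param target_specificity required specificity (default 0.99).
#' @param deltas margins to sweep.
#' @param mirror_common see [evaluate_calls()].
#' @return list with `delta`, `del_thr`, `dup_thr`, `sensitivity`,
#'   `specificity` at the chosen margin, and `roc` (tibble over the sweep).
#' @export
tune_threshold <- function(calls, truth, target_specificity = 0.99,
                           deltas = seq(0.05, 1.0, by = 0.05),
                           mirror_common = TRUE) {
  stopifnot(inherits(truth, "spike_truth"))
  cp <- calls_to_copy(calls, truth)
  if (anyNA(cp))
    stop("copy matrix has uncovered cells; call with all_segments = TRUE")
  eff <- effective_truth(truth, mirror_common)
  is_var <- eff$expect != "neutral"
  neg <- !is_var & eff$countable

  rows <- lapply(deltas, function(d) {
    st <- matrix("neutral", truth$n, truth$m)
    st[cp < 2 - d] <- "del"
    st[cp > 2 + d] <- "dup"
    tp <- sum(is_var & st == eff$expect)
    fn <- sum(is_var & st != eff$expect)
    tn <- sum(neg & st == "neutral")
    fp <- sum(neg & st != "neutral")
    tibble::tibble(delta = d,
                   sensitivity = tp / max(tp + fn, 1),
                   specificity = tn / max(tn + fp, 1),
                   tp = tp, fn = fn, fp = fp, tn = tn)
  })
  roc <- dplyr::bind_rows(rows)
  ok <- roc$specificity >= target_specificity
  if (!any(ok))
    stop("no margin in the sweep attains specificity ", target_specificity)
  pick <- roc[which(ok)[1], ]
  list(delta = pick$delta, del_thr = 2 - pick$delta,
       dup_thr = 2 + pick$delta,
       sensitivity = pick$sensitivity, specificity = pick$specificity,
       roc = roc)
}

#' End-to-end spike-in study
#'
#' Simulates a CNV-free cohort, spikes in the given events, fits the null
#' model (latent dimension by BIC over `K_grid` unless `K` is given),
#' segments every sample, tunes the fraction-mode calling margin to the
#' specificity target, and evaluates the tuned calls against truth.
#'
#' @param cfg a [sim_config()] (its seed drives all randomness).
#' @param events events tibble from [spike_events()].
#' @param K fixed latent dimension; if `NULL`, chosen by BIC over `K_grid`.
#' @param K_grid candidate dimensions for selection (default `1:5`).
#' @param target_specificity specificity control level.
#' @param control a [fit_control()].
#' @return list with `evaluation` (a `cnv_evaluation` at the tuned margin),
#'   `threshold` (the [tune_threshold()] result), `fit`, `truth`, `calls`
#'   and `chosen_K`.
#' @export
spike_in_study <- function(cfg, events, K = NULL, K_grid = 1:5,
                           target_specificity = 0.99,
                           control = fit_control()) {
  base <- simulate_null(cfg)
  sp <- spike_in(base, events, seed = cfg$seed + 1L)
  if (is.null(K)) {
    sel <- model_selection(sp$cov, K_grid, control, keep_fits = TRUE)
    K <- sel$chosen$bic
    fit <- sel$fits[[paste0("K", K)]]
  } else {
    fit <- fit_null_model(sp$cov, K, control)
  }
  segs <- call_cnvs(fit, mode = "fraction", all_segments = TRUE)
  thr <- tune_threshold(segs, sp$truth,
                        target_specificity = target_specificity)
  calls <- segs
  calls$call <- dplyr::case_when(
    calls$copy < thr$del_thr ~ "del",
    calls$copy > thr$dup_thr ~ "dup",
    TRUE ~ "neutral")
  evaluation <- evaluate_calls(calls[calls$call != "neutral", ], sp$truth)
  list(evaluation = evaluation, threshold = thr, fit = fit,
       truth = sp$truth, calls = calls, chosen_K = K)
}

#' @describeIn evaluate_calls sensitivity against population frequency.
#' @param object a `cnv_evaluation`.
#' @export
autoplot.cnv_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$by_group,
                  ggplot2::aes(x = .data$p, y = .data$sensitivity,
                               colour = factor(.data$length),
                               linetype = .data$type)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "population frequency p", y = "exon-level sensitivity",
                  colour = "length (exons)", linetype = "event type") +
    ggplot2::theme_minimal()
}
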