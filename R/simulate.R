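#' Configuration for the synthetic exome-coverage generator
#'
#' Describes a cohort drawn from the null model itself: per-exon GC content
#' uniform on `gc_range`, log-normal exon capture biases, per-sample totals
#' `N_j`, per-sample smooth GC-bias curves (unimodal bumps, a fraction of
#' samples bimodal, so that the curves differ in shape and not just scale),
#' and `K_true` orthonormal latent factors whose combined exponent has
#' standard deviation `latent_sd`. Counts are Poisson around the resulting
#' rate. The defaults emulate a modern exome cohort: ~100x mean target
#' depth, tens-of-millions read totals, GC between 20% and 80% (the
#' post-QC range).
#'
#' @param n,m number of exons and samples.
#' @param K_true number of latent factors (0 for none).
#' @param seed integer seed; the generator is fully reproducible.
#' @param gc_range range of simulated GC fractions.
#' @param beta_sdlog log-sd of the log-normal exon bias.
#' @param N_range range of per-sample genome-wide read totals.
#' @param depth_range range of per-sample mean target depth.
#' @param latent_sd standard deviation of the latent log-rate term
#'   `(g h')_{ij}`.
#' @param bimodal_frac fraction of samples given a bimodal GC curve.
#' @param flat_gc if `TRUE`, GC bias is flat (f = 1 up to scale).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n = 2000, m = 90, K_true = 3, seed = 1,
                       gc_range = c(0.2, 0.8), beta_sdlog = 0.5,
                       N_range = c(2e7, 4e7), depth_range = c(80, 120),
                       latent_sd = 0.2, bimodal_frac = 0.2,
                       flat_gc = FALSE) {
  stopifnot(n >= 2, m >= 2, K_true >= 0, K_true < m,
            gc_range[1] < gc_range[2])
  structure(
    list(n = n, m = m, K_true = K_true, seed = as.integer(seed),
         gc_range = gc_range, beta_sdlog = beta_sdlog, N_range = N_range,
         depth_range = depth_range, latent_sd = latent_sd,
         bimodal_frac = bimodal_frac, flat_gc = flat_gc),
    class = "sim_config"
  )
}

gc_bump <- function(gc, peak, width) exp(-(gc - peak)^2 / (2 * width^2))

#' Simulate CNV-free exome coverage from the null model
#'
#' Draws `Y_ij ~ Poisson(N_j f_j(GC_i) beta_i exp(sum_k g_ik h_jk))` with
#' every generating parameter stored for recovery tests. Targets are laid
#' out as consecutive 150 bp exons spaced 3 kb apart on a single synthetic
#' chromosome with mappability 1.
#'
#' @param cfg a [sim_config()].
#' @return a [coverage_matrix()] with the generating parameters attached as
#'   `attr(, "params")` (list: `gc`, `beta`, `fGC`, `g`, `h`, `GH`, `lam`,
#'   `depth`).
#' @export
simulate_null <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n; m <- cfg$m; K <- cfg$K_true

  gc <- runif(n, cfg$gc_range[1], cfg$gc_range[2])
  beta <- exp(rnorm(n, 0, cfg$beta_sdlog))
  N <- runif(m, cfg$N_range[1], cfg$N_range[2])
  depth <- runif(m, cfg$depth_range[1], cfg$depth_range[2])

  # per-sample GC curves: unimodal bump, some samples bimodal
  shape <- matrix(1, n, m)
  if (!cfg$flat_gc) {
    for (j in seq_len(m)) {
      peak <- runif(1, 0.38, 0.55)
      width <- runif(1, 0.18, 0.30)
      s <- gc_bump(gc, peak, width)
      if (runif(1) < cfg$bimodal_frac) {
        s <- s + runif(1, 0.4, 0.8) *
          gc_bump(gc, runif(1, 0.6, 0.72), runif(1, 0.06, 0.12))
      }
      shape[, j] <- s
    }
  }

  if (K > 0) {
    h <- qr.Q(qr(matrix(rnorm(m * K), m, K)))
    g <- matrix(rnorm(n * K, 0, cfg$latent_sd * sqrt(m / K)), n, K)
    GH <- g %*% t(h)
  } else {
    g <- matrix(0, n, 0); h <- matrix(0, m, 0); GH <- matrix(0, n, m)
  }

  # scale f_j so that mean target depth matches the drawn per-sample depth
  fGC <- shape
  for (j in seq_len(m)) {
    raw <- N[j] * shape[, j] * beta * exp(GH[, j])
    fGC[, j] <- shape[, j] * depth[j] * n / sum(raw)
  }
  lam <- sweep(fGC * beta, 2, N, `*`) * exp(GH)

  Y <- matrix(rpois(n * m, lam), n, m)
  start <- seq(0L, by = 3000L, length.out = n)
  targets <- tibble::tibble(
    chrom = "chrS", start = start, end = start + 150L,
    length = 150L, gc = gc, mappability = 1.0
  )
  cov <- coverage_matrix(Y, targets, sprintf("S%03d", seq_len(m)), N)
  attr(cov, "params") <- list(gc = gc, beta = beta, fGC = fGC, g = g, h = h,
                              GH = GH, lam = lam, depth = depth, N = N)
  cov
}

#' Lay out spike-in events along the exome
#'
#' Events are centered at every `stride`-th exon; each event takes its
#' length / type / population frequency from the recycled argument vectors,
#' so a single cohort can carry the full frequency grid.
#'
#' @param n number of exons in the cohort.
#' @param p population frequency (or vector, recycled over events).
#' @param length event length in exons (vector recycled).
#' @param type `"het_del"`, `"hom_del"` or `"dup"` (vector recycled).
#' @param stride spacing of event centers in exons (default 100).
#' @return tibble: `event`, `center`, `exon_lo`, `exon_hi`, `length`,
#'   `type`, `p`.
#' @export
spike_events <- function(n, p, length = 5, type = "het_del", stride = 100) {
  centers <- seq(stride, n, by = stride)
  k <- length(centers)
  ev <- tibble::tibble(
    event = seq_len(k),
    center = centers,
    length = rep_len(as.integer(length), k),
    type = rep_len(type, k),
    p = rep_len(p, k)
  )
  ev$exon_lo <- ev$center - (ev$length - 1L) %/% 2L
  ev$exon_hi <- ev$exon_lo + ev$length - 1L
  keep <- ev$exon_lo >= 1 & ev$exon_hi <= n
  ev <- ev[keep, ]
  if (!nrow(ev)) stop("no event fits inside the target list")
  ev$event <- seq_len(nrow(ev))
  ev[, c("event", "center", "exon_lo", "exon_hi", "length", "type", "p")]
}

#' Spike CNV signals into copy-number-neutral coverage
#'
#' For each event, `round(m * p)` carrier samples are drawn at random (or
#' taken from an explicit `carriers` list-column) and their raw counts over
#' the spanned exons are scaled: heterozygous deletions multiply by `c / 2`,
#' duplications (one extra copy) by `3c / 2`, homozygous deletions set the
#' count to zero, with `c ~ Normal(1, carrier_sd)` truncated at zero drawn
#' fresh per carrier-event and the result rounded to an integer count.
#'
#' @param cov a [coverage_matrix()] of copy-neutral coverage (events are
#'   placed by construction, so input exons are copy-neutral by design).
#' @param events tibble from [spike_events()], optionally with a `carriers`
#'   list-column of sample indices.
#' @param carrier_sd standard deviation of the carrier scaling factor `c`.
#' @param seed optional seed for carrier choice and `c` draws.
#' @return list with `cov` (the spiked matrix) and `truth` (class
#'   `spike_truth`: the events with carriers, plus the per-cell true copy
#'   matrix, 2 = neutral).
#' @export
spike_in <- function(cov, events, carrier_sd = 0.1, seed = NULL) {
  stopifnot(inherits(cov, "coverage_matrix"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cov$Y); m <- ncol(cov$Y)
  ev <- events
  if (any(ev$p <= 0) || any(ev$p >= 1)) stop("need 0 < p < 1")
  o <- order(ev$exon_lo)
  if (any(ev$exon_hi[o][-nrow(ev)] >= ev$exon_lo[o][-1]))
    stop("overlapping spike-in events")

  copy_of <- c(het_del = 1, hom_del = 0, dup = 3)
  if (!all(ev$type %in% names(copy_of))) stop("unknown event type")

  Y <- cov$Y
  truth_copy <- matrix(2, n, m)
  if (!"carriers" %in% names(ev)) {
    ev$carriers <- lapply(ev$p, function(p) sort(sample.int(m, round(m * p))))
  }
  for (e in seq_len(nrow(ev))) {
    exons <- ev$exon_lo[e]:ev$exon_hi[e]
    for (s in ev$carriers[[e]]) {
      cc <- max(rnorm(1, 1, carrier_sd), 0)
      fac <- switch(ev$type[e],
                    het_del = cc / 2, hom_del = 0, dup = 3 * cc / 2)
      Y[exons, s] <- round(fac * Y[exons, s])
      truth_copy[exons, s] <- copy_of[[ev$type[e]]]
    }
  }
  cov2 <- coverage_matrix(Y, cov$targets, cov$sample_ids, cov$N)
  attr(cov2, "params") <- attr(cov, "params")
  truth <- structure(
    list(events = ev, copy = truth_copy, n = n, m = m,
         sample_ids = cov$sample_ids),
    class = "spike_truth"
  )
  list(cov = cov2, truth = truth)
}

#' Mirror a spiked truth into the complementary cohort
#'
#' Returns the event table whose carriers are the complement of the input's,
#' with deletions swapped for duplications and `p` for `1 - p`. Spiking
#' these events into the same base cohort gives the mirrored simulation used
#' to check the deletion-at-p vs duplication-at-(1-p) duality.
#'
#' @param truth a `spike_truth`.
#' @return events tibble suitable for [spike_in()].
#' @export
mirror_events <- function(truth) {
  stopifnot(inherits(truth, "spike_truth"))
  ev <- truth$events
  flip <- c(het_del = "dup", dup = "het_del")
  if (!all(ev$type %in% names(flip)))
    stop("only het_del/dup events can be mirrored")
  ev$type <- unname(flip[ev$type])
  ev$carriers <- lapply(ev$carriers, function(cs) setdiff(seq_len(truth$m), cs))
  ev$p <- 1 - ev$p
  ev
}
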