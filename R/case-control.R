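#' Fit the null model in case-control mode
#'
#' When recurrent large aberrations are expected in the case cohort (e.g.
#' tumors), a pooled fit would absorb them into the latent factors and the
#' exon bias, deflating the signal. Here the exon-side parameters are
#' estimated from the control cohort only: a full fit on the controls fixes
#' the exon bias `beta` and the exon loadings `g`, and each case sample then
#' receives its sample-side terms - the GC-bias function `f_j` and the
#' factor coefficients `h_j` - by per-sample smoothing-spline and Poisson
#' regression steps on its own counts. Case aberrations therefore cannot
#' leak into the exon-side null.
#'
#' @param cases,controls [coverage_matrix()] objects on the identical
#'   QC-filtered target set.
#' @param K latent dimension for the control fit.
#' @param frozen which exon-side parameters to take from the control fit:
#'   `"exon"` (default) freezes both `beta` and `g`; `"latent"` freezes only
#'   the latent exon loadings `g` and re-estimates `beta` from the case
#'   cohort medians (appropriate when capture efficiency differs between
#'   cohorts but case CNVs are rare).
#' @param control a [fit_control()].
#' @param control_fit optionally, a pre-computed `null_model_fit` on
#'   `controls` (skips refitting).
#' @return a `null_model_fit` for the case samples (with `control_fit`
#'   attached as an attribute).
#' @export
fit_case_control <- function(cases, controls, K,
                             frozen = c("exon", "latent"),
                             control = fit_control(),
                             control_fit = NULL) {
  stopifnot(inherits(cases, "coverage_matrix"),
            inherits(controls, "coverage_matrix"))
  frozen <- match.arg(frozen)
  if (ncol(cases$Y) == 0) stop("zero case samples")
  same <- identical(cases$targets[, c("chrom", "start", "end")],
                    controls$targets[, c("chrom", "start", "end")])
  if (!same) stop("case and control cohorts must share the same target set")

  if (is.null(control_fit)) control_fit <- fit_null_model(controls, K, control)
  stopifnot(inherits(control_fit, "null_model_fit"))

  Y <- cases$Y; N <- cases$N
  n <- nrow(Y); m <- ncol(Y)
  gc <- cases$targets$gc
  g <- control_fit$g
  beta <- control_fit$beta
  h <- matrix(0, m, K)
  GH <- matrix(0, n, m)
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  gc_fit <- NULL

  spar <- NULL
  for (iter in seq_len(control$outer_maxit)) {
    gc_fit <- fit_gc_functions(Y, N, beta, GH, gc, control$floor, spar)
    if (is.null(spar)) spar <- gc_fit$spar
    fGC <- gc_fit$fitted
    if (frozen == "latent")
      beta <- update_exon_bias(Y, N, fGC, GH, control$floor)
    Z <- sweep(fGC * beta, 2, N, `*`)
    if (K > 0) {
      h <- update_h(Y, Z, g, h)
      GH <- g %*% t(h)
    }
    lam <- Z * exp(GH)
    ll <- poisson_loglik(Y, lam)
    trace <- c(trace, ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < control$outer_tol * abs(ll_old)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
  }

  lam <- sweep(gc_fit$fitted * beta, 2, N, `*`) * exp(GH)
  out <- structure(
    list(beta = beta, gc_funcs = gc_fit$funcs, fGC = gc_fit$fitted,
         g = g, h = h, K = K, lam = lam,
         loglik = poisson_loglik(Y, lam),
         deviance = poisson_deviance(Y, lam),
         converged = converged,
         trace = tibble::tibble(iter = seq_along(trace), loglik = trace),
         targets = cases$targets, sample_ids = cases$sample_ids,
         N = N, Y = Y),
    class = "null_model_fit"
  )
  attr(out, "control_fit") <- control_fit
  attr(out, "mode") <- paste0("case-control/", frozen)
  out
}
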