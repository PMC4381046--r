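#' Control parameters for the null-model fit
#'
#' @param outer_maxit,outer_tol outer loop (GC spline + exon bias + latent
#'   block) iteration cap and relative log-likelihood convergence tolerance.
#' @param inner_maxit,inner_tol latent alternation (exon-side and sample-side
#'   Poisson regressions) iteration cap and relative Frobenius-norm tolerance
#'   on the change in `g %*% t(h)`.
#' @param floor relative floor applied to ratios wherever divisions by model
#'   terms occur, as a fraction of the positive median.
#' @param damping initial step size in (0, 1], on the log scale, for the
#'   GC-curve and exon-bias updates after the first outer iteration. The
#'   smoothing-spline and row-median steps are robust approximations of the
#'   conditional maximum-likelihood updates, not exact ascent steps, so the
#'   step is halved (backtracking) until the joint move does not lower the
#'   likelihood; the fixed point is unchanged.
#' @return a `fit_control` list.
#' @export
fit_control <- function(outer_maxit = 20, outer_tol = 1e-6,
                        inner_maxit = 10, inner_tol = 1e-4,
                        floor = 1e-6, damping = 1) {
  stopifnot(damping > 0, damping <= 1)
  structure(list(outer_maxit = outer_maxit, outer_tol = outer_tol,
                 inner_maxit = inner_maxit, inner_tol = inner_tol,
                 floor = floor, damping = damping),
            class = "fit_control")
}

# floor a positive quantity at `frac` of its positive median
floor_pos <- function(x, frac = 1e-6) {
  pos <- x[is.finite(x) & x > 0]
  if (!length(pos)) stop("degenerate all-zero ratios")
  pmax(x, frac * stats::median(pos))
}

#' Fit per-sample GC-bias functions
#'
#' For each sample fits a cubic smoothing spline (smoothing parameter by
#' generalized cross-validation) of the ratio `Y / (N * beta * exp(g h'))`
#' against exon GC content, giving the sample-specific multiplicative GC
#' bias. Fitted values are clipped below at a small positive floor; the
#' spline is only ever evaluated within the observed GC range (predictions
#' outside are clamped to the range endpoints).
#'
#' The spline is weighted by the model denominator (the expected-count
#' scale), which makes the least-squares smoothing step the quadratic
#' approximation of the penalized Poisson fit of the GC curve; heavily
#' covered exons, whose ratios are precise, therefore carry more weight.
#'
#' @param Y n x m count matrix. @param N m-vector of sample totals.
#' @param beta n-vector of exon biases. @param GH n x m latent matrix
#'   `g %*% t(h)`. @param gc n-vector of exon GC fractions.
#' @param floor relative flooring fraction.
#' @param spar optional m-vector of fixed smoothing parameters; when `NULL`
#'   each sample's parameter is chosen by generalized cross-validation.
#' @return list with `fitted` (n x m matrix of f_j(GC_i)), `funcs`
#'   (list of m functions gc -> bias, clamped to the observed range) and
#'   `spar` (the smoothing parameters used).
#' @export
fit_gc_functions <- function(Y, N, beta, GH, gc, floor = 1e-6, spar = NULL) {
  n <- nrow(Y); m <- ncol(Y)
  if (length(unique(gc)) < 10) stop("insufficient GC spread")
  fitted <- matrix(NA_real_, n, m)
  funcs <- vector("list", m)
  spar_out <- numeric(m)
  rng <- range(gc)
  for (j in seq_len(m)) {
    denom <- floor_pos(N[j] * beta * exp(GH[, j]), floor)
    ratio <- Y[, j] / denom
    w <- denom / mean(denom)
    sp <- if (is.null(spar)) {
      stats::smooth.spline(gc, ratio, w = w, cv = FALSE)
    } else {
      stats::smooth.spline(gc, ratio, w = w, spar = spar[j])
    }
    spar_out[j] <- sp$spar
    pred <- stats::predict(sp, gc)$y
    pred <- floor_pos(pred, 1e-4)
    fitted[, j] <- pred
    funcs[[j]] <- local({
      sp_j <- sp; rng_j <- rng
      function(x) {
        x <- pmin(pmax(x, rng_j[1]), rng_j[2])
        floor_pos(stats::predict(sp_j, x)$y, 1e-4)
      }
    })
  }
  list(fitted = fitted, funcs = funcs, spar = spar_out)
}

#' Update exon-specific bias
#'
#' `beta_i` is the median over samples of `Y / (N * f(GC) * exp(g h'))`,
#' floored at a small positive value. The median makes the exon bias robust
#' to a minority of samples carrying a CNV at the exon.
#'
#' @inheritParams fit_gc_functions
#' @param fGC n x m matrix of fitted GC biases.
#' @return n-vector of positive exon biases.
#' @export
update_exon_bias <- function(Y, N, fGC, GH, floor = 1e-6) {
  denom <- sweep(fGC * exp(GH), 2, N, `*`)
  ratio <- Y / floor_pos(denom, floor)
  if (any(rowSums(Y) == 0)) stop("exon with zero counts in every sample")
  beta <- apply(ratio, 1, stats::median)
  floor_pos(beta, floor)
}

# fix SVD sign ambiguity: largest-|.| entry of each column of h positive
fix_signs <- function(g, h) {
  for (k in seq_len(ncol(h))) {
    i <- which.max(abs(h[, k]))
    if (h[i, k] < 0) {
      h[, k] <- -h[, k]
      if (!is.null(g)) g[, k] <- -g[, k]
    }
  }
  list(g = g, h = h)
}

#' Initialize sample factors by SVD of the log ratio matrix
#'
#' Applies SVD to the row-centered `log(Y / Z)` (zeros in `Y` replaced by
#' 0.5, a continuity correction) and returns the first `K` right singular
#' vectors as the initial orthonormal sample-factor matrix `h`.
#'
#' @param Y n x m counts. @param Z n x m positive expected-scale matrix
#'   `N * f(GC) * beta`. @param K latent dimension.
#' @return m x K matrix with orthonormal columns.
#' @export
init_latent <- function(Y, Z, K) {
  m <- ncol(Y)
  if (K >= m) stop("K must be smaller than the number of samples")
  Yp <- Y
  Yp[Yp == 0] <- 0.5
  L <- log(Yp / Z)
  L <- L - rowMeans(L)
  sv <- svd(L, nu = 0, nv = K)
  h <- sv$v[, seq_len(K), drop = FALSE]
  fix_signs(NULL, h)$h
}

#' Exon-side and sample-side Poisson regressions
#'
#' `update_g()` fits, for every exon, a Poisson log-linear regression with
#' that exon's counts as response, the sample factors `h` as covariates and
#' `log(Z)` as fixed offset; `update_h()` fits the symmetric per-sample
#' regressions with exon loadings `g` as covariates. Non-convergent rows
#' fall back to zero coefficients with a warning.
#'
#' @param Y n x m counts. @param Z n x m positive offset scale.
#' @param h m x K sample factors. @param g n x K exon loadings.
#' @param g0,h0 optional warm starts.
#' @return updated `g` (n x K) or `h` (m x K).
#' @export
update_g <- function(Y, Z, h, g0 = NULL) {
  n <- nrow(Y); K <- ncol(h)
  if (is.null(g0)) g0 <- matrix(0, n, K)
  res <- batch_poisson_irls(Y, log(Z), h, g0)
  if (!all(res$converged == 1))
    warning(sum(res$converged == 0), " exon regression(s) not converged; ",
            "coefficients set to zero")
  res$G
}

#' @rdname update_g
#' @export
update_h <- function(Y, Z, g, h0 = NULL) {
  m <- ncol(Y); K <- ncol(g)
  if (is.null(h0)) h0 <- matrix(0, m, K)
  res <- batch_poisson_irls(t(Y), t(log(Z)), g, h0)
  if (!all(res$converged == 1))
    warning(sum(res$converged == 0), " sample regression(s) not converged; ",
            "coefficients set to zero")
  res$G
}

# orthonormalize: SVD of the row-centered g h', h <- right vectors,
# g <- U D so that g h' reproduces the centered matrix exactly. The removed
# row means (g %*% colMeans(h), an exon-level log offset) are returned so
# the caller can absorb them into the exon bias; row-centering a rank-K
# matrix is a projection, so the truncated SVD is exact and the step is
# likelihood-preserving.
orthonormalize <- function(g, h) {
  K <- ncol(h)
  M <- g %*% t(h)
  rm_ <- rowMeans(M)
  M <- M - rm_
  sv <- svd(M, nu = K, nv = K)
  g <- sv$u %*% diag(sv$d[seq_len(K)], K, K)
  h <- sv$v
  out <- fix_signs(g, h)
  out$log_offset <- rm_
  out
}

poisson_loglik <- function(Y, lam) sum(stats::dpois(Y, lam, log = TRUE))

poisson_deviance <- function(Y, lam) {
  t1 <- ifelse(Y > 0, Y * log(Y / lam), 0)
  2 * sum(t1 - (Y - lam))
}

#' Fit the Poisson latent-factor null model
#'
#' Models the expected (CNV-free) read count of exon `i` in sample `j` as
#' \deqn{\lambda_{ij} = N_j f_j(GC_i) \beta_i \exp(\sum_k g_{ik} h_{jk})}
#' where `N_j` is the sample's total mapped reads, `f_j` a per-sample smooth
#' GC-bias function, `beta_i` an exon-specific capture/amplification bias
#' and `g, h` latent factors absorbing systemic artifacts. Estimation is by
#' blockwise maximum likelihood: each outer iteration refits the GC splines,
#' updates `beta` by row medians, re-initializes `h` by SVD of the
#' row-centered log ratios, then alternates exon-side and sample-side
#' Poisson regressions (with SVD re-orthonormalization of `h` after every
#' sample-side update, which fixes identifiability) until the latent matrix
#' stabilizes. The outer loop stops when the total Poisson log-likelihood
#' changes by less than `control$outer_tol` in relative terms.
#'
#' The algorithm is deterministic given the data (SVD signs are fixed by
#' making the largest-magnitude entry of each singular vector positive).
#'
#' @param cov a QC-filtered [coverage_matrix()] with `gc` populated.
#' @param K latent dimension, `0 <= K < min(n, m)`; `K = 0` fits only the
#'   GC and exon-bias terms.
#' @param control a [fit_control()].
#' @return An object of class `null_model_fit`: list with `beta`, `gc_funcs`
#'   (per-sample functions), `fGC` (fitted GC bias matrix), `g`, `h`, `K`,
#'   `lam` (the control coverage), `loglik`, `deviance`, `converged`,
#'   `trace` (per-outer-iteration log-likelihood tibble), plus the inputs
#'   needed downstream (`targets`, `sample_ids`, `N`, `Y`).
#' @references The model and fitting algorithm follow the multi-sample
#'   Poisson latent-factor normalization approach for whole-exome read
#'   depth.
#' @export
fit_null_model <- function(cov, K, control = fit_control()) {
  stopifnot(inherits(cov, "coverage_matrix"))
  Y <- cov$Y; N <- cov$N
  n <- nrow(Y); m <- ncol(Y)
  if (K < 0 || K >= min(n, m)) stop("need 0 <= K < min(n, m)")
  gc <- cov$targets$gc
  if (anyNA(gc)) stop("targets have unset gc; run compute_gc() first")

  beta <- rep(1, n)
  g <- matrix(0, n, K); h <- matrix(0, m, K)
  GH <- matrix(0, n, m)
  spar <- NULL
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  gc_fit <- NULL

  for (iter in seq_len(control$outer_maxit)) {
    # GCV selects each sample's smoothing parameter at the first outer
    # iteration; later refits reuse it, so the spline's flexibility does not
    # drift across iterations
    gc_fit <- fit_gc_functions(Y, N, beta, GH, gc, control$floor, spar)
    if (is.null(spar)) spar <- gc_fit$spar
    f_star <- gc_fit$fitted
    if (iter == 1) {
      fGC <- f_star
      beta <- update_exon_bias(Y, N, fGC, GH, control$floor)
    } else {
      # the spline and median proposals are robust steps, not exact ascent
      # steps; take them with backtracking on the log scale so the joint
      # f/beta move never lowers the likelihood (the fixed point is
      # unchanged: at convergence the proposals equal the current values)
      beta_star <- update_exon_bias(Y, N, f_star, GH, control$floor)
      ll_ref <- poisson_loglik(Y, sweep(fGC * beta, 2, N, `*`) * exp(GH))
      gamma <- control$damping
      while (gamma >= 1 / 256) {
        f_try <- fGC * (f_star / fGC)^gamma
        b_try <- beta * (beta_star / beta)^gamma
        ll_try <- poisson_loglik(Y, sweep(f_try * b_try, 2, N, `*`) * exp(GH))
        if (ll_try >= ll_ref - 1e-9 * abs(ll_ref)) {
          fGC <- f_try; beta <- b_try
          break
        }
        gamma <- gamma / 2
      }
    }
    gc_fit$fitted <- fGC
    Z <- sweep(fGC * beta, 2, N, `*`)

    if (K > 0) {
      if (iter == 1) {
        # SVD of the row-centered log ratios seeds the factors; later outer
        # iterations warm-start from the current (g, h)
        h <- init_latent(Y, Z, K)
        g <- matrix(0, n, K)
      }
      GH_inner <- GH
      for (it in seq_len(control$inner_maxit)) {
        g <- update_g(Y, Z, h, g)
        h <- update_h(Y, Z, g, h)
        oo <- orthonormalize(g, h)
        g <- oo$g; h <- oo$h
        # push the centered-out exon-level log offset into the fixed part
        # so the reparameterization leaves every lambda unchanged
        Z <- Z * exp(oo$log_offset)
        beta <- beta * exp(oo$log_offset)
        GH_new <- g %*% t(h)
        delta <- sqrt(sum((GH_new - GH_inner)^2)) /
          max(sqrt(sum(GH_inner^2)), 1e-12)
        GH_inner <- GH_new
        if (delta < control$inner_tol) break
      }
      GH <- GH_inner
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
  ll <- poisson_loglik(Y, lam)
  structure(
    list(beta = beta, gc_funcs = gc_fit$funcs, fGC = gc_fit$fitted,
         g = g, h = h, K = K, lam = lam,
         loglik = ll, deviance = poisson_deviance(Y, lam),
         converged = converged,
         trace = tibble::tibble(iter = seq_along(trace), loglik = trace),
         targets = cov$targets, sample_ids = cov$sample_ids,
         N = N, Y = Y),
    class = "null_model_fit"
  )
}

#' @export
print.null_model_fit <- function(x, ...) {
  cat("<null_model_fit> K = ", x$K, ", ", nrow(x$Y), " exons x ",
      ncol(x$Y), " samples\n", sep = "")
  cat("  log-likelihood: ", format(x$loglik), "; converged: ",
      x$converged, "\n", sep = "")
  invisible(x)
}
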