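#' Choose the number of latent factors
#'
#' Fits the null model over a grid of latent dimensions and scores each fit
#' with \eqn{AIC = 2\ln(L) - 2k} and \eqn{BIC = 2\ln(L) - k\ln(n_{obs})}
#' (both to be maximized), where `L` is the Poisson likelihood of the fit,
#' `k = K (n + m)` counts the parameters added per unit of latent dimension
#' and `n_obs = n * m` is the number of observed counts. The percentage of
#' variance explained is the share of the K = 0 model's Poisson deviance
#' removed by the latent factors. BIC is the default criterion: a smaller K
#' gives a more conservative normalization, and signals removed during
#' normalization cannot be recovered downstream, whereas false positives can
#' still be screened after segmentation.
#'
#' @param cov a QC-filtered [coverage_matrix()] with `gc` populated.
#' @param K_grid candidate latent dimensions (default `1:9`, capped at
#'   `m - 1`).
#' @param control a [fit_control()].
#' @param keep_fits keep the fitted models in the result (memory permitting).
#' @return An object of class `k_selection`: list with `metrics` (tibble:
#'   K, loglik, aic, bic, pve, converged), `chosen` (named list with the
#'   argmax-K under each criterion), `default` ("bic"), and optionally
#'   `fits`. `tidy()` returns the metrics tibble.
#' @export
model_selection <- function(cov, K_grid = NULL, control = fit_control(),
                            keep_fits = TRUE) {
  stopifnot(inherits(cov, "coverage_matrix"))
  n <- nrow(cov$Y); m <- ncol(cov$Y)
  if (is.null(K_grid)) K_grid <- seq_len(min(9, m - 1))
  K_grid <- sort(unique(as.integer(K_grid)))
  if (any(K_grid < 1) || any(K_grid >= min(n, m)))
    stop("K_grid must lie within 1 .. min(n, m) - 1")

  fit0 <- fit_null_model(cov, 0, control)
  dev0 <- fit0$deviance
  n_obs <- n * m

  fits <- vector("list", length(K_grid))
  rows <- vector("list", length(K_grid))
  for (i in seq_along(K_grid)) {
    K <- K_grid[i]
    fit <- fit_null_model(cov, K, control)
    k_params <- K * (n + m)
    rows[[i]] <- tibble::tibble(
      K = K, loglik = fit$loglik,
      aic = 2 * fit$loglik - 2 * k_params,
      bic = 2 * fit$loglik - k_params * log(n_obs),
      pve = 100 * (1 - fit$deviance / dev0),
      converged = fit$converged
    )
    fits[[i]] <- fit
  }
  metrics <- dplyr::bind_rows(rows)
  # ties broken toward the smaller K, which also guarantees
  # chosen_K(AIC) >= chosen_K(BIC) since BIC penalizes each K more
  chosen <- list(
    aic = metrics$K[which.max(metrics$aic)],
    bic = metrics$K[which.max(metrics$bic)],
    pve = metrics$K[which.max(metrics$pve)]
  )
  structure(
    list(metrics = metrics, chosen = chosen, default = "bic",
         chosen_K = chosen$bic,
         fits = if (keep_fits) stats::setNames(fits, paste0("K", K_grid))),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat("<k_selection> default criterion: BIC -> K =", x$chosen$bic, "\n")
  cat("  AIC -> K =", x$chosen$aic, "; %deviance explained curve over",
      nrow(x$metrics), "candidates\n")
  print(x$metrics)
  invisible(x)
}

#' @describeIn model_selection per-K metrics as a tibble.
#' @param x a `k_selection`. @param ... ignored.
#' @export
tidy.k_selection <- function(x, ...) x$metrics

#' @describeIn model_selection one-row summary of the default choice.
#' @export
glance.k_selection <- function(x, ...) {
  best <- x$metrics[x$metrics$K == x$chosen$bic, ]
  tibble::tibble(chosen_K = x$chosen$bic, criterion = "bic",
                 loglik = best$loglik, bic = best$bic, aic = best$aic,
                 pve = best$pve)
}

#' @describeIn model_selection AIC/BIC/%variance curves against K.
#' @param object a `k_selection`.
#' @export
autoplot.k_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(object$metrics, c("aic", "bic", "pve"),
                            names_to = "criterion", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$chosen$bic, linetype = 2) +
    ggplot2::facet_wrap(~criterion, scales = "free_y") +
    ggplot2::labs(x = "number of latent factors K", y = NULL,
                  title = "Latent-dimension selection (dashed: BIC choice)") +
    ggplot2::theme_minimal()
}
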