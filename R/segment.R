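#' Poisson generalized-likelihood-ratio scan statistic
#'
#' For a window with observed count sum `y_st` and expected (control) sum
#' `lam_st`, the statistic is the log generalized likelihood ratio of
#' `y_st ~ Poisson(mu)` with free `mu` against the null `mu = lam_st`:
#' \deqn{U = y_{s:t} \log(y_{s:t}/\lambda_{s:t}) - (y_{s:t} - \lambda_{s:t})}
#' with the `y_st = 0` limit defined as `lam_st` (0 log 0 := 0). `U >= 0`,
#' with equality iff `y_st = lam_st`, and for fixed `lam_st` it decreases on
#' `[0, lam_st]` and increases on `[lam_st, Inf)`. Vectorized.
#'
#' @param y_st non-negative observed count sum(s).
#' @param lam_st positive expected count sum(s).
#' @return the statistic, same length as the inputs.
#' @export
scan_stat <- function(y_st, lam_st) {
  if (any(lam_st <= 0)) stop("lam_st must be positive")
  if (any(y_st < 0)) stop("y_st must be non-negative")
  ifelse(y_st == 0, lam_st, y_st * log(y_st / lam_st) - (y_st - lam_st))
}

# best split of the stretch lo..hi by the change in mBIC it would produce.
#
# The candidate window [s, t] contributes (i) a likelihood gain
# U(window) + U(left flank) + U(right flank) - U(stretch), where U(left
# flank) depends only on s and U(right flank) only on t, and (ii) a penalty
# change from the mBIC spacing and (1/2 - P) log(n) terms, which is likewise
# separable apart from a log(t - s + 1) matrix. Steering the recursion by
# the penalized gain rather than the bare window statistic keeps the greedy
# search aligned with the mBIC objective: the bare statistic always prefers
# cutting two change points where one suffices, and is maximized by the
# whole stretch itself when the segment is uniformly shifted. The spacing
# term also makes a change point at position 1 impossible (its tau spacing
# is zero under the tau_0 = 1 boundary convention); that shows up here as a
# -Inf penalty, so such windows are never proposed.
#
# a, b are the neighbouring change points in the tau convention (a = 1 for
# the first segment, lo - 1 otherwise; b = n for the last, hi otherwise).
# Ties break toward the smallest s, then the smallest t. Returns NULL when
# the stretch cannot be split.
best_window <- function(cy, cl, lo, hi, a, b, n) {
  if (hi - lo + 1 < 2) return(NULL)
  res <- best_window_cpp(cy, cl, lo, hi, a, b, n)
  if (res[1] < 0 || !is.finite(res[4])) return(NULL)
  list(s = as.integer(res[1]), t = as.integer(res[2]),
       U = res[3], delta = res[4])
}

#' Modified BIC for a Poisson change-point model
#'
#' Scores a segmentation of `y` (with expected values `lam`) having change
#' points `tau`:
#' \deqn{mBIC(P) = \log(L_\tau/L_0) - \tfrac12 \sum_{\rho=0}^{P}
#'   \log(\hat\tau_{\rho+1} - \hat\tau_\rho) + (\tfrac12 - P)\log(n)}
#' where the likelihood ratio uses the per-segment Poisson MLE (the segment
#' count sum) against the no-change null, and the boundary convention is
#' \eqn{1 = \tau_0 < \tau_1 < \dots < \tau_P < \tau_{P+1} = n}. Interior
#' change points are supplied as the index of the last exon of each segment.
#' Under this convention a change point immediately after the first exon
#' gives a zero spacing and `mBIC = -Inf`; such models are never selected.
#'
#' @param y per-exon counts. @param lam matching positive expected counts.
#' @param tau integer vector of interior change points (possibly empty),
#'   strictly increasing, within `1 .. n-1`.
#' @return the mBIC score (to be maximized over `P`).
#' @export
mbic <- function(y, lam, tau) {
  n <- length(y)
  stopifnot(length(lam) == n, all(lam > 0))
  tau <- as.integer(tau)
  if (length(tau)) {
    if (is.unsorted(tau, strictly = TRUE) || any(tau < 1) || any(tau > n - 1))
      stop("invalid change points")
  }
  bounds <- c(0L, tau, n)
  if (any(diff(bounds) < 1)) stop("segment of length 0")
  P <- length(tau)
  seg <- findInterval(seq_len(n) - 1L, bounds, left.open = FALSE)
  # log L_tau / L_0 = sum over segments of U(segment)
  ysum <- tapply(y, seg, sum)
  lsum <- tapply(lam, seg, sum)
  llr <- sum(scan_stat(as.numeric(ysum), as.numeric(lsum)))
  # spacing term with the printed boundary convention tau_0 = 1, tau_{P+1} = n
  tau_full <- c(1L, tau, n)
  gaps <- diff(tau_full)
  if (any(gaps <= 0)) return(-Inf)
  llr - 0.5 * sum(log(gaps)) + (0.5 - P) * log(n)
}

#' Circular binary segmentation with mBIC model choice
#'
#' Recursively splits one sample's per-chromosome exon counts: at each step,
#' within every current segment the candidate window whose excision would
#' most increase the mBIC score - the split's likelihood gain in scan
#' statistics [scan_stat()] plus the change in the mBIC spacing and
#' change-point-count penalties - is found, and the best split over all
#' segments is applied (ties broken toward the leftmost start, then the
#' shortest window). This produces a nested sequence of candidate
#' change-point models; every candidate is rescored by [mbic()] and the
#' argmax returned. Steering the recursion by the penalized gain rather
#' than the bare window statistic keeps the greedy search aligned with the
#' selection objective: the bare statistic is maximized by the whole
#' segment itself when the segment is uniformly shifted (proposing no
#' split), and always prefers cutting two change points where one
#' suffices. Every candidate is scored
#' by [mbic()] and the argmax-mBIC model is returned. Splitting stops when
#' no window improves the likelihood, when `max_changepoints` is reached, or
#' when `patience` successive candidates have failed to improve the best
#' mBIC seen.
#'
#' @param y per-exon counts for one sample on one chromosome.
#' @param lam matching positive expected (control) coverage.
#' @param max_changepoints cap on `P` (default `length(y) - 1`).
#' @param patience early-stop horizon on non-improving candidates.
#' @return An object of class `changepoint_model`: list with `P`, `tau`
#'   (interior change points, last-exon-of-segment indices), `mbic`,
#'   `segments` (tibble: s, t, n_exons, y_sum, lam_sum, U, fold, copy) and
#'   `candidates` (tibble of the scored nested sequence).
#' @export
cbs_segment <- function(y, lam, max_changepoints = NULL, patience = 10L) {
  n <- length(y)
  if (n < 1) stop("empty input")
  stopifnot(length(lam) == n, all(lam > 0), all(y >= 0))
  if (is.null(max_changepoints)) max_changepoints <- n - 1L

  cy <- c(0, cumsum(y))
  cl <- c(0, cumsum(lam))

  # the best split of a segment depends only on (lo, hi), so splits of
  # untouched segments are cached across iterations
  split_of <- function(lo, hi) {
    a_nb <- if (lo == 1L) 1L else lo - 1L
    b_nb <- if (hi == n) n else hi
    w <- best_window(cy, cl, lo, hi, a_nb, b_nb, n)
    if (is.null(w)) return(NULL)
    w$new_cp <- c(if (w$s > lo) w$s - 1L, if (w$t < hi) w$t)
    if (length(w$new_cp) == 0) return(NULL)
    w
  }

  tau <- integer(0)
  cand_tau <- list(integer(0))
  # current segments with their cached best splits
  segs <- list(list(lo = 1L, hi = n, w = split_of(1L, n)))
  repeat {
    if (length(tau) >= max_changepoints) break
    best <- NULL; at <- NA_integer_
    for (b in seq_along(segs)) {
      w <- segs[[b]]$w
      if (is.null(w)) next
      if (is.null(best) || w$delta > best$delta ||
          (w$delta == best$delta && w$s < best$s)) { best <- w; at <- b }
    }
    if (is.null(best)) break
    tau <- sort(unique(c(tau, best$new_cp)))
    cand_tau[[length(cand_tau) + 1]] <- tau

    # replace the split segment by its (up to three) pieces; every other
    # cached split stays valid
    seg <- segs[[at]]
    cuts <- sort(unique(c(seg$lo - 1L, best$new_cp, seg$hi)))
    pieces <- lapply(seq_len(length(cuts) - 1L), function(q) {
      lo <- cuts[q] + 1L; hi <- cuts[q + 1L]
      list(lo = lo, hi = hi, w = split_of(lo, hi))
    })
    segs <- c(segs[seq_len(at - 1L)], pieces,
              segs[seq_len(length(segs) - at) + at])

    # stop once mBIC has been flat for `patience` extra candidates, or as
    # soon as the best available split no longer improves it
    scores <- vapply(cand_tau, function(tt) mbic(y, lam, tt), numeric(1))
    if (best$delta <= 1e-12 && which.max(scores) < length(scores)) break
    if (which.max(scores) <= length(scores) - patience) break
  }

  scores <- vapply(cand_tau, function(tt) mbic(y, lam, tt), numeric(1))
  pick <- which.max(scores)
  tau_hat <- cand_tau[[pick]]

  bounds <- c(0L, tau_hat, n)
  seg <- tibble::tibble(
    s = head(bounds, -1) + 1L,
    t = tail(bounds, -1)
  )
  seg$n_exons <- seg$t - seg$s + 1L
  seg$y_sum <- cy[seg$t + 1] - cy[seg$s]
  seg$lam_sum <- cl[seg$t + 1] - cl[seg$s]
  seg$U <- scan_stat(seg$y_sum, seg$lam_sum)
  seg$fold <- seg$y_sum / seg$lam_sum
  seg$copy <- 2 * seg$fold

  structure(
    list(P = length(tau_hat), tau = tau_hat, mbic = scores[pick],
         segments = seg,
         candidates = tibble::tibble(
           P = vapply(cand_tau, length, integer(1)), mbic = scores)),
    class = "changepoint_model"
  )
}

#' @export
print.changepoint_model <- function(x, ...) {
  cat("<changepoint_model> P =", x$P, "change points, mBIC =",
      format(x$mbic), "\n")
  print(x$segments)
  invisible(x)
}

#' @describeIn cbs_segment the per-segment table.
#' @param x a `changepoint_model`. @param ... ignored.
#' @export
tidy.changepoint_model <- function(x, ...) x$segments
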