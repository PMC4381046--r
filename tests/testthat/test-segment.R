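# ---- independent oracles -------------------------------------------------

# brute-force: score every one of the 2^(n-1) change-point placements with
# an independently written mBIC and return the global maximum
oracle_best_model <- function(y, lam) {
  n <- length(y)
  score_one <- function(tau) {
    bounds <- c(0, tau, n)
    llr <- 0
    for (b in seq_len(length(bounds) - 1)) {
      i <- (bounds[b] + 1):bounds[b + 1]
      ys <- sum(y[i]); ls <- sum(lam[i])
      llr <- llr + (if (ys > 0) ys * log(ys / ls) else 0) - (ys - ls)
    }
    gaps <- diff(c(1, tau, n))
    if (any(gaps <= 0)) return(-Inf)
    llr - 0.5 * sum(log(gaps)) + (0.5 - length(tau)) * log(n)
  }
  best <- list(tau = integer(0), score = score_one(integer(0)))
  for (mask in seq_len(2^(n - 1) - 1)) {
    tau <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 2))) != 0L)
    s <- score_one(tau)
    if (s > best$score) best <- list(tau = tau, score = s)
  }
  best
}

# ---- scan statistic closed forms ----------------------------------------

test_that("the scan statistic matches its closed form", {
  expect_equal(scan_stat(10, 10), 0)
  expect_equal(scan_stat(20, 10), 20 * log(2) - 10)
  expect_equal(scan_stat(0, 7), 7)
  expect_error(scan_stat(5, 0), "positive")
  expect_error(scan_stat(-1, 5), "non-negative")
})

test_that("the scan statistic is scale-equivariant and U-shaped", {
  y <- c(3, 17, 40); lam <- c(10, 10, 25)
  for (k in c(2, 5, 11)) {
    expect_equal(scan_stat(k * y, k * lam), k * scan_stat(y, lam))
  }
  # strictly decreasing below lam, increasing above
  lam0 <- 30
  lo <- scan_stat(seq(0, lam0, by = 1), lam0)
  hi <- scan_stat(seq(lam0, 3 * lam0, by = 1), lam0)
  expect_true(all(diff(lo) < 0))
  expect_true(all(diff(hi) > 0))
  expect_true(all(c(lo, hi) >= 0))
})

# ---- mBIC ----------------------------------------------------------------

test_that("mBIC matches direct evaluation of its formula", {
  y <- rep(10, 10); lam <- rep(10, 10)
  expect_equal(mbic(y, lam, integer(0)), -0.5 * log(9) + 0.5 * log(10))
  # pure function of (y, lam, tau): independent of external labels
  expect_equal(mbic(y, lam, 4L), mbic(y, lam, 4L))
  expect_error(mbic(y, lam, c(4L, 4L)), "invalid change points")
  expect_error(mbic(y, lam, 11L), "invalid change points")
})

test_that("splitting a homogeneous stretch lowers mBIC for large n", {
  set.seed(401)
  n <- 200
  lam <- rep(50, n)
  y <- rpois(n, lam)
  base <- mbic(y, lam, integer(0))
  for (tau in c(50L, 100L, 150L)) {
    expect_lt(mbic(y, lam, tau), base)
  }
})

# ---- CBS -----------------------------------------------------------------

test_that("an exact null segments into a single diploid segment", {
  y <- rep(100, 40); lam <- rep(100, 40)
  cp <- cbs_segment(y, lam)
  expect_equal(cp$P, 0L)
  expect_equal(nrow(cp$segments), 1L)
  expect_equal(cp$segments$copy, 2.0)
  expect_error(cbs_segment(numeric(0), numeric(0)), "empty")
})

test_that("a mid-chromosome het deletion is recovered within one exon", {
  set.seed(402)
  n <- 60
  lam <- rep(100, n)
  y <- rpois(n, lam)
  y[21:30] <- rpois(10, 50)
  cp <- cbs_segment(y, lam)
  expect_equal(cp$P, 2L)
  expect_lte(abs(cp$tau[1] - 20), 1)
  expect_lte(abs(cp$tau[2] - 30), 1)
  mid <- which(cp$segments$s > 15 & cp$segments$t < 35)
  expect_equal(cp$segments$copy[mid], 1.0, tolerance = 0.2)
})

test_that("CBS with mBIC matches exhaustive enumeration on small instances", {
  set.seed(403)
  mism <- 0L
  for (rep in 1:40) {
    n <- sample(6:12, 1)
    P_true <- sample(0:2, 1)
    lam <- rep(runif(1, 30, 80), n)
    mult <- rep(1, n)
    if (P_true >= 1) {
      tau <- sort(sample(2:(n - 2), P_true))
      lvl <- sample(c(0.5, 1.5, 2), P_true)
      for (i in seq_len(P_true)) mult[(tau[i] + 1):n] <- lvl[i]
    }
    y <- rpois(n, lam * mult)
    cp <- cbs_segment(y, lam)
    oracle <- oracle_best_model(y, lam)
    if (abs(cp$mbic - oracle$score) > 1e-8) mism <- mism + 1L
  }
  expect_equal(mism, 0L)
})

test_that("nested deletions resolve into distinct copy levels", {
  set.seed(404)
  n <- 80
  lam <- rep(120, n)
  y <- rpois(n, lam)
  y[21:50] <- rpois(30, 60)    # long het deletion
  y[31:40] <- rpois(10, 1)     # nested homozygous core
  cp <- cbs_segment(y, lam)
  seg <- cp$segments
  het <- seg[seg$copy > 0.6 & seg$copy < 1.4, ]
  hom <- seg[seg$copy < 0.3, ]
  expect_gte(nrow(het), 1L)
  expect_equal(nrow(hom), 1L)
  expect_lte(abs(hom$s - 31), 1)
  expect_lte(abs(hom$t - 40), 1)
  bounds <- sort(c(cp$tau))
  expect_true(any(abs(bounds - 20) <= 1))
  expect_true(any(abs(bounds - 50) <= 1))
})

test_that("segment tables expose likelihood, fold and copy consistently", {
  set.seed(405)
  y <- rpois(30, 90); lam <- rep(90, 30)
  cp <- cbs_segment(y, lam)
  seg <- tidy(cp)
  expect_equal(seg$fold, seg$y_sum / seg$lam_sum)
  expect_equal(seg$copy, 2 * seg$fold)
  expect_equal(seg$U, scan_stat(seg$y_sum, seg$lam_sum))
})
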