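# build a small truth object directly
toy_truth <- function(n = 100, m = 10, p = 0.2, type = "het_del",
                      lo = 41L, hi = 45L, carriers = 1:2) {
  ev <- tibble::tibble(event = 1L, center = (lo + hi) %/% 2L,
                       exon_lo = lo, exon_hi = hi,
                       length = hi - lo + 1L, type = type, p = p)
  ev$carriers <- list(carriers)
  cp <- matrix(2, n, m)
  cp[lo:hi, carriers] <- if (type == "dup") 3 else 1
  structure(list(events = ev, copy = cp, n = n, m = m,
                 sample_ids = sprintf("S%02d", 1:m)),
            class = "spike_truth")
}

call_row <- function(sample, lo, hi, call, copy = if (call == "del") 1 else 3) {
  tibble::tibble(sample = sample, chrom = "chrS", exon_lo = lo, exon_hi = hi,
                 start = 0L, end = 1L, n_exons = hi - lo + 1L,
                 y_sum = 1, lam_sum = 1, U = 1, fold = copy / 2,
                 copy = copy, call = call)
}

test_that("perfect calls and empty calls bound the metrics", {
  tr <- toy_truth()
  perfect <- dplyr::bind_rows(
    call_row("S01", 41L, 45L, "del"), call_row("S02", 41L, 45L, "del"))
  ev <- evaluate_calls(perfect, tr)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)

  none <- perfect[0, ]
  ev0 <- evaluate_calls(none, tr)
  expect_equal(ev0$sensitivity, 0)
  expect_equal(ev0$specificity, 1)
})

test_that("wrong-direction and off-target calls are penalized", {
  tr <- toy_truth()
  wrong <- call_row("S01", 41L, 45L, "dup")   # direction matters
  ev <- evaluate_calls(wrong, tr)
  expect_equal(ev$sensitivity, 0)
  # the miscalled cells are true variants, not negatives, so specificity
  # is untouched
  expect_equal(ev$specificity, 1)

  off <- call_row("S05", 10L, 14L, "del")     # 5 false-positive cells
  ev2 <- evaluate_calls(off, tr)
  n_neg <- 100 * 10 - 10
  expect_equal(ev2$specificity, (n_neg - 5) / n_neg)
  expect_error(evaluate_calls(call_row("nope", 1L, 2L, "del"), tr), "absent")
})

test_that("common events are scored against the population-average mirror", {
  # deletion at p = 0.8: non-carriers should be seen as duplicated
  tr <- toy_truth(p = 0.8, carriers = 1:8)
  mirror_calls <- dplyr::bind_rows(lapply(sprintf("S%02d", 9:10), function(s)
    call_row(s, 41L, 45L, "dup")))
  ev <- evaluate_calls(mirror_calls, tr)
  expect_equal(ev$sensitivity, 1)
  expect_equal(ev$specificity, 1)
  # carrier cells are excluded from the negatives, so calling them is free
  # of specificity cost but contributes no sensitivity either
  carrier_calls <- call_row("S01", 41L, 45L, "del")
  ev2 <- evaluate_calls(carrier_calls, tr)
  expect_equal(ev2$sensitivity, 0)
  expect_equal(ev2$specificity, 1)
  # without mirroring the carriers are the truth cells again
  ev3 <- evaluate_calls(carrier_calls, tr, mirror_common = FALSE)
  expect_gt(ev3$sensitivity, 0)
})

test_that("threshold tuning finds the loosest margin meeting the target", {
  set.seed(701)
  n <- 200; m <- 20
  lam <- matrix(100, n, m)
  Y <- matrix(rpois(n * m, lam), n, m)
  carriers <- 1:4
  Y[101:110, carriers] <- rpois(10 * 4, 50)
  fit <- fake_fit(Y, lam)
  tr <- toy_truth(n = n, m = m, lo = 101L, hi = 110L, carriers = carriers,
                  p = 0.2)
  tr$sample_ids <- fit$sample_ids
  segs <- call_cnvs(fit, all_segments = TRUE)
  thr <- tune_threshold(segs, tr, target_specificity = 0.99)
  expect_gte(thr$specificity, 0.99)
  expect_gt(thr$sensitivity, 0.9)
  # ROC sweep: specificity non-decreasing, sensitivity non-increasing in delta
  expect_true(all(diff(thr$roc$specificity) >= 0))
  expect_true(all(diff(thr$roc$sensitivity) <= 0))
  # chosen margin is the loosest admissible one
  looser <- thr$roc[thr$roc$delta < thr$delta, ]
  expect_true(all(looser$specificity < 0.99))
})
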