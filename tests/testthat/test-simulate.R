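test_that("the generator is deterministic and Poisson around its rates", {
  cfg <- sim_config(n = 100, m = 10, K_true = 2, seed = 601)
  cov1 <- simulate_null(cfg)
  cov2 <- simulate_null(cfg)
  expect_identical(cov1$Y, cov2$Y)
  expect_identical(attr(cov1, "params")$lam, attr(cov2, "params")$lam)

  # Poisson mean-variance: standardized residuals against the true rates
  cfg2 <- sim_config(n = 500, m = 30, K_true = 2, seed = 602)
  cov <- simulate_null(cfg2)
  lam <- attr(cov, "params")$lam
  z <- (cov$Y - lam) / sqrt(lam)
  expect_lt(abs(mean(z)), 0.02)
  expect_gt(var(as.vector(z)), 0.9)
  expect_lt(var(as.vector(z)), 1.1)
})

test_that("a structureless configuration gives exchangeable columns", {
  cfg <- sim_config(n = 2000, m = 6, K_true = 0, seed = 603,
                    flat_gc = TRUE, beta_sdlog = 0,
                    depth_range = c(100, 100))
  cov <- simulate_null(cfg)
  cm <- unname(colMeans(cov$Y))
  expect_equal(cm, rep(100, 6), tolerance = 0.02)
})

test_that("spike-in carrier counts and scaling follow the protocol", {
  cfg <- sim_config(n = 1000, m = 90, K_true = 0, seed = 604)
  cov <- simulate_null(cfg)
  ev <- spike_events(1000, p = 0.1, length = 5, stride = 100)
  sp <- spike_in(cov, ev, seed = 605)
  expect_equal(nrow(sp$truth$events), 9L)  # centers 100..900 fit a 5-exon event
  # m * p = 9 carriers per event
  expect_true(all(lengths(sp$truth$events$carriers) == 9L))

  # deterministic limit: carrier_sd = 0 halves counts exactly
  sp0 <- spike_in(cov, ev, carrier_sd = 0, seed = 606)
  e1 <- sp0$truth$events[1, ]
  exons <- e1$exon_lo:e1$exon_hi
  carriers <- e1$carriers[[1]]
  expect_identical(sp0$cov$Y[exons, carriers],
                   round(cov$Y[exons, carriers] / 2))
  # non-carriers and non-spiked exons untouched
  others <- setdiff(seq_len(90), carriers)
  expect_identical(sp0$cov$Y[exons, others], cov$Y[exons, others])
  expect_identical(sp0$cov$Y[setdiff(1:1000, unlist(mapply(seq,
    sp0$truth$events$exon_lo, sp0$truth$events$exon_hi))), ],
    cov$Y[setdiff(1:1000, unlist(mapply(seq, sp0$truth$events$exon_lo,
    sp0$truth$events$exon_hi))), ])

  # with c ~ N(1, 0.1) the carrier/non-carrier depth ratio is 0.5 on average
  ratios <- vapply(seq_len(nrow(sp$truth$events)), function(e) {
    exq <- sp$truth$events$exon_lo[e]:sp$truth$events$exon_hi[e]
    cs <- sp$truth$events$carriers[[e]]
    mean(sp$cov$Y[exq, cs]) / mean(sp$cov$Y[exq, -cs])
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 0.5), 0.02)

  # truth matrix carries the true copy state
  expect_true(all(sp0$truth$copy[exons, carriers] == 1))
  expect_true(all(sp0$truth$copy[exons, others] == 2))
})

test_that("event layout, overlap and frequency validation", {
  ev <- spike_events(500, p = c(0.2, 0.6), length = c(5, 10), stride = 100)
  expect_equal(ev$length, rep(c(5L, 10L), length.out = nrow(ev)))
  expect_true(all(ev$exon_hi <= 500))

  cfg <- sim_config(n = 300, m = 10, K_true = 0, seed = 607)
  cov <- simulate_null(cfg)
  bad <- tibble::tibble(event = 1:2, center = c(100L, 102L),
                        exon_lo = c(98L, 100L), exon_hi = c(102L, 104L),
                        length = 5L, type = "het_del", p = 0.2)
  expect_error(spike_in(cov, bad), "overlapping")
  bad2 <- spike_events(300, p = 1.5)
  expect_error(spike_in(cov, bad2), "0 < p < 1")
})

test_that("mirrored events complement the carriers and flip the state", {
  cfg <- sim_config(n = 400, m = 20, K_true = 0, seed = 608)
  cov <- simulate_null(cfg)
  ev <- spike_events(400, p = 0.3, length = 5, stride = 100)
  sp <- spike_in(cov, ev, seed = 609)
  mir <- mirror_events(sp$truth)
  expect_equal(mir$p, rep(0.7, nrow(mir)))
  expect_true(all(mir$type == "dup"))
  for (e in seq_len(nrow(mir))) {
    expect_equal(sort(c(sp$truth$events$carriers[[e]], mir$carriers[[e]])),
                 1:20)
  }
})
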