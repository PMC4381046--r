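# unit-level checks of the individual normalization steps

test_that("exon bias is the row median of the ratio matrix", {
  # N = 1, fGC = 1, GH = 0 so the ratio matrix equals Y itself
  Y <- rbind(c(1, 2, 3), c(5, 5, 5))
  fGC <- matrix(1, 2, 3); GH <- matrix(0, 2, 3)
  beta <- update_exon_bias(Y, N = c(1, 1, 1), fGC, GH)
  expect_equal(beta, c(2, 5))

  Yz <- rbind(c(0, 0, 0), c(1, 1, 1))
  expect_error(update_exon_bias(Yz, c(1, 1, 1), fGC, GH), "zero counts")
})

test_that("GC spline recovers a flat profile within 5%", {
  set.seed(41)
  n <- 500; m <- 4
  gc <- runif(n, 0.2, 0.8)
  beta <- rep(1, n)
  N <- rep(1e6, m)
  lam <- matrix(100, n, m)   # f constant: lambda = N * f * beta => f = 1e-4
  Y <- matrix(rpois(n * m, lam), n, m)
  gf <- fit_gc_functions(Y, N, beta, matrix(0, n, m), gc)
  rel <- abs(gf$fitted / 1e-4 - 1)
  expect_lt(median(rel), 0.05)
})

test_that("GC spline finds the peak of a unimodal bias within 0.05", {
  set.seed(42)
  n <- 800; m <- 2
  gc <- runif(n, 0.2, 0.8)
  peak <- 0.45
  f <- 1e-4 * exp(-(gc - peak)^2 / (2 * 0.15^2))
  N <- rep(1e6, m)
  lam <- outer(f, N)
  Y <- matrix(rpois(n * m, lam), n, m)
  gf <- fit_gc_functions(Y, N, rep(1, n), matrix(0, n, m), gc)
  for (j in 1:m) {
    grid <- seq(0.25, 0.75, by = 0.001)
    argmax <- grid[which.max(gf$funcs[[j]](grid))]
    expect_lt(abs(argmax - peak), 0.05)
  }
  # evaluation outside the observed range clamps, stays positive
  expect_true(all(gf$funcs[[1]](c(0, 1)) > 0))
})

test_that("too little GC spread is an error", {
  Y <- matrix(10, 20, 3)
  expect_error(
    fit_gc_functions(Y, rep(1, 3), rep(1, 20), matrix(0, 20, 3),
                     gc = rep(c(0.4, 0.5), 10)),
    "insufficient GC spread")
})

test_that("latent initialization returns orthonormal factors and checks K", {
  set.seed(43)
  Y <- matrix(rpois(200 * 10, 50), 200, 10)
  Z <- matrix(50, 200, 10)
  h <- init_latent(Y, Z, 3)
  expect_equal(dim(h), c(10L, 3L))
  expect_equal(crossprod(h), diag(3), tolerance = 1e-10)
  expect_error(init_latent(Y, Z, 10), "smaller")
})

test_that("the batched exon regression matches glm with offset", {
  set.seed(44)
  m <- 40; K <- 2
  h <- qr.Q(qr(matrix(rnorm(m * K), m, K)))
  z <- runif(m, 50, 150)
  g_true <- c(1.2, -0.8)
  y <- rpois(m, z * exp(drop(h %*% g_true)))
  Y <- matrix(y, 1, m)
  Z <- matrix(z, 1, m)
  g_pkg <- update_g(Y, Z, h)
  g_glm <- unname(coef(glm(y ~ 0 + h, family = poisson(),
                           offset = log(z))))
  expect_equal(drop(g_pkg), g_glm, tolerance = 1e-6)
  # first-order condition: score residuals vanish
  mu <- z * exp(drop(h %*% drop(g_pkg)))
  expect_equal(drop(crossprod(h, y - mu)), c(0, 0), tolerance = 1e-4)
})

test_that("sample-side regression matches glm and recovers known factors", {
  set.seed(45)
  n <- 300; K <- 1
  g <- matrix(rnorm(n, 0, 0.5), n, K)
  z <- matrix(runif(n, 40, 120), n, 2)
  h_true <- matrix(c(0.7, -0.4), 2, K)
  lam <- z * exp(g %*% t(h_true))
  Y <- matrix(rpois(n * 2, lam), n, 2)
  h_fit <- update_h(Y, z, g)
  h_glm <- unname(coef(glm(Y[, 1] ~ 0 + g, family = poisson(),
                           offset = log(z[, 1]))))
  expect_equal(h_fit[1, 1], h_glm, tolerance = 1e-6)
  expect_equal(drop(h_fit), drop(h_true), tolerance = 0.1)
})

test_that("fitted g is within 3 SE of truth for most exons (K = 1, h known)", {
  set.seed(46)
  n <- 300; m <- 40
  h <- matrix(qr.Q(qr(matrix(rnorm(m), m, 1))), m, 1)
  g_true <- matrix(rnorm(n, 0, 1.0), n, 1)
  Z <- matrix(80, n, m)
  lam <- Z * exp(g_true %*% t(h))
  Y <- matrix(rpois(n * m, lam), n, m)
  g_fit <- update_g(Y, Z, h)
  # Fisher information for g_i: sum_j lam_ij h_j^2
  se <- sqrt(1 / rowSums(lam * matrix(h^2, n, m, byrow = TRUE)))
  frac_ok <- mean(abs(g_fit - g_true) <= 3 * se)
  expect_gte(frac_ok, 0.95)
})

test_that("data without latent structure yield only overfit-level deviance", {
  set.seed(47)
  n <- 300; m <- 20; K <- 2
  Z <- matrix(60, n, m)
  Y <- matrix(rpois(n * m, Z), n, m)
  dev_null <- poisson_dev_ref(Y, Z)

  # sample-side factors fitted against fixed exon loadings capture < 1% of
  # the deviance: there is no structure for them to find
  g_fixed <- matrix(rnorm(n * K, 0, 0.5), n, K)
  h <- update_h(Y, Z, g_fixed)
  dev_h <- poisson_dev_ref(Y, Z * exp(g_fixed %*% t(h)))
  expect_lt((dev_null - dev_h) / dev_null, 0.01)

  # the full alternation can only absorb noise at the chi-square scale of
  # its K (n + m) free parameters, not systematic signal
  h0 <- init_latent(Y, Z, K)
  g <- update_g(Y, Z, h0)
  h1 <- update_h(Y, Z, g)
  dev_gh <- poisson_dev_ref(Y, Z * exp(g %*% t(h1)))
  expect_lt(dev_null - dev_gh, 2 * K * (n + m))
})
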