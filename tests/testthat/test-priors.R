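test_that("regularized horseshoe matches a direct reimplementation", {
  set.seed(2)
  p <- 25
  beta <- rnorm(p); lambda <- abs(rcauchy(p)); tau <- 0.2; cs <- 1.7
  lt <- sqrt(cs^2 * lambda^2 / (cs^2 + tau^2 * lambda^2))
  direct <- sum(dnorm(beta, 0, tau * lt, log = TRUE))
  expect_equal(
    regularizedHorseshoeLogDensity(beta, lambda, tau, cs,
                                   includeHyperpriors = FALSE),
    direct, tolerance = 1e-13)
  # hyperprior terms: half-Cauchy for lambda and tau, inverse-gamma slab
  hc <- function(x, s) log(2 / pi) - log(s) - log1p((x / s)^2)
  full <- direct + sum(hc(lambda, 1)) + hc(tau, 1) +
    2 * log(8) - lgamma(2) - 3 * log(cs^2) - 8 / cs^2
  expect_equal(
    regularizedHorseshoeLogDensity(beta, lambda, tau, cs),
    full, tolerance = 1e-12)
})

test_that("slab-off and regularization limits hold", {
  beta <- c(0.5, -1, 2); lambda <- c(0.3, 1, 4); tau <- 0.5
  # c -> infinity: lambda_tilde -> lambda (plain horseshoe)
  expect_lt(abs(
    regularizedHorseshoeLogDensity(beta, lambda, tau, 1e8,
                                   includeHyperpriors = FALSE) -
      sum(dnorm(beta, 0, tau * lambda, log = TRUE))), 1e-8)
  # lambda -> infinity: prior sd capped at the slab scale c
  expect_lt(abs(
    regularizedHorseshoeLogDensity(beta, rep(1e8, 3), tau, 2,
                                   includeHyperpriors = FALSE) -
      sum(dnorm(beta, 0, 2, log = TRUE))), 1e-6)
  expect_error(regularizedHorseshoeLogDensity(beta, -lambda, tau, 2), "> 0")
})

test_that("paired horseshoe reduces, increases in rho, and matches MVN", {
  set.seed(3)
  p <- 12
  bm <- rnorm(p); bp <- rnorm(p); lambda <- abs(rcauchy(p))
  tau <- 0.3; cs <- 2
  # rho = 0: two independent univariate horseshoe normal terms
  expect_equal(
    pairedHorseshoeLogDensity(bm, bp, lambda, tau, cs, rho = 0),
    regularizedHorseshoeLogDensity(bm, lambda, tau, cs,
                                   includeHyperpriors = FALSE) +
      regularizedHorseshoeLogDensity(bp, lambda, tau, cs,
                                     includeHyperpriors = FALSE),
    tolerance = 1e-12)
  # equal coefficient pairs: density increases monotonically in rho
  v <- vapply(c(0, 0.3, 0.6, 0.9, 0.99), function(r) {
    pairedHorseshoeLogDensity(bm, bm, lambda, tau, cs, rho = r)
  }, 0.0)
  expect_true(all(diff(v) > 0))
  # closed-form bivariate normal oracle
  rho <- -0.4
  s <- tau * sqrt(cs^2 * lambda^2 / (cs^2 + tau^2 * lambda^2))
  oracle <- sum(vapply(seq_len(p), function(j) {
    S <- s[j]^2 * matrix(c(1, rho, rho, 1), 2)
    x <- c(bm[j], bp[j])
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(x %*% solve(S) %*% x)
  }, 0.0))
  expect_equal(pairedHorseshoeLogDensity(bm, bp, lambda, tau, cs, rho),
               oracle, tolerance = 1e-11)
  expect_error(pairedHorseshoeLogDensity(bm, bp, lambda, tau, cs, 1), "rho")
})

test_that("ICAR kernel equals the Laplacian quadratic form", {
  h <- generateHierarchy(2, 4, 12, seed = 21)
  set.seed(4)
  phi <- rnorm(12)
  A <- as.matrix(adjacencyMatrix(h))
  Q <- diag(rowSums(A)) - A
  tauPhi <- 0.7
  expect_equal(
    icarLogDensity(phi, h, tauPhi, sumToZero = FALSE),
    -drop(phi %*% Q %*% phi) / (2 * tauPhi^2), tolerance = 1e-13)
  # two nodes, one edge, phi = (1, -1): pairwise term (1-(-1))^2/2 = 2
  e2 <- matrix(c(1L, 2L), 1)
  expect_equal(icarLogDensity(c(1, -1), e2, 1, sumToZero = FALSE), -2)
  # constant field: pairwise term zero (maximal)
  expect_equal(icarLogDensity(rep(3, 12), h, 1, sumToZero = FALSE), 0)
})

test_that("ICAR shift invariance holds and sum-to-zero restores identity", {
  h <- generateHierarchy(2, 4, 12, seed = 21)
  set.seed(5)
  phi <- rnorm(12)
  a <- icarLogDensity(phi, h, 1, sumToZero = FALSE)
  b <- icarLogDensity(phi + 100, h, 1, sumToZero = FALSE)
  expect_equal(a, b, tolerance = 1e-9)
  # with the soft constraint the shifted field is heavily penalized
  a2 <- icarLogDensity(phi - mean(phi), h, 1)
  b2 <- icarLogDensity(phi - mean(phi) + 100, h, 1)
  expect_lt(b2, a2 - 1e4)
  expect_error(icarLogDensity(phi, matrix(c(1L, 2L), 1), 1), "connected")
})

test_that("AR(1) x ICAR kernel matches a dense brute-force evaluation", {
  h <- generateHierarchy(2, 4, 12, seed = 22)
  s <- 12; tn <- 6
  set.seed(6)
  Phi <- matrix(rnorm(s * tn, sd = 0.5), s, tn)
  ar <- 0.6; tauPhi <- 0.8
  # brute force: ICAR on column 1 and on innovations, sum-to-zero per month
  e <- adjacencyEdges(h)
  idx <- matrix(match(e, l3Regions(h)), ncol = 2)
  bf <- 0
  for (t in seq_len(tn)) {
    innov <- if (t == 1) Phi[, 1] else Phi[, t] - ar * Phi[, t - 1]
    bf <- bf - sum((innov[idx[, 1]] - innov[idx[, 2]])^2) / (2 * tauPhi^2)
    bf <- bf + dnorm(mean(Phi[, t]), 0, 0.001 * s, log = TRUE)
  }
  expect_equal(arIcarLogDensity(Phi, h, ar, tauPhi), bf, tolerance = 1e-10)
  # ar = 0 reduces to independent per-month ICAR kernels
  perMonth <- sum(vapply(seq_len(tn), function(t) {
    icarLogDensity(Phi[, t], h, tauPhi)
  }, 0.0))
  expect_equal(arIcarLogDensity(Phi, h, 0, tauPhi), perMonth,
               tolerance = 1e-10)
  # single time step equals one ICAR kernel
  expect_equal(arIcarLogDensity(Phi[, 1, drop = FALSE], h, 0.9, tauPhi),
               icarLogDensity(Phi[, 1], h, tauPhi), tolerance = 1e-12)
  expect_error(arIcarLogDensity(Phi, h, 1.2, tauPhi), "arCoef")
})

test_that("kernels decrease away from their modes along rays", {
  h <- generateHierarchy(2, 4, 12, seed = 23)
  set.seed(7)
  dir <- rnorm(12); dir <- dir - mean(dir)
  v <- vapply(c(0, 0.5, 1, 2, 4), function(s) {
    icarLogDensity(s * dir, h, 1)
  }, 0.0)
  expect_true(all(diff(v) < 0))
  b <- seq(0, 3, by = 0.5)
  vb <- vapply(b, function(s) {
    regularizedHorseshoeLogDensity(rep(s, 4), rep(1, 4), 0.5, 2,
                                   includeHyperpriors = FALSE)
  }, 0.0)
  expect_true(all(diff(vb) < 0))
})
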