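test_that("maxima CDF is the n-th power with a vacuous empty maximum", {
  expect_equal(maximaCdf(0.9, 2), 0.81)
  expect_equal(maximaCdf(c(0.2, 0.7), 0), c(1, 1))
  expect_error(maximaCdf(1.2, 3), "in \\[0, 1\\]")
  # Monte-Carlo oracle: P(max of 100 iid lognormals <= q0.95)
  set.seed(50)
  R <- 2e5
  q95 <- qlnorm(0.95)
  mx <- apply(matrix(rlnorm(R / 100 * 100 * 100), ncol = 100), 1, max)
  mx <- matrix(rlnorm(R * 20), ncol = 20)   # n = 20 keeps the MC cheap
  pEmp <- mean(apply(mx, 1, max) <= q95)
  pTheo <- maximaCdf(0.95, 20)
  expect_lt(abs(pEmp - pTheo), 3 * sqrt(pTheo * (1 - pTheo) / R))
})

test_that("lognormal maxima quantile has its closed-form special cases", {
  expect_equal(lognormalMaximaQuantile(0, 1, 1, 0.5), 1)       # the median
  expect_equal(lognormalMaximaQuantile(0, 2.7, 1, 0.5), 1)
  expect_equal(lognormalMaximaQuantile(1.3, 0, 50, 0.9), exp(1.3))
  expect_error(lognormalMaximaQuantile(0, 1, 1, 1.2), "in \\(0, 1\\)")
  # monotone in P and in n
  P <- c(0.1, 0.4, 0.7, 0.95)
  expect_true(all(diff(lognormalMaximaQuantile(0, 1, 10, P)) > 0))
  n <- c(1, 5, 50, 500)
  expect_true(all(diff(lognormalMaximaQuantile(0, 1, n, 0.5)) > 0))
})

test_that("quantile and CDF round-trip across a parameter grid", {
  worst <- 0
  for (mu in c(-1, 0, 2)) for (sg in c(0.3, 1, 2)) {
    for (n in c(1, 7, 120)) for (P in c(0.01, 0.5, 0.99)) {
      q <- lognormalMaximaQuantile(mu, sg, n, P)
      worst <- max(worst, abs(maximaCdf(plnorm(q, mu, sg), n) - P))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("the family-agnostic quantile path matches the closed form", {
  for (P in c(0.05, 0.5, 0.95)) {
    for (n in c(1, 30)) {
      expect_lt(abs(maximaQuantile("lognormal", P, n, 0.7, c(sdlog = 1.2)) -
                      lognormalMaximaQuantile(0.7, 1.2, n, P)), 1e-8)
    }
  }
})

test_that("maxima quantile matches Monte-Carlo maxima", {
  set.seed(51)
  R <- 2e5
  q <- lognormalMaximaQuantile(0, 1, 100, 0.5)
  # P(max of 100 standard lognormals <= q) should be 0.5
  below <- vapply(seq_len(R / 1000), function(b) {
    sum(apply(matrix(rlnorm(1000 * 100), ncol = 100), 1, max) <= q)
  }, 0.0)
  pEmp <- sum(below) / R
  expect_lt(abs(pEmp - 0.5), 3 * sqrt(0.25 / R))
})

test_that("maxima intervals reduce correctly and are monotone in level", {
  # all draws have exactly one fire and identical size parameters
  D <- 40; nCell <- 3
  counts <- matrix(1L, D, nCell)
  loc <- matrix(rep(c(3, 4, 5), each = 1), nCell, D)
  sp <- list(loc = loc, aux = matrix(1, D, 1,
                                     dimnames = list(NULL, "sdlog")),
             family = "lognormal")
  iv <- maximaInterval(counts, sp, level = 0.95)
  expect_equal(iv$lower, qlnorm(0.025, c(3, 4, 5), 1), tolerance = 1e-6)
  expect_equal(iv$upper, qlnorm(0.975, c(3, 4, 5), 1), tolerance = 1e-6)
  # wider levels give wider intervals
  iv50 <- maximaInterval(counts, sp, level = 0.5)
  iv99 <- maximaInterval(counts, sp, level = 0.99)
  expect_true(all(iv50$lower >= iv$lower & iv$lower >= iv99$lower))
  expect_true(all(iv50$upper <= iv$upper & iv$upper <= iv99$upper))
  # cells with no fires in any draw are flagged
  counts0 <- counts; counts0[, 2] <- 0L
  iv0 <- maximaInterval(counts0, sp)
  expect_true(iv0$noFire[2] && is.na(iv0$lower[2]))
  expect_error(maximaInterval(counts[, 1:2], sp), "misaligned")
})

test_that("exceedance probabilities follow the product construction", {
  D <- 5
  sp1 <- list(loc = matrix(0, 1, D), aux = matrix(1, D, 1,
                                                  dimnames = list(NULL, "sdlog")),
              family = "lognormal")
  # no fires: probability zero in every draw
  z <- exceedanceProbability(matrix(0L, D, 1), sp1, threshold = 100)
  expect_true(all(z$median == 0 & z$hi == 0))
  # one cell, n = 1, threshold at the 99th percentile: probability 0.01
  thr <- qlnorm(0.99)
  one <- exceedanceProbability(matrix(1L, D, 1), sp1, threshold = thr)
  expect_equal(one$median, 0.01, tolerance = 1e-9)
  # two independent cells: 1 - (1 - p)^2, against direct enumeration
  sp2 <- list(loc = matrix(0, 2, D), aux = sp1$aux, family = "lognormal")
  two <- exceedanceProbability(matrix(1L, D, 2), sp2, threshold = thr,
                               scope = "monthly", S = 2)
  expect_equal(two$median, 1 - (1 - 0.01)^2, tolerance = 1e-9)
  # monotone: nonincreasing in the threshold, nondecreasing in n
  p1 <- exceedanceProbability(matrix(3L, D, 1), sp1, thr)$median
  p2 <- exceedanceProbability(matrix(3L, D, 1), sp1, thr * 2)$median
  p3 <- exceedanceProbability(matrix(5L, D, 1), sp1, thr)$median
  expect_lte(p2, p1)
  expect_gte(p3, p1)
})
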