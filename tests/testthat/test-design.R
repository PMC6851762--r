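# naive Cox-de Boor recursion, the independent oracle for basis evaluation
cdbBasis <- function(knots, x, ord) {
  nb <- length(knots) - ord
  B <- function(i, k, x) {
    if (k == 1) {
      # right-closed at the final interval so the boundary point is covered
      hi <- knots[i + 1]
      lo <- knots[i]
      as.numeric(x >= lo & (x < hi | (hi == knots[length(knots)] & x <= hi)))
    } else {
      a <- 0
      if (knots[i + k - 1] > knots[i]) {
        a <- (x - knots[i]) / (knots[i + k - 1] - knots[i]) * B(i, k - 1, x)
      }
      b <- 0
      if (knots[i + k] > knots[i + 1]) {
        b <- (knots[i + k] - x) / (knots[i + k] - knots[i + 1]) *
          B(i + 1, k - 1, x)
      }
      a + b
    }
  }
  vapply(seq_len(nb), function(i) B(i, ord, x), numeric(length(x)))
}

test_that("interior knots sit at equally spaced training quantiles", {
  x <- seq(0, 1, length.out = 1001)
  sp5 <- makeSplineSpec(x, "u", df = 5)       # cubic: one interior knot
  expect_equal(sp5@interior, 0.5, tolerance = 1e-6)
  sp7 <- makeSplineSpec(x, "u", df = 7)       # cubic: three interior knots
  expect_equal(sp7@interior, c(0.25, 0.5, 0.75), tolerance = 1e-6)
  expect_equal(sp5@boundary, c(0, 1))
  expect_error(makeSplineSpec(rep(1, 100), "u"), "distinct")
  expect_error(makeSplineSpec(1:4, "u", df = 5), "distinct")
})

test_that("basis rows are a partition of unity and match Cox-de Boor", {
  set.seed(1)
  sp <- makeSplineSpec(runif(500, 2, 9), "v", df = 5)
  g <- seq(sp@boundary[1], sp@boundary[2], length.out = 10000)
  M <- evaluateBasis(sp, g)
  expect_true(all(M >= 0))
  expect_lt(max(abs(rowSums(M) - 1)), 1e-10)
  ord <- sp@degree + 1L
  knots <- c(rep(sp@boundary[1], ord), sp@interior, rep(sp@boundary[2], ord))
  xs <- c(sp@boundary[1], quantile(g, c(.17, .5, .83), names = FALSE),
          sp@boundary[2])
  expect_equal(evaluateBasis(sp, xs), cdbBasis(knots, xs, ord),
               ignore_attr = TRUE, tolerance = 1e-12)
  # at the lower boundary the first basis function is maximal (value 1)
  b0 <- evaluateBasis(sp, sp@boundary[1])
  expect_equal(as.numeric(b0), c(1, 0, 0, 0, 0))
})

test_that("out-of-range values are clamped to the boundary with a warning", {
  sp <- makeSplineSpec(seq(0, 1, 0.01), "v", df = 5)
  expect_warning(hi <- evaluateBasis(sp, 2), "clamped")
  expect_equal(as.numeric(hi), as.numeric(evaluateBasis(sp, 1)))
  expect_error(evaluateBasis(sp, NaN), "non-finite")
})

test_that("six df-5 covariate bases yield 30 global basis vectors", {
  sim <- fixtureSim
  specs <- splineSpecs(sim$design)
  expect_length(specs, 6)
  expect_equal(sum(vapply(specs, function(s) s@df, 0L)), 30L)
  ci <- columnInfo(sim$design)
  expect_equal(sum(ci$level == "global" &
                     ci$covariate != "intercept-adjustment"), 30L)
})

test_that("column count follows p = B(1+R)+R on the toy and random trees", {
  sim <- fixtureSim
  expect_equal(ncol(designMatrix(sim$design)), 30 * (1 + 18) + 18)  # 588
  # brute-force enumeration of the column metadata
  ci <- columnInfo(sim$design)
  expect_equal(nrow(ci), 588L)
  expect_equal(as.integer(table(ci$level)[c("global", "L1", "L2", "L3")]),
               c(30L, 2L * 30 + 2L, 4L * 30 + 4L, 12L * 30 + 12L))
  set.seed(99)
  for (k in 1:3) {
    n1 <- sample(1:2, 1); n2 <- n1 + sample(0:2, 1); n3 <- n2 + sample(0:4, 1)
    h <- generateHierarchy(n1, n2, n3, seed = k)
    cv <- simulateCovariates(h, 20, seed = k + 10)
    panel <- assemblePanel(emptyFireCatalog(), cv, h, 16)
    specs <- makeDefaultSplineSpecs(cv[cv$t <= 16, ])
    d <- buildDesignMatrix(panel, h, specs, warnClamp = FALSE)
    R <- n1 + n2 + n3
    expect_equal(ncol(designMatrix(d)), 30 * (1 + R) + R)
  }
})

test_that("row sparsity is bounded by 4B + 3 nonzeros", {
  X <- designMatrix(fixtureSim$design)
  nnzRow <- Matrix::rowSums(X != 0)
  expect_true(all(nnzRow <= 4 * 30 + 3))
  expect_gt(1 - max(nnzRow) / ncol(X), 1 - 123 / 588)
})

test_that("sparse assembly equals a dense row-wise construction", {
  h <- generateHierarchy(1, 2, 4, seed = 5)
  cv <- simulateCovariates(h, 15, seed = 6)
  panel <- assemblePanel(emptyFireCatalog(), cv, h, 13)
  specs <- makeDefaultSplineSpecs(cv[cv$t <= 13, ])
  d <- buildDesignMatrix(panel, h, specs, warnClamp = FALSE)
  ci <- columnInfo(d)
  fp <- flattenPanel(panel)
  dense <- matrix(0, nrow(fp), nrow(ci))
  bases <- lapply(specs, function(sp) evaluateBasis(sp, fp[[sp@covariate]],
                                                    warnClamp = FALSE))
  unitOf <- function(lev, i) switch(lev, global = NA,
                                    L1 = l1Of(h, fp$l3[i]),
                                    L2 = l2Of(h, fp$l3[i]), L3 = fp$l3[i])
  for (j in seq_len(nrow(ci))) {
    for (i in seq_len(nrow(fp))) {
      if (ci$covariate[j] == "intercept-adjustment") {
        dense[i, j] <- as.numeric(unitOf(ci$level[j], i) == ci$region[j])
      } else {
        v <- bases[[ci$covariate[j]]][i, ci$basis_index[j]]
        dense[i, j] <- if (ci$level[j] == "global") v else {
          v * (unitOf(ci$level[j], i) == ci$region[j])
        }
      }
    }
  }
  expect_equal(as.matrix(designMatrix(d)), dense, ignore_attr = TRUE,
               tolerance = 1e-15)
})

test_that("regional coefficients sum global and level adjustments", {
  sim <- fixtureSim
  ci <- columnInfo(sim$design)
  p <- nrow(ci)
  set.seed(7)
  beta <- rnorm(p)
  l3 <- l3Regions(sim$hierarchy)
  # all adjustments zero -> the global coefficients
  bg <- beta
  bg[ci$level != "global"] <- 0
  cf <- coefficientForRegion(bg, sim$design, sim$hierarchy, "humidity", l3[1])
  expect_equal(cf, bg[ci$level == "global" & ci$covariate == "humidity"])
  # two L3 regions under the same L2 differ only via their L3 adjustments
  sib <- l3[l2Of(sim$hierarchy, l3) == l2Of(sim$hierarchy, l3[1])][1:2]
  c1 <- coefficientForRegion(beta, sim$design, sim$hierarchy, "wind", sib[1])
  c2 <- coefficientForRegion(beta, sim$design, sim$hierarchy, "wind", sib[2])
  d3 <- function(r) {
    k <- ci$covariate == "wind" & ci$level == "L3" & ci$region == r
    beta[k][order(ci$basis_index[k])]
  }
  expect_equal(c1 - c2, d3(sib[1]) - d3(sib[2]))
  # dot product with a basis row equals the direct X beta contribution
  fp <- flattenPanel(sim$panel)
  i <- 37
  r <- fp$l3[i]
  cf <- coefficientForRegion(beta, sim$design, sim$hierarchy, "temperature", r)
  row <- evaluateBasis(splineSpecs(sim$design)$temperature,
                       fp$temperature[i], warnClamp = FALSE)
  cols <- ci$covariate == "temperature"
  direct <- as.numeric(designMatrix(sim$design)[i, cols] %*% beta[cols])
  expect_equal(sum(cf * row), direct, tolerance = 1e-12)
  expect_error(coefficientForRegion(beta, sim$design, sim$hierarchy,
                                    "nosuch", l3[1]), "unknown covariate")
})
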