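test_that("degenerate single-region hierarchy is valid with no edges", {
  h <- generateHierarchy(1, 1, 1, seed = 1)
  expect_s4_class(h, "EcoregionHierarchy")
  expect_equal(nrow(adjacencyEdges(h)), 0)
  expect_equal(unname(nRegions(h)), c(1L, 1L, 1L))
})

test_that("hierarchy is a nested partition with positive areas", {
  h <- generateHierarchy(2, 4, 12, seed = 7)
  l3 <- l3Regions(h)
  expect_length(l3, 12)
  expect_length(unique(l2Of(h, l3)), 4)
  expect_length(unique(l1Of(h, l3)), 2)
  # every L3 has exactly one L2 parent, every L2 exactly one L1 parent
  expect_false(any(is.na(l2Of(h, l3))))
  perL2 <- tapply(l1Of(h, l3), l2Of(h, l3), function(x) length(unique(x)))
  expect_true(all(perL2 == 1))
  expect_true(all(regionArea(h) > 0))
})

test_that("adjacency is symmetric and connected (graph-traversal oracle)", {
  skip_if_not_installed("igraph")
  for (dims in list(c(2, 4, 12), c(1, 2, 7), c(3, 5, 20))) {
    h <- generateHierarchy(dims[1], dims[2], dims[3], seed = 7)
    A <- as.matrix(adjacencyMatrix(h))
    expect_true(isSymmetric(A))
    expect_true(all(diag(A) == 0))
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    expect_true(igraph::is_connected(g))
  }
})

test_that("invalid hierarchy sizes are rejected", {
  expect_error(generateHierarchy(3, 2, 12, seed = 1), "nL1 <= nL2")
  expect_error(generateHierarchy(0, 1, 1, seed = 1), "nL1")
})

test_that("noiseless temperature is an exact region-specific sinusoid", {
  h <- generateHierarchy(1, 1, 2, seed = 3)
  cv <- simulateCovariates(h, 48, seed = 5,
                           noiseSd = c(humidity = 0, temperature = 0,
                                       precipitation = 0, wind = 0))
  for (r in l3Regions(h)) {
    d <- cv[cv$l3 == r, ]
    f <- lm(temperature ~ cos(2 * pi * t / 12) + sin(2 * pi * t / 12),
            data = d)
    expect_lt(max(abs(residuals(f))), 1e-9)
  }
})

test_that("covariate simulation is deterministic given the seed", {
  h <- generateHierarchy(2, 4, 12, seed = 7)
  a <- simulateCovariates(h, 24, seed = 9)
  b <- simulateCovariates(h, 24, seed = 9)
  expect_identical(a, b)
  expect_error(simulateCovariates(h, 12, seed = 1), ">= 13")
})

test_that("covariates respect their ranges and housing grows monotonically", {
  cv <- simulateCovariates(generateHierarchy(2, 4, 12, seed = 7), 36, seed = 1)
  expect_true(all(cv$humidity > 0 & cv$humidity < 100))
  expect_true(all(cv$precipitation > 0 & cv$wind > 0 & cv$housing > 0))
  for (r in unique(cv$l3)) {
    expect_true(all(diff(cv$housing[cv$l3 == r][order(cv$t[cv$l3 == r])]) > 0))
  }
})

test_that("prior-12-month precipitation matches the rolling operator", {
  cv <- simulateCovariates(generateHierarchy(1, 1, 1, seed = 2), 30, seed = 4)
  roll <- rollingPriorPrecip(cv$precipitation)
  t13 <- which(cv$t >= 13)
  expect_equal(cv$precip12[t13], roll[t13], tolerance = 1e-12)
})

test_that("AR(1) noise has the configured lag-1 autocorrelation", {
  h <- generateHierarchy(1, 1, 1, seed = 1)
  cv <- simulateCovariates(h, 1200, seed = 8, arCoef = 0.7,
                           noiseSd = c(humidity = 0, temperature = 2,
                                       precipitation = 0, wind = 0))
  f <- lm(temperature ~ cos(2 * pi * t / 12) + sin(2 * pi * t / 12), data = cv)
  r <- residuals(f)
  acf1 <- cor(r[-1], r[-length(r)])
  se <- sqrt((1 - 0.7^2) / length(r))   # large-sample sd of the lag-1 ACF
  expect_lt(abs(acf1 - 0.7), 3 * se)
})

test_that("certain zero-inflation produces an empty catalog", {
  sim <- fixtureSim
  truth <- sim$truth
  truth@alphaPi <- 40   # logit^-1(40) = 1 up to machine precision
  out <- simulateFires(sim$panel, sim$design, truth, seed = 11)
  expect_equal(length(out$catalog), 0)
  expect_true(all(panelCounts(out$panel) == 0))
})

test_that("catalog events tally exactly to panel counts", {
  sim <- fixtureSim
  ev <- catalogEvents(sim$catalog)
  cd <- SummarizedExperiment::colData(sim$panel)
  cnt <- panelCounts(sim$panel)
  expect_equal(sum(cnt), nrow(ev))
  tab <- table(factor(ev$l3, levels = rownames(cnt)),
               factor(match(paste(ev$year, ev$month),
                            paste(cd$year, cd$month)),
                      levels = seq_len(ncol(cnt))))
  expect_true(all(as.integer(tab) == as.integer(cnt)))
})

test_that("fire simulation is deterministic given the seed", {
  sim <- fixtureSim
  a <- simulateFires(sim$panel, sim$design, sim$truth, seed = 5)
  b <- simulateFires(sim$panel, sim$design, sim$truth, seed = 5)
  expect_identical(catalogEvents(a$catalog), catalogEvents(b$catalog))
})

test_that("null-covariate count and size moments match closed forms", {
  # 12 regions x 840 months > 10,000 cells; beta = 0, pi = 0
  h <- generateHierarchy(2, 4, 12, seed = 13)
  cv <- simulateCovariates(h, 840, seed = 14)
  panel <- assemblePanel(emptyFireCatalog(), cv, h, splitMonth = 700)
  specs <- makeDefaultSplineSpecs(cv[cv$t <= 700, ])
  des <- buildDesignMatrix(panel, h, specs, warnClamp = FALSE)
  p <- ncol(designMatrix(des))
  truth <- trueParameters("zinb", "lognormal", alphaMu = -7, alphaPi = -40,
                          betaMu = numeric(p), betaPi = numeric(p),
                          dispersion = 2, alphaSize = 4,
                          betaSize = numeric(p), aux = c(sdlog = 1))
  out <- simulateFires(panel, des, truth, seed = 15)
  a <- rep(unname(regionArea(h)), times = ncol(panel))
  mu <- a * exp(-7)
  n <- as.integer(panelCounts(out$panel))
  se <- sqrt(sum(mu + mu^2 / 2)) / length(mu)   # ZINB variance, pi = 0
  expect_lt(abs(mean(n) - mean(mu)), 3 * se)
  # lognormal exceedances: mean log size near alphaSize
  ly <- log(catalogEvents(out$catalog)$exceedance_ha)
  expect_lt(abs(mean(ly) - 4), 3 * 1 / sqrt(length(ly)))
})
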