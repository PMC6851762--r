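# half-Cauchy log pdf used by the cross-module reconstruction
hcPdf <- function(x, s) log(2 / pi) - log(s) - log1p((x / s)^2)

test_that("the sampler's joint density equals the module-composed one", {
  sim <- fixtureSim
  rows <- fireMEV:::.panelRowIdx(sim$panel, "train")
  X <- designMatrix(sim$design)[rows, ]
  y <- as.integer(panelCounts(sim$panel, "train"))
  tn <- sum(panelSplit(sim$panel) == "train")
  logOff <- rep(log(unname(regionArea(sim$hierarchy))), tn)
  ci <- columnInfo(sim$design)
  post <- fireMEV:::.buildCountPosterior(X, y, logOff, "zinb", ci)
  set.seed(11)
  theta <- post$init()
  u <- post$unpack(theta)
  hsIdx <- post$hsIdx; adjIdx <- post$adjIdx
  lvl <- match(ci$level[adjIdx], c("L1", "L2", "L3"))
  etaMu <- u$alphaMu + as.numeric(X %*% u$betaMu) + logOff
  etaPi <- u$alphaPi + as.numeric(X %*% u$betaPi)
  manual <- sum(countLogPmf("zinb", y, exp(etaMu), u$delta,
                            stats::plogis(etaPi))) +
    dnorm(u$alphaMu, 0, 5, log = TRUE) + dnorm(u$alphaPi, 0, 5, log = TRUE) +
    # paired horseshoe in non-centered coordinates: bivariate normal plus
    # the (z -> beta) change-of-variables terms
    pairedHorseshoeLogDensity(u$betaMu[hsIdx], u$betaPi[hsIdx], u$lambda,
                              u$tau, u$c, u$rho) +
    sum(2 * log(u$sHs)) + length(hsIdx) * 0.5 * log(1 - u$rho^2) +
    sum(hcPdf(u$lambda, 1) + log(u$lambda)) +
    hcPdf(u$tau, post$hyper$tauScale) + log(u$tau) +
    2 * log(8) - lgamma(2) - 3 * log(u$c^2) - 8 / u$c^2 + log(2 * u$c^2) +
    sum(dnorm(u$betaMu[adjIdx], 0, u$sigmaAdjMu[lvl], log = TRUE) +
          log(u$sigmaAdjMu[lvl])) +
    sum(dnorm(u$betaPi[adjIdx], 0, u$sigmaAdjPi[lvl], log = TRUE) +
          log(u$sigmaAdjPi[lvl])) +
    sum(dnorm(u$sigmaAdjMu, 0, 1, log = TRUE) + log(2) +
          log(u$sigmaAdjMu)) +
    sum(dnorm(u$sigmaAdjPi, 0, 1, log = TRUE) + log(2) +
          log(u$sigmaAdjPi)) +
    dnorm(log(u$delta), 0, 1.5, log = TRUE) +
    log(1 - u$rho^2) - log(2)
  expect_equal(post$lpGrad(theta)$value, manual, tolerance = 1e-10)
})

test_that("analytic gradients match central differences", {
  sim <- fixtureSim
  rows <- fireMEV:::.panelRowIdx(sim$panel, "train")
  X <- designMatrix(sim$design)[rows, ]
  y <- as.integer(panelCounts(sim$panel, "train"))
  tn <- sum(panelSplit(sim$panel) == "train")
  logOff <- rep(log(unname(regionArea(sim$hierarchy))), tn)
  ci <- columnInfo(sim$design)
  edgeIdx <- fireMEV:::.edgeIndexOf(sim$hierarchy)
  post <- fireMEV:::.buildCountPosterior(
    X, y, logOff, "zinb", ci, edgeIdx = edgeIdx, S = 12, Tn = tn,
    spatioTemporal = TRUE)
  set.seed(21)
  theta <- post$init()
  g <- post$lpGrad(theta)
  idx <- sort(sample(length(theta), 60))
  num <- fdGradient(post$lpGrad, theta, idx)
  expect_lt(max(abs(num - g$grad[idx]) / pmax(1, abs(num))), 1e-4)
  # size model
  evIdx <- fireMEV:::.eventCellIndex(sim$catalog, sim$panel)
  keep <- evIdx %in% rows
  Xe <- designMatrix(sim$design)[evIdx[keep], ]
  ye <- catalogEvents(sim$catalog)$exceedance_ha[keep]
  postS <- fireMEV:::.buildSizePosterior(Xe, ye, "lognormal", ci)
  set.seed(22)
  th2 <- postS$init()
  g2 <- postS$lpGrad(th2)
  idx2 <- sort(sample(length(th2), 60))
  num2 <- fdGradient(postS$lpGrad, th2, idx2)
  expect_lt(max(abs(num2 - g2$grad[idx2]) / pmax(1, abs(num2))), 1e-4)
})

test_that("HMC recovers a conjugate normal posterior", {
  set.seed(30)
  yObs <- rnorm(20, 1.4, 1)
  tau2 <- 4
  postVar <- 1 / (length(yObs) + 1 / tau2)
  postMean <- postVar * sum(yObs)
  lpGrad <- function(th) {
    list(value = -0.5 * sum((yObs - th)^2) - th^2 / (2 * tau2),
         grad = sum(yObs - th) - th / tau2)
  }
  res <- fireMEV:::.hmcSample(lpGrad, function() rnorm(1), chains = 2,
                              nIter = 1500, nWarmup = 500, seed = 77)
  d <- as.vector(res$theta)
  expect_lt(abs(mean(d) - postMean), 3 * sqrt(postVar) / sqrt(400))
  expect_lt(abs(sd(d) - sqrt(postVar)) / sqrt(postVar), 0.1)
})

test_that("fits are deterministic given seed and config", {
  sim <- fixtureSim
  cfg <- list(sim$panel, sim$design, "poisson")
  f1 <- fitCountModel(sim$panel, sim$design, "poisson", chains = 1,
                      iterations = 40, warmup = 20, seed = 9)
  f2 <- fitCountModel(sim$panel, sim$design, "poisson", chains = 1,
                      iterations = 40, warmup = 20, seed = 9)
  expect_identical(drawsArray(f1, "betaMu"), drawsArray(f2, "betaMu"))
  expect_identical(drawsArray(f1, "alphaMu"), drawsArray(f2, "alphaMu"))
})

test_that("the Laplace screening pass produces usable draws", {
  sim <- fixtureSim
  f <- fitCountModel(sim$panel, sim$design, "poisson", method = "laplace",
                     chains = 2, iterations = 150, warmup = 50, seed = 3)
  expect_true(all(is.finite(drawsMatrix(f, "betaMu"))))
  hl <- holdoutLogLik(f, sim$panel, sim$design)
  expect_true(is.finite(hl$mean))
})

test_that("spatiotemporal fits run and store the effect fields", {
  sim <- fixtureSim
  f <- fitCountModel(sim$panel, sim$design, "nb", hierarchy = sim$hierarchy,
                     chains = 1, iterations = 30, warmup = 15, seed = 5,
                     spatioTemporal = TRUE)
  tn <- sum(panelSplit(sim$panel) == "train")
  expect_equal(dim(drawsArray(f, "phiMu"))[3], 12 * tn)
  expect_true(all(is.finite(drawsArray(f, "phiMu"))))
  expect_true(all(abs(drawsMatrix(f, "arMu")) < 1))
})

test_that("split R-hat flags nonconvergence and passes iid chains", {
  mk <- function(a) {
    new("PosteriorDraws", draws = list(x = a),
        model = list(component = "count", family = "poisson"),
        seed = 1L, warmup = 0L, iterations = dim(a)[2],
        chains = dim(a)[1], method = "hmc", diagnostics = list())
  }
  set.seed(40)
  iid <- array(rnorm(4 * 500), c(4, 500, 1))
  r <- computeRhat(mk(iid))
  expect_lt(unname(r), 1.01)
  shifted <- iid
  shifted[1, , 1] <- shifted[1, , 1] + 10
  r2 <- computeRhat(mk(shifted))
  expect_gte(unname(r2), 1.1)
  expect_true("x" %in% attr(r2, "flagged"))
  const <- array(1, c(4, 500, 1))
  r3 <- computeRhat(mk(const))
  expect_true(!is.finite(unname(r3)))
  expect_true("x" %in% attr(r3, "flagged"))
  one <- array(rnorm(500), c(1, 500, 1))
  expect_error(computeRhat(mk(one)), "2 chains")
})

test_that("holdout log likelihood matches a direct sum for a single draw", {
  sim <- fixtureSim
  fit1 <- truthCountDraws(sim, nDraws = 1L, chains = 1L)
  hl <- holdoutLogLik(fit1, sim$panel, sim$design)
  expect_equal(hl$sd, 0)
  y <- as.integer(panelCounts(sim$panel, "test"))
  rows <- fireMEV:::.panelRowIdx(sim$panel, "test")
  X <- designMatrix(sim$design)[rows, ]
  tr <- sim$truth
  a <- rep(unname(regionArea(sim$hierarchy)),
           sum(panelSplit(sim$panel) == "test"))
  mu <- a * exp(tr@alphaMu + as.numeric(X %*% tr@betaMu))
  pi <- plogis(tr@alphaPi + as.numeric(X %*% tr@betaPi))
  expect_equal(hl$mean, sum(countLogPmf("zinb", y, mu, tr@dispersion, pi)),
               tolerance = 1e-10)
  # a duplicated draw set keeps the same mean and sd
  fit5 <- truthCountDraws(sim, nDraws = 5L, chains = 2L)
  hl5 <- holdoutLogLik(fit5, sim$panel, sim$design)
  expect_equal(hl5$mean, hl$mean, tolerance = 1e-10)
  expect_equal(hl5$sd, 0)
})

test_that("posterior predictive replicates have the model's cell means", {
  sim <- fixtureSim
  fit <- truthCountDraws(sim, nDraws = 300L, chains = 2L)
  rep <- posteriorPredict(fit, sim$panel, sim$design, split = "test",
                          seed = 8)
  tr <- sim$truth
  rows <- fireMEV:::.panelRowIdx(sim$panel, "test")
  X <- designMatrix(sim$design)[rows, ]
  a <- rep(unname(regionArea(sim$hierarchy)),
           sum(panelSplit(sim$panel) == "test"))
  mu <- a * exp(tr@alphaMu + as.numeric(X %*% tr@betaMu))
  pi <- plogis(tr@alphaPi + as.numeric(X %*% tr@betaPi))
  m <- (1 - pi) * mu
  v <- (1 - pi) * (mu + mu^2 / tr@dispersion) + pi * (1 - pi) * mu^2
  D <- nrow(rep)
  pooledSe <- sqrt(sum(v) / D) / length(mu)
  expect_lt(abs(mean(colMeans(rep)) - mean(m)), 3 * pooledSe)
  # seeded determinism
  rep2 <- posteriorPredict(fit, sim$panel, sim$design, split = "test",
                           seed = 8)
  expect_identical(rep, rep2)
  # certain zero inflation replicates all zeros
  fitZero <- truthCountDraws(sim, nDraws = 10L)
  fitZero@draws$alphaPi[] <- 40
  expect_true(all(posteriorPredict(fitZero, sim$panel, sim$design,
                                   split = "test", seed = 1) == 0))
})
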