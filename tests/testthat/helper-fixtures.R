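# Shared fixtures, built once per test run.

# small end-to-end synthetic study (12 regions, 24 months)
fixtureSim <- simulateWildfireData(seed = 42, nMonths = 24)

# central-difference gradient of a scalar-valued lpGrad closure
fdGradient <- function(lpGrad, theta, idx, h = 1e-5) {
  vapply(idx, function(i) {
    e <- numeric(length(theta)); e[i] <- h
    (lpGrad(theta + e)$value - lpGrad(theta - e)$value) / (2 * h)
  }, 0.0)
}

# PosteriorDraws object whose draws all equal the generative truth;
# lets predictive machinery be exercised against known parameters
truthCountDraws <- function(sim, nDraws = 200L, chains = 2L) {
  truth <- sim$truth
  p <- length(truth@betaMu)
  rep3 <- function(v) {
    array(rep(v, each = chains * nDraws), c(chains, nDraws, length(v)))
  }
  new("PosteriorDraws",
      draws = list(alphaMu = rep3(truth@alphaMu), betaMu = rep3(truth@betaMu),
                   delta = rep3(truth@dispersion),
                   alphaPi = rep3(truth@alphaPi), betaPi = rep3(truth@betaPi)),
      model = list(component = "count", family = truth@countFamily,
                   spatioTemporal = FALSE, S = nrow(sim$panel),
                   trainT = SummarizedExperiment::colData(sim$panel)$t[
                     panelSplit(sim$panel) == "train"]),
      seed = 1L, warmup = 0L, iterations = nDraws, chains = chains,
      method = "hmc", diagnostics = list())
}

truthSizeDraws <- function(sim, nDraws = 200L, chains = 2L) {
  truth <- sim$truth
  rep3 <- function(v) {
    array(rep(v, each = chains * nDraws), c(chains, nDraws, length(v)))
  }
  aux <- truth@aux
  auxFree <- aux[setdiff(names(aux), "y0")]
  new("PosteriorDraws",
      draws = list(alpha = rep3(truth@alphaSize), beta = rep3(truth@betaSize),
                   aux = rep3(unname(auxFree))),
      model = list(component = "size", family = truth@sizeFamily,
                   spatioTemporal = FALSE, S = nrow(sim$panel),
                   y0 = unname(aux["y0"] %||% 1),
                   auxNames = setdiff(names(aux), "y0"),
                   trainT = SummarizedExperiment::colData(sim$panel)$t[
                     panelSplit(sim$panel) == "train"]),
      seed = 1L, warmup = 0L, iterations = nDraws, chains = chains,
      method = "hmc", diagnostics = list())
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a
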