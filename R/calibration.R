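#' @include recovery.R extremes.R
NULL

## PosteriorDraws whose draws all equal the generative truth
.truthDraws <- function(sim, component, nDraws, chains = 2L) {
  truth <- sim$truth
  rep3 <- function(v) {
    array(rep(v, each = chains * nDraws), c(chains, nDraws, length(v)))
  }
  trainT <- SummarizedExperiment::colData(sim$panel)$t[
    panelSplit(sim$panel) == "train"]
  if (component == "count") {
    new("PosteriorDraws",
        draws = list(alphaMu = rep3(truth@alphaMu),
                     betaMu = rep3(truth@betaMu),
                     delta = rep3(truth@dispersion),
                     alphaPi = rep3(truth@alphaPi),
                     betaPi = rep3(truth@betaPi)),
        model = list(component = "count", family = truth@countFamily,
                     spatioTemporal = FALSE, S = nrow(sim$panel),
                     trainT = trainT),
        seed = 1L, warmup = 0L, iterations = as.integer(nDraws),
        chains = as.integer(chains), method = "hmc", diagnostics = list())
  } else {
    aux <- truth@aux
    free <- setdiff(names(aux), "y0")
    new("PosteriorDraws",
        draws = list(alpha = rep3(truth@alphaSize),
                     beta = rep3(truth@betaSize),
                     aux = rep3(unname(aux[free]))),
        model = list(component = "size", family = truth@sizeFamily,
                     spatioTemporal = FALSE, S = nrow(sim$panel),
                     y0 = if ("y0" %in% names(aux)) unname(aux["y0"]) else 1,
                     auxNames = free, trainT = trainT),
        seed = 1L, warmup = 0L, iterations = as.integer(nDraws),
        chains = as.integer(chains), method = "hmc", diagnostics = list())
  }
}

#' Predictive-interval calibration under the generative truth
#'
#' Simulates a study, builds predictive distributions from the true
#' (generative) parameters, and audits interval coverage on the held-out
#' block: central 95\% intervals for test-month counts and for test-event
#' exceedance sizes, and 99\% finite-sample-maxima intervals for the
#' monthly burned-area maximum in cells with at least one fire.  Under
#' the truth all three should achieve their nominal level up to binomial
#' noise — the self-consistency counterpart of the holdout coverage
#' audit.
#'
#' @param seed integer seed.
#' @param nDraws predictive draws per check (default 400).
#' @param level,maximaLevel interval levels (defaults 0.95 and 0.99).
#' @return list with countCoverage, sizeCoverage, maximaCoverage and the
#'   unit counts behind each.
#' @export
calibrationExperiment <- function(seed = 1L, nDraws = 400L, level = 0.95,
                                  maximaLevel = 0.99) {
  sim <- simulateWildfireData(seed = seed)
  fitC <- .truthDraws(sim, "count", nDraws)
  fitS <- .truthDraws(sim, "size", nDraws)
  ## counts on the test block
  yTest <- as.integer(panelCounts(sim$panel, "test"))
  repC <- posteriorPredict(fitC, sim$panel, sim$design, split = "test",
                           seed = seed + 1L)
  covC <- intervalCoverage(repC, yTest, level)
  ## event sizes on the test block
  idx <- .eventCellIndex(sim$catalog, sim$panel)
  testCells <- .panelRowIdx(sim$panel, "test")
  inTest <- idx %in% testCells
  ySize <- catalogEvents(sim$catalog)$exceedance_ha[inTest]
  repS <- posteriorPredict(fitS, sim$panel, sim$design,
                           catalog = sim$catalog, split = "test",
                           seed = seed + 2L)
  covS <- intervalCoverage(repS, ySize, level)
  ## monthly maxima, conditional on fires having occurred
  spTest <- sizeParamsAt(fitS, sim$panel, sim$design, split = "test")
  iv <- maximaInterval(repC, spTest, level = maximaLevel)
  obsMax <- vapply(seq_along(testCells), function(j) {
    v <- ySize[idx[inTest] == testCells[j]]
    if (length(v)) max(v) else NA_real_
  }, 0.0)
  use <- which(!is.na(obsMax) & !iv$noFire)
  covM <- mean(obsMax[use] >= iv$lower[use] & obsMax[use] <= iv$upper[use])
  list(countCoverage = covC$coverage, nCountUnits = length(yTest),
       sizeCoverage = covS$coverage, nSizeUnits = length(ySize),
       maximaCoverage = covM, nMaximaUnits = length(use))
}
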