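#' @include posterior.R hmc.R
NULL

.edgeIndexOf <- function(hierarchy) {
  matrix(match(adjacencyEdges(hierarchy), l3Regions(hierarchy)), ncol = 2)
}

.panelRowIdx <- function(panel, split) {
  s <- nrow(panel)
  cols <- .splitCols(panel, split)
  as.vector(outer(seq_len(s), (cols - 1L) * s, "+"))
}

## pack a (chains, iter, npar) theta array into named constrained arrays
.packDraws <- function(theta, unpack, keepNames) {
  dth <- dim(theta)
  first <- unpack(theta[1, 1, ])
  keepNames <- intersect(keepNames, names(first))
  out <- lapply(keepNames, function(nm) {
    array(NA_real_, c(dth[1], dth[2], length(first[[nm]])))
  })
  names(out) <- keepNames
  for (ch in seq_len(dth[1])) {
    for (it in seq_len(dth[2])) {
      u <- unpack(theta[ch, it, ])
      for (nm in keepNames) out[[nm]][ch, it, ] <- as.vector(u[[nm]])
    }
  }
  out
}

.runSampler <- function(post, method, chains, iterations, warmup, seed,
                        control) {
  if (method == "hmc") {
    .hmcSample(post$lpGrad, post$init, chains, iterations, warmup, seed,
               control)
  } else {
    .laplaceSample(post$lpGrad, post$init, chains, iterations - warmup, seed)
  }
}

#' Fit a fire-occurrence count model
#'
#' Samples the joint posterior of the chosen count family on the panel's
#' training months: paired (for zero-inflated families) or univariate
#' regularized-horseshoe priors on the spline coefficients, hierarchical
#' normal priors on the region intercept adjustments, and optionally
#' AR(1) x ICAR spatiotemporal effects.  \code{method = "hmc"} runs the
#' package's adaptive Hamiltonian Monte Carlo sampler; \code{"laplace"}
#' is the fast Gaussian screening approximation used to shortlist count
#' families before committing to full MCMC.
#'
#' @param panel a \linkS4class{SpaceTimePanel}.
#' @param design the \linkS4class{DesignMatrix} built on the full panel.
#' @param family "poisson", "nb", "zip" or "zinb".
#' @param hierarchy the \linkS4class{EcoregionHierarchy} (needed when
#'   \code{spatioTemporal = TRUE}).
#' @param method "hmc" or "laplace".
#' @param chains,iterations,warmup sampler configuration; defaults mirror
#'   four chains of 1,000 iterations with the first 500 discarded as
#'   warmup.
#' @param seed integer seed (drives initialization and sampling).
#' @param spatioTemporal include the AR(1) x ICAR effects (default FALSE).
#' @param hyper named overrides of the prior hyperparameters (p0,
#'   tauScale, slabShape, slabRate, alphaSd, auxLogSd, adjScaleSd,
#'   phiTauSd).
#' @param control sampler control overrides (targetAccept, maxSteps,
#'   initStepSize, ...).
#' @return a \linkS4class{PosteriorDraws} with parameters alphaMu, betaMu
#'   (full design length), tau, c, and family-dependent delta, alphaPi,
#'   betaPi, rho, phiMu/phiPi, arMu/arPi, tauPhiMu/tauPhiPi.
#' @export
fitCountModel <- function(panel, design, family, hierarchy = NULL,
                          method = c("hmc", "laplace"), chains = 4L,
                          iterations = 1000L, warmup = 500L, seed = 1L,
                          spatioTemporal = FALSE, hyper = list(),
                          control = list()) {
  method <- match.arg(method)
  stopifnot(is(panel, "SpaceTimePanel"), is(design, "DesignMatrix"))
  rows <- .panelRowIdx(panel, "train")
  X <- designMatrix(design)[rows, , drop = FALSE]
  y <- as.integer(panelCounts(panel, "train"))
  s <- nrow(panel)
  trainCols <- .splitCols(panel, "train")
  logOffset <- rep(log(SummarizedExperiment::rowData(panel)$area),
                   times = length(trainCols))
  edgeIdx <- NULL
  if (spatioTemporal) {
    if (is.null(hierarchy)) stop("spatioTemporal fits need the hierarchy")
    edgeIdx <- .edgeIndexOf(hierarchy)
  }
  post <- .buildCountPosterior(X, y, logOffset, family,
                               columnInfo(design), edgeIdx = edgeIdx,
                               S = s, Tn = length(trainCols),
                               spatioTemporal = spatioTemporal,
                               hyper = hyper)
  res <- .runSampler(post, method, chains, iterations, warmup, seed, control)
  keep <- c("alphaMu", "betaMu", "tau", "c", "delta", "alphaPi", "betaPi",
            "rho", "phiMu", "tauPhiMu", "arMu", "phiPi", "tauPhiPi", "arPi")
  draws <- .packDraws(res$theta, post$unpack, keep)
  new("PosteriorDraws", draws = draws,
      model = list(component = "count", family = family,
                   spatioTemporal = spatioTemporal, hyper = post$hyper,
                   S = s, trainT = SummarizedExperiment::colData(panel)$t[trainCols]),
      seed = as.integer(seed), warmup = as.integer(warmup),
      iterations = as.integer(iterations - warmup),
      chains = as.integer(chains), method = method,
      diagnostics = res$diagnostics)
}

#' Fit a burned-area exceedance model
#'
#' Samples the posterior of the chosen size family over the training-set
#' events: a univariate regularized horseshoe on the spline coefficients,
#' hierarchical normal region adjustments, a weakly informative lognormal
#' prior on the auxiliary scalar, and optionally AR(1) x ICAR effects at
#' the event cells.
#'
#' @param catalog a \linkS4class{FireCatalog}; only events in training
#'   months are used.
#' @param panel,design as in \code{\link{fitCountModel}}.
#' @param family one of \code{\link{sizeFamilies}()}.
#' @param y0 tapered-Pareto lower bound on the exceedance scale (default
#'   1 ha); ignored by other families.
#' @inheritParams fitCountModel
#' @return a \linkS4class{PosteriorDraws} with parameters alpha, beta,
#'   aux, tau, c (and phi, tauPhi, ar for spatiotemporal fits).
#' @export
fitSizeModel <- function(catalog, panel, design, family, hierarchy = NULL,
                         method = c("hmc", "laplace"), chains = 4L,
                         iterations = 1000L, warmup = 500L, seed = 1L,
                         spatioTemporal = FALSE, hyper = list(),
                         control = list(), y0 = 1) {
  method <- match.arg(method)
  stopifnot(is(catalog, "FireCatalog"), is(panel, "SpaceTimePanel"))
  idx <- .eventCellIndex(catalog, panel)
  trainCells <- .panelRowIdx(panel, "train")
  inTrain <- idx %in% trainCells
  if (!any(inTrain)) stop("no training events")
  cellIdx <- idx[inTrain]
  X <- designMatrix(design)[cellIdx, , drop = FALSE]
  y <- catalogEvents(catalog)$exceedance_ha[inTrain]
  s <- nrow(panel)
  trainCols <- .splitCols(panel, "train")
  edgeIdx <- NULL; stCellIdx <- NULL
  if (spatioTemporal) {
    if (is.null(hierarchy)) stop("spatioTemporal fits need the hierarchy")
    edgeIdx <- .edgeIndexOf(hierarchy)
    stCellIdx <- match(cellIdx, trainCells)
  }
  post <- .buildSizePosterior(X, y, family, columnInfo(design),
                              cellIndex = stCellIdx, edgeIdx = edgeIdx,
                              S = s, Tn = length(trainCols),
                              spatioTemporal = spatioTemporal,
                              hyper = hyper, y0 = y0)
  res <- .runSampler(post, method, chains, iterations, warmup, seed, control)
  keep <- c("alpha", "beta", "aux", "tau", "c", "phi", "tauPhi", "ar")
  draws <- .packDraws(res$theta, post$unpack, keep)
  new("PosteriorDraws", draws = draws,
      model = list(component = "size", family = family,
                   spatioTemporal = spatioTemporal, hyper = post$hyper,
                   y0 = y0, S = s,
                   trainT = SummarizedExperiment::colData(panel)$t[trainCols],
                   auxNames = .sizeAuxNames[[family]]),
      seed = as.integer(seed), warmup = as.integer(warmup),
      iterations = as.integer(iterations - warmup),
      chains = as.integer(chains), method = method,
      diagnostics = res$diagnostics)
}

## flattened cell index of each catalog event within the panel grid
.eventCellIndex <- function(catalog, panel) {
  ev <- catalogEvents(catalog)
  rd <- SummarizedExperiment::rowData(panel)
  cd <- SummarizedExperiment::colData(panel)
  sIdx <- match(ev$l3, rd$l3)
  tIdx <- match(paste(ev$year, ev$month), paste(cd$year, cd$month))
  bad <- is.na(sIdx) | is.na(tIdx)
  if (any(bad)) {
    stop("events outside the panel: ",
         paste(utils::head(ev$event_id[bad], 10), collapse = ", "))
  }
  (tIdx - 1L) * nrow(panel) + sIdx
}
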