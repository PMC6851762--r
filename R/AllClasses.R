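#' @import methods
#' @importFrom Matrix sparseMatrix rowSums colSums t crossprod
#' @importClassesFrom Matrix dgCMatrix
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   assayNames rowData colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats rnorm runif quantile var sd
#' @importFrom utils head write.csv read.csv
NULL

## Cell ordering convention used throughout: the (s, t) grid is flattened with
## space varying fastest, i.e. cell index (t - 1) * S + s.  Linear predictors,
## offsets, spatiotemporal effects and design-matrix rows all share this order.

#' Nested ecoregion hierarchy with adjacency
#'
#' Three-level nesting (L3 within L2 within L1) of spatial analysis units,
#' an undirected adjacency graph over the finest (L3) level, and L3 areas
#' in square kilometres.  The adjacency graph must be connected: the
#' intrinsic CAR prior uses a single sum-to-zero constraint, which is only
#' identifying on a connected graph.
#'
#' @slot l3 character vector of L3 region identifiers (the spatial units).
#' @slot l2ByL3 named character vector mapping each L3 id to its L2 parent.
#' @slot l1ByL2 named character vector mapping each L2 id to its L1 parent.
#' @slot edges two-column character matrix; each row one unordered L3 pair.
#' @slot area named numeric vector of positive L3 areas (km^2).
#'
#' @exportClass EcoregionHierarchy
setClass("EcoregionHierarchy",
  representation(
    l3 = "character",
    l2ByL3 = "character",
    l1ByL2 = "character",
    edges = "matrix",
    area = "numeric"
  )
)

setValidity("EcoregionHierarchy", function(object) {
  msg <- character()
  l3 <- object@l3
  if (anyDuplicated(l3)) msg <- c(msg, "duplicated L3 ids")
  if (!setequal(names(object@l2ByL3), l3)) {
    msg <- c(msg, "l2ByL3 must be named by exactly the L3 ids")
  }
  if (!all(object@l2ByL3 %in% names(object@l1ByL2))) {
    msg <- c(msg, "every L2 parent must appear in l1ByL2")
  }
  if (!setequal(names(object@area), l3) || any(object@area <= 0)) {
    msg <- c(msg, "areas must be named by L3 ids and strictly positive")
  }
  e <- object@edges
  if (nrow(e) > 0) {
    if (ncol(e) != 2) msg <- c(msg, "edges must have two columns")
    else {
      if (!all(e %in% l3)) msg <- c(msg, "edge endpoints must be L3 ids")
      if (any(e[, 1] == e[, 2])) msg <- c(msg, "self-loops not allowed")
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
    }
  }
  if (length(l3) > 1 && !.graphConnected(l3, e)) {
    msg <- c(msg, "adjacency graph must be connected")
  }
  if (length(msg)) msg else TRUE
})

## breadth-first search connectivity used by the validity method
.graphConnected <- function(nodes, edges) {
  if (length(nodes) <= 1) return(TRUE)
  if (nrow(edges) == 0) return(FALSE)
  nbr <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  seen <- structure(logical(length(nodes)), names = nodes)
  queue <- nodes[1]
  seen[queue] <- TRUE
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    nx <- nbr[[cur]]
    nx <- nx[!seen[nx]]
    if (length(nx)) { seen[nx] <- TRUE; queue <- c(queue, nx) }
  }
  all(seen)
}

#' Fire event catalog
#'
#' Event-level records of fires whose burned area exceeds a fixed size
#' threshold.  `exceedance_ha` is the burned area minus the threshold and is
#' strictly positive by construction; all five burned-area likelihoods are
#' supported on positive exceedances.
#'
#' @slot events data.frame with columns event_id, year, month, l3,
#'   size_ha, exceedance_ha.
#' @slot thresholdHa the size threshold (ha) already applied.
#'
#' @exportClass FireCatalog
setClass("FireCatalog",
  representation(events = "data.frame", thresholdHa = "numeric")
)

setValidity("FireCatalog", function(object) {
  msg <- character()
  need <- c("event_id", "year", "month", "l3", "size_ha", "exceedance_ha")
  if (!all(need %in% names(object@events))) {
    msg <- c(msg, paste("events needs columns:", paste(need, collapse = ", ")))
  } else {
    ev <- object@events
    if (nrow(ev)) {
      if (any(ev$size_ha <= object@thresholdHa)) {
        msg <- c(msg, "all retained sizes must exceed the threshold")
      }
      if (any(ev$exceedance_ha <= 0)) msg <- c(msg, "exceedances must be > 0")
      if (any(ev$month < 1 | ev$month > 12)) msg <- c(msg, "month outside 1..12")
    }
  }
  if (length(object@thresholdHa) != 1 || object@thresholdHa < 0) {
    msg <- c(msg, "thresholdHa must be a single nonnegative number")
  }
  if (length(msg)) msg else TRUE
})

#' Space-time panel of counts, covariates and offsets
#'
#' A complete S x T (region x month) grid stored as a
#' \linkS4class{SummarizedExperiment}: rows are L3 regions, columns are
#' months.  Assays hold the fire count and the six model covariates
#' (humidity \%, air temperature, same-month precipitation, prior-12-month
#' precipitation, wind speed, housing density in units/km^2); `rowData`
#' carries the hierarchy labels and the offset area; `colData` carries
#' (year, month, t) and the train/test split label, which is constant
#' within a month (a time cut).
#'
#' @exportClass SpaceTimePanel
setClass("SpaceTimePanel", contains = "SummarizedExperiment")

.panelCovariateNames <- c("humidity", "temperature", "precipitation",
                          "precip12", "wind", "housing")

setValidity("SpaceTimePanel", function(object) {
  msg <- character()
  an <- SummarizedExperiment::assayNames(object)
  need <- c("counts", .panelCovariateNames)
  if (!all(need %in% an)) {
    msg <- c(msg, paste("missing assays:", paste(setdiff(need, an), collapse = ", ")))
  }
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("l3", "l2", "l1", "area") %in% names(rd))) {
    msg <- c(msg, "rowData needs l3, l2, l1, area")
  } else if (any(rd$area <= 0)) msg <- c(msg, "offset areas must be positive")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("year", "month", "t", "split") %in% names(cd))) {
    msg <- c(msg, "colData needs year, month, t, split")
  } else {
    if (!all(cd$split %in% c("train", "test"))) {
      msg <- c(msg, "split labels must be 'train' or 'test'")
    }
    if (is.unsorted(cd$t) || anyDuplicated(cd$t)) {
      msg <- c(msg, "time index t must be strictly increasing")
    }
    ## split must be a time cut: no train month after the first test month
    if (any(cd$split == "test") &&
        any(cd$t[cd$split == "train"] > min(cd$t[cd$split == "test"]))) {
      msg <- c(msg, "split must be a time cut (train months precede test months)")
    }
  }
  if ("counts" %in% an) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0) || any(cnt != round(cnt))) {
      msg <- c(msg, "counts must be nonnegative integers")
    }
  }
  if (length(msg)) msg else TRUE
})

#' B-spline specification for one covariate
#'
#' Boundary knots at the training minimum/maximum, interior knots at equally
#' spaced training quantiles, basis dimension `df` whose span includes the
#' constant function.  Values outside the boundary are clamped before
#' evaluation (bounded extrapolation).
#'
#' @slot covariate covariate name.
#' @slot df basis dimension (default 5, intercept included in the span).
#' @slot degree polynomial degree (default 3, cubic).
#' @slot boundary length-2 numeric, training min and max (after transform).
#' @slot interior strictly increasing interior knots inside the boundary.
#' @slot logTransform whether the covariate is log-transformed first
#'   (TRUE for housing density).
#'
#' @exportClass SplineSpec
setClass("SplineSpec",
  representation(
    covariate = "character", df = "integer", degree = "integer",
    boundary = "numeric", interior = "numeric", logTransform = "logical"
  )
)

setValidity("SplineSpec", function(object) {
  msg <- character()
  if (object@df < 2) msg <- c(msg, "df must be >= 2")
  if (object@degree < 1) msg <- c(msg, "degree must be >= 1")
  if (length(object@boundary) != 2 || diff(object@boundary) <= 0) {
    msg <- c(msg, "boundary must be two increasing values")
  }
  k <- object@interior
  if (length(k)) {
    if (is.unsorted(k, strictly = TRUE)) msg <- c(msg, "interior knots must increase")
    if (any(k <= object@boundary[1]) || any(k >= object@boundary[2])) {
      msg <- c(msg, "interior knots must lie strictly inside the boundary")
    }
  }
  if (object@df != length(k) + object@degree + 1) {
    msg <- c(msg, "df must equal #interior + degree + 1")
  }
  if (length(msg)) msg else TRUE
})

#' Sparse design matrix with per-column metadata
#'
#' Columns are: the B global basis vectors (B = sum of the six spline df),
#' then one masked copy of the global block per hierarchy unit (L1 blocks,
#' then L2, then L3; each copy zeroed outside the unit's rows), then one
#' intercept-adjustment indicator column per unit.  With R hierarchy units
#' in total, p = B(1 + R) + R.
#'
#' @slot X sparse matrix, (S*T) x p for count models or (events) x p for
#'   size models.
#' @slot columnInfo data.frame with one row per column: covariate (or
#'   "intercept-adjustment"), basis_index (NA for indicators), level
#'   ("global", "L1", "L2", "L3"), region (NA for global columns).
#' @slot specs list of the six \linkS4class{SplineSpec} objects used.
#'
#' @exportClass DesignMatrix
setClass("DesignMatrix",
  representation(X = "dgCMatrix", columnInfo = "data.frame", specs = "list")
)

setValidity("DesignMatrix", function(object) {
  msg <- character()
  if (nrow(object@columnInfo) != ncol(object@X)) {
    msg <- c(msg, "columnInfo must have one row per column of X")
  }
  need <- c("covariate", "basis_index", "level", "region")
  if (!all(need %in% names(object@columnInfo))) {
    msg <- c(msg, paste("columnInfo needs:", paste(need, collapse = ", ")))
  } else if (!all(object@columnInfo$level %in% c("global", "L1", "L2", "L3"))) {
    msg <- c(msg, "level must be one of global, L1, L2, L3")
  }
  if (length(msg)) msg else TRUE
})

#' Generative ("true") parameters for the synthetic-data module
#'
#' Parameters of the data-generating model: intercepts and sparse
#' coefficient vectors on the count mean (log link) and, for zero-inflated
#' families, on the structural-zero probability (logit link); NB
#' dispersion; the burned-area family with its intercept, coefficients and
#' auxiliary scalar(s); and the AR(1) x ICAR spatiotemporal effect
#' hyperparameters.
#'
#' @slot countFamily one of "poisson", "nb", "zip", "zinb".
#' @slot sizeFamily one of "lognormal", "gamma", "weibull", "gpd_lomax",
#'   "tapered_pareto".
#' @slot alphaMu,alphaPi scalar intercepts (log-mean; logit zero-inflation).
#' @slot betaMu,betaPi coefficient vectors (length p; mostly zero).
#' @slot dispersion NB dispersion delta > 0 (variance mu + mu^2/delta).
#' @slot alphaSize,betaSize size-model intercept and coefficients.
#' @slot aux named numeric of size-family auxiliary scalar(s) (e.g. sdlog,
#'   shape, theta/y0).
#' @slot arCoef AR(1) coefficient in (-1, 1).
#' @slot icarScale spatial innovation scale >= 0 (0 disables the effects).
#'
#' @exportClass TrueParameters
setClass("TrueParameters",
  representation(
    countFamily = "character", sizeFamily = "character",
    alphaMu = "numeric", alphaPi = "numeric",
    betaMu = "numeric", betaPi = "numeric",
    dispersion = "numeric",
    alphaSize = "numeric", betaSize = "numeric", aux = "numeric",
    arCoef = "numeric", icarScale = "numeric"
  )
)

setValidity("TrueParameters", function(object) {
  msg <- character()
  if (!object@countFamily %in% c("poisson", "nb", "zip", "zinb")) {
    msg <- c(msg, "unknown count family")
  }
  if (!object@sizeFamily %in% c("lognormal", "gamma", "weibull",
                                "gpd_lomax", "tapered_pareto")) {
    msg <- c(msg, "unknown size family")
  }
  if (object@countFamily %in% c("nb", "zinb") && object@dispersion <= 0) {
    msg <- c(msg, "dispersion must be > 0")
  }
  if (length(object@betaPi) && length(object@betaMu) &&
      length(object@betaPi) != length(object@betaMu)) {
    msg <- c(msg, "betaMu and betaPi must have equal length")
  }
  if (any(object@aux <= 0)) msg <- c(msg, "aux scalars must be > 0")
  if (abs(object@arCoef) >= 1) msg <- c(msg, "arCoef must be in (-1, 1)")
  if (object@icarScale < 0) msg <- c(msg, "icarScale must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Posterior draws from a fitted model
#'
#' Named parameter draws indexed by (chain, iteration), together with the
#' model description and sampler metadata needed to reproduce the run.
#'
#' @slot draws named list; each element an array with dim
#'   (chains, iterations, parameter dimension).
#' @slot model list describing the fitted model (component, family, design
#'   column info, hyperparameters, ...).
#' @slot seed,warmup,iterations,chains sampler metadata; `iterations` is the
#'   number of post-warmup draws retained per chain.
#' @slot method sampling method used ("hmc" or "laplace").
#' @slot diagnostics list of sampler diagnostics (acceptance rates, ...).
#'
#' @exportClass PosteriorDraws
setClass("PosteriorDraws",
  representation(
    draws = "list", model = "list",
    seed = "integer", warmup = "integer", iterations = "integer",
    chains = "integer", method = "character", diagnostics = "list"
  )
)

setValidity("PosteriorDraws", function(object) {
  msg <- character()
  if (is.null(names(object@draws)) || any(names(object@draws) == "")) {
    msg <- c(msg, "draws must be a fully named list")
  }
  for (nm in names(object@draws)) {
    a <- object@draws[[nm]]
    if (!is.array(a) || length(dim(a)) != 3) {
      msg <- c(msg, sprintf("draws[['%s']] must be a 3-d array", nm)); next
    }
    if (any(!is.finite(a))) msg <- c(msg, sprintf("non-finite draws in '%s'", nm))
    if (dim(a)[1] != object@chains || dim(a)[2] != object@iterations) {
      msg <- c(msg, sprintf("draws[['%s']] dims disagree with metadata", nm))
    }
  }
  if (length(msg)) msg else TRUE
})
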