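#' @include AllClasses.R
NULL

#' Accessors for the ecoregion hierarchy
#'
#' @param x an \linkS4class{EcoregionHierarchy}.
#' @return \code{l3Regions}: character vector of L3 ids; \code{l2Of},
#'   \code{l1Of}: named parent lookups; \code{regionArea}: named areas;
#'   \code{adjacencyEdges}: two-column character matrix of unordered L3
#'   pairs; \code{adjacencyMatrix}: symmetric 0/1 sparse matrix;
#'   \code{nRegions}: named vector with the number of L1, L2 and L3 units.
#' @aliases l3Regions l2Of l1Of regionArea adjacencyEdges adjacencyMatrix
#'   nRegions
#' @name hierarchy-accessors
NULL

#' @rdname hierarchy-accessors
#' @export
l3Regions <- function(x) x@l3

#' @rdname hierarchy-accessors
#' @param l3 L3 region id(s).
#' @export
l2Of <- function(x, l3) unname(x@l2ByL3[l3])

#' @rdname hierarchy-accessors
#' @export
l1Of <- function(x, l3) unname(x@l1ByL2[x@l2ByL3[l3]])

#' @rdname hierarchy-accessors
#' @export
regionArea <- function(x) x@area[x@l3]

#' @rdname hierarchy-accessors
#' @export
adjacencyEdges <- function(x) x@edges

#' @rdname hierarchy-accessors
#' @export
adjacencyMatrix <- function(x) {
  s <- length(x@l3)
  idx <- match(x@edges, x@l3)
  dim(idx) <- dim(x@edges)
  A <- Matrix::sparseMatrix(
    i = c(idx[, 1], idx[, 2]), j = c(idx[, 2], idx[, 1]),
    x = 1, dims = c(s, s), dimnames = list(x@l3, x@l3)
  )
  A
}

#' @rdname hierarchy-accessors
#' @export
nRegions <- function(x) {
  c(L1 = length(unique(x@l1ByL2)), L2 = length(unique(x@l2ByL3)),
    L3 = length(x@l3))
}

setMethod("show", "EcoregionHierarchy", function(object) {
  n <- nRegions(object)
  cat(sprintf("EcoregionHierarchy: %d L3 in %d L2 in %d L1; %d adjacency edges\n",
              n["L3"], n["L2"], n["L1"], nrow(object@edges)))
})

#' Accessors for fire catalogs
#'
#' @param x a \linkS4class{FireCatalog}.
#' @return \code{catalogEvents}: the event data.frame; \code{sizeThreshold}:
#'   the threshold (ha) applied to it.
#' @aliases catalogEvents sizeThreshold
#' @name catalog-accessors
NULL

#' @rdname catalog-accessors
#' @export
catalogEvents <- function(x) x@events

#' @rdname catalog-accessors
#' @export
sizeThreshold <- function(x) x@thresholdHa

setMethod("show", "FireCatalog", function(object) {
  cat(sprintf("FireCatalog: %d events over %.0f ha", nrow(object@events),
              object@thresholdHa))
  if (nrow(object@events)) {
    cat(sprintf(" in %d regions, years %d-%d",
                length(unique(object@events$l3)),
                min(object@events$year), max(object@events$year)))
  }
  cat("\n")
})

setMethod("length", "FireCatalog", function(x) nrow(x@events))

#' Accessors for the space-time panel
#'
#' The panel rows are L3 regions and columns are months; flattening uses
#' the package-wide cell order (space fastest: cell = (t-1)*S + s).
#'
#' @param x a \linkS4class{SpaceTimePanel}.
#' @param name a covariate name (one of humidity, temperature,
#'   precipitation, precip12, wind, housing).
#' @param split optional subset: "train", "test" or NULL for all months.
#' @return \code{panelCounts}: S x T integer matrix; \code{panelCovariate}:
#'   S x T numeric matrix; \code{panelOffset}: length-S vector of areas;
#'   \code{panelSplit}: per-month labels; \code{flattenPanel}: data.frame
#'   with one row per cell in flattened order.
#' @aliases panelCounts panelCovariate panelOffset panelSplit flattenPanel
#' @name panel-accessors
NULL

#' @rdname panel-accessors
#' @export
panelCounts <- function(x, split = NULL) {
  m <- SummarizedExperiment::assay(x, "counts")
  m[, .splitCols(x, split), drop = FALSE]
}

#' @rdname panel-accessors
#' @export
panelCovariate <- function(x, name, split = NULL) {
  stopifnot(name %in% .panelCovariateNames)
  SummarizedExperiment::assay(x, name)[, .splitCols(x, split), drop = FALSE]
}

#' @rdname panel-accessors
#' @export
panelOffset <- function(x) {
  a <- SummarizedExperiment::rowData(x)$area
  names(a) <- SummarizedExperiment::rowData(x)$l3
  a
}

#' @rdname panel-accessors
#' @export
panelSplit <- function(x) SummarizedExperiment::colData(x)$split

.splitCols <- function(x, split) {
  if (is.null(split)) return(seq_len(ncol(x)))
  which(SummarizedExperiment::colData(x)$split == match.arg(split, c("train", "test")))
}

#' @rdname panel-accessors
#' @export
flattenPanel <- function(x, split = NULL) {
  cols <- .splitCols(x, split)
  rd <- SummarizedExperiment::rowData(x)
  cd <- SummarizedExperiment::colData(x)[cols, , drop = FALSE]
  s <- nrow(x); t <- length(cols)
  out <- data.frame(
    l3 = rep(rd$l3, times = t),
    t = rep(cd$t, each = s),
    year = rep(cd$year, each = s),
    month = rep(cd$month, each = s),
    split = rep(as.character(cd$split), each = s),
    area = rep(rd$area, times = t),
    count = as.vector(SummarizedExperiment::assay(x, "counts")[, cols]),
    stringsAsFactors = FALSE
  )
  for (nm in .panelCovariateNames) {
    out[[nm]] <- as.vector(SummarizedExperiment::assay(x, nm)[, cols])
  }
  out
}

#' Accessors for posterior draws
#'
#' @param x a \linkS4class{PosteriorDraws}.
#' @param name parameter name.
#' @return \code{drawNames}: names of stored parameters; \code{nChains},
#'   \code{nIterations}: sampler dimensions; \code{drawsMatrix}: draws for
#'   one parameter flattened to (chains*iterations) x dim;
#'   \code{drawsArray}: the raw (chain, iteration, dim) array.
#' @aliases drawNames nChains nIterations drawsMatrix drawsArray
#' @name draws-accessors
NULL

#' @rdname draws-accessors
#' @export
drawNames <- function(x) names(x@draws)

#' @rdname draws-accessors
#' @export
nChains <- function(x) x@chains

#' @rdname draws-accessors
#' @export
nIterations <- function(x) x@iterations

#' @rdname draws-accessors
#' @export
drawsArray <- function(x, name) {
  if (!name %in% names(x@draws)) stop("unknown parameter: ", name)
  x@draws[[name]]
}

#' @rdname draws-accessors
#' @export
drawsMatrix <- function(x, name) {
  a <- drawsArray(x, name)
  d <- dim(a)
  matrix(a, nrow = d[1] * d[2], ncol = d[3])
}

setMethod("show", "PosteriorDraws", function(object) {
  p <- sum(vapply(object@draws, function(a) dim(a)[3], 0))
  cat(sprintf(
    "PosteriorDraws (%s): %s %s model; %d chains x %d draws (+%d warmup), %d parameters\n",
    object@method, object@model$family %||% "?", object@model$component %||% "",
    object@chains, object@iterations, object@warmup, p))
})

#' Accessors for design matrices
#'
#' @param x a \linkS4class{DesignMatrix}.
#' @return \code{designMatrix}: the sparse matrix; \code{columnInfo}:
#'   per-column metadata; \code{splineSpecs}: the fitted spline
#'   specifications.
#' @aliases designMatrix columnInfo splineSpecs
#' @name design-accessors
NULL

#' @rdname design-accessors
#' @export
designMatrix <- function(x) x@X

#' @rdname design-accessors
#' @export
columnInfo <- function(x) x@columnInfo

#' @rdname design-accessors
#' @export
splineSpecs <- function(x) x@specs

setMethod("show", "DesignMatrix", function(object) {
  nnz <- length(object@X@x)
  cat(sprintf("DesignMatrix: %d x %d, %.1f%% zero entries\n",
              nrow(object@X), ncol(object@X),
              100 * (1 - nnz / prod(dim(object@X)))))
})

setMethod("dim", "DesignMatrix", function(x) dim(x@X))

setMethod("show", "TrueParameters", function(object) {
  cat(sprintf(
    "TrueParameters: %s counts (%d/%d nonzero beta), %s sizes; AR %.2f, ICAR scale %.2f\n",
    object@countFamily, sum(object@betaMu != 0), length(object@betaMu),
    object@sizeFamily, object@arCoef, object@icarScale))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
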