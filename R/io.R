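#' @include AllClasses.R AllGenerics.R preprocess.R
NULL

#' Read and write package objects as plain text
#'
#' Catalogs and covariate panels round-trip through CSV; the hierarchy
#' through a nesting CSV (l3, l2, l1, area) plus an edge-list text file;
#' generative parameters through JSON.
#'
#' @param x the object to write.
#' @param path,nestingPath,edgePath file paths.
#' @param catalog,covariates,hierarchy,splitMonth see
#'   \code{\link{assemblePanel}}.
#' @name firemev-io
NULL

#' @rdname firemev-io
#' @export
writeFireCatalog <- function(x, path) {
  stopifnot(is(x, "FireCatalog"))
  ev <- catalogEvents(x)
  ev$threshold_ha <- sizeThreshold(x)
  utils::write.csv(ev, path, row.names = FALSE)
  invisible(path)
}

#' @rdname firemev-io
#' @export
readFireCatalog <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  thr <- if ("threshold_ha" %in% names(df)) df$threshold_ha[1] else 405
  df$threshold_ha <- NULL
  if (!nrow(df)) return(emptyFireCatalog(thr))
  new("FireCatalog", events = df, thresholdHa = thr)
}

#' @rdname firemev-io
#' @export
writeHierarchy <- function(x, nestingPath, edgePath) {
  stopifnot(is(x, "EcoregionHierarchy"))
  l3 <- l3Regions(x)
  utils::write.csv(
    data.frame(l3 = l3, l2 = l2Of(x, l3), l1 = l1Of(x, l3),
               area = unname(regionArea(x))),
    nestingPath, row.names = FALSE)
  e <- adjacencyEdges(x)
  utils::write.table(e, edgePath, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(nestingPath)
}

#' @rdname firemev-io
#' @export
readHierarchy <- function(nestingPath, edgePath) {
  nest <- utils::read.csv(nestingPath, stringsAsFactors = FALSE)
  e <- as.matrix(utils::read.table(edgePath, stringsAsFactors = FALSE,
                                   colClasses = "character"))
  l2ByL3 <- structure(nest$l2, names = nest$l3)
  l1 <- nest$l1[!duplicated(nest$l2)]
  l1ByL2 <- structure(l1, names = nest$l2[!duplicated(nest$l2)])
  EcoregionHierarchy(nest$l3, l2ByL3, l1ByL2, e,
                     structure(nest$area, names = nest$l3))
}

#' @rdname firemev-io
#' @export
writePanel <- function(x, path) {
  stopifnot(is(x, "SpaceTimePanel"))
  utils::write.csv(flattenPanel(x), path, row.names = FALSE)
  invisible(path)
}

#' @rdname firemev-io
#' @export
readPanel <- function(path, hierarchy) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  splitMonth <- max(df$t[df$split == "train"])
  panel <- assemblePanel(emptyFireCatalog(), df, hierarchy, splitMonth)
  cnt <- matrix(0L, nrow(panel), ncol(panel))
  i <- match(df$l3, SummarizedExperiment::rowData(panel)$l3)
  j <- match(df$t, SummarizedExperiment::colData(panel)$t)
  cnt[cbind(i, j)] <- as.integer(df$count)
  dimnames(cnt) <- dimnames(SummarizedExperiment::assay(panel, "counts"))
  SummarizedExperiment::assay(panel, "counts") <- cnt
  panel
}

#' @rdname firemev-io
#' @export
writeTrueParameters <- function(x, path) {
  stopifnot(is(x, "TrueParameters"))
  obj <- list(countFamily = x@countFamily, sizeFamily = x@sizeFamily,
              alphaMu = x@alphaMu, alphaPi = x@alphaPi,
              betaMu = x@betaMu, betaPi = x@betaPi,
              dispersion = x@dispersion, alphaSize = x@alphaSize,
              betaSize = x@betaSize, aux = as.list(x@aux),
              arCoef = x@arCoef, icarScale = x@icarScale)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname firemev-io
#' @export
readTrueParameters <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  trueParameters(o$countFamily, o$sizeFamily, alphaMu = o$alphaMu,
                 alphaPi = o$alphaPi, betaMu = o$betaMu,
                 betaPi = o$betaPi %||% numeric(),
                 dispersion = o$dispersion, alphaSize = o$alphaSize,
                 betaSize = o$betaSize, aux = unlist(o$aux),
                 arCoef = o$arCoef, icarScale = o$icarScale)
}
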