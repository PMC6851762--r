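#' @include AllClasses.R AllGenerics.R
NULL

## Run expr with a temporary RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv())) {
          rm(".Random.seed", envir = globalenv())
        }
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

#' Construct an ecoregion hierarchy
#'
#' @param l3 character vector of L3 ids.
#' @param l2ByL3 named map L3 -> L2.
#' @param l1ByL2 named map L2 -> L1.
#' @param edges two-column matrix of unordered L3 adjacency pairs.
#' @param area named positive areas (km^2) for each L3.
#' @return a validated \linkS4class{EcoregionHierarchy}.
#' @export
EcoregionHierarchy <- function(l3, l2ByL3, l1ByL2, edges, area) {
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2)
  storage.mode(edges) <- "character"
  new("EcoregionHierarchy", l3 = as.character(l3),
      l2ByL3 = l2ByL3, l1ByL2 = l1ByL2, edges = edges, area = area)
}

#' Generate a nested region hierarchy with a connected adjacency graph
#'
#' L3 regions are laid out on a planar grid (row-major) and connected by
#' rook adjacency, which guarantees a connected graph — required by the
#' intrinsic CAR prior, whose single sum-to-zero constraint only identifies
#' the field on a connected graph.  L3 units are partitioned into L2
#' parents, and L2 units into L1 parents, by contiguous blocks of the grid
#' order so that every parent is non-empty.  Areas are drawn lognormal
#' (median 1000 km^2).
#'
#' @param nL1,nL2,nL3 number of units per level; 1 <= nL1 <= nL2 <= nL3.
#' @param seed integer seed.
#' @return an \linkS4class{EcoregionHierarchy}.
#' @examples
#' h <- generateHierarchy(2, 4, 12, seed = 7)
#' nRegions(h)
#' @export
generateHierarchy <- function(nL1, nL2, nL3, seed) {
  if (!(nL1 >= 1 && nL1 <= nL2 && nL2 <= nL3)) {
    stop("need 1 <= nL1 <= nL2 <= nL3")
  }
  .withSeed(seed, {
    l3 <- sprintf("L3_%02d", seq_len(nL3))
    l2 <- sprintf("L2_%02d", seq_len(nL2))
    l1 <- sprintf("L1_%02d", seq_len(nL1))
    ## balanced contiguous partition of n items into k blocks
    blocks <- function(n, k) sort(rep_len(seq_len(k), n))
    l2ByL3 <- structure(l2[blocks(nL3, nL2)], names = l3)
    l1ByL2 <- structure(l1[blocks(nL2, nL1)], names = l2)
    ## rook adjacency on a row-major grid layout
    ncols <- ceiling(sqrt(nL3))
    row <- (seq_len(nL3) - 1) %/% ncols
    col <- (seq_len(nL3) - 1) %% ncols
    e <- NULL
    for (i in seq_len(nL3)) {
      right <- which(row == row[i] & col == col[i] + 1)
      below <- which(row == row[i] + 1 & col == col[i])
      for (j in c(right, below)) e <- rbind(e, c(l3[i], l3[j]))
    }
    ## a partially filled last grid row can orphan nothing under row-major
    ## filling, but guard anyway by bridging any unreached component
    if (is.null(e)) e <- matrix(character(), ncol = 2)
    if (nL3 > 1 && !.graphConnected(l3, e)) {
      for (i in seq_len(nL3 - 1)) e <- rbind(e, c(l3[i], l3[i + 1]))
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      e <- e[!duplicated(key), , drop = FALSE]
    }
    area <- structure(1000 * exp(stats::rnorm(nL3, 0, 0.5)), names = l3)
    EcoregionHierarchy(l3, l2ByL3, l1ByL2, e, area)
  })
}
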