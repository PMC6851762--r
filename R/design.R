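#' @include AllClasses.R AllGenerics.R splines.R
NULL

#' Fit the six default spline specifications on training rows
#'
#' @param training data.frame with the six covariate columns (training
#'   rows only).
#' @param df basis dimension per covariate (default 5).
#' @param degree B-spline degree (default 3).
#' @return named list of \linkS4class{SplineSpec}, in the fixed covariate
#'   order humidity, temperature, precipitation, precip12, wind, housing
#'   (housing is log-transformed).
#' @export
makeDefaultSplineSpecs <- function(training, df = 5L, degree = 3L) {
  out <- lapply(.panelCovariateNames, function(nm) {
    makeSplineSpec(training[[nm]], nm, df = df, degree = degree,
                   logTransform = (nm == "housing"))
  })
  names(out) <- .panelCovariateNames
  out
}

#' Build the sparse design matrix with hierarchical interactions
#'
#' Columns are, in order: the B global basis vectors (B = sum of spline
#' df, covariate-major), then masked copies of the global block for each
#' L1, L2 and L3 unit (covariate-major, then region, then basis index;
#' each copy is zeroed outside the unit's rows), then one
#' intercept-adjustment indicator per unit (L1, then L2, then L3).  With
#' R total units this gives p = B(1 + R) + R columns.  The additive
#' global + L1 + L2 + L3 decomposition of every regional coefficient is
#' exact under this masking construction.
#'
#' @param data a \linkS4class{SpaceTimePanel} (rows = flattened cells) or a
#'   data.frame with the covariate columns and an \code{l3} column (e.g.
#'   per-event rows for size models).
#' @param hierarchy an \linkS4class{EcoregionHierarchy}.
#' @param specs named list of \linkS4class{SplineSpec} (fitted on training
#'   rows only).
#' @param warnClamp warn when covariates fall outside the training range.
#' @return a \linkS4class{DesignMatrix}.
#' @export
buildDesignMatrix <- function(data, hierarchy, specs, warnClamp = TRUE) {
  df <- if (is(data, "SpaceTimePanel")) flattenPanel(data) else data
  if (!"l3" %in% names(df)) stop("data needs an 'l3' column")
  unknown <- setdiff(unique(df$l3), l3Regions(hierarchy))
  if (length(unknown)) {
    stop("region(s) absent from hierarchy: ", paste(unknown, collapse = ", "))
  }
  n <- nrow(df)
  ## global basis block, covariate-major
  G <- do.call(cbind, lapply(specs, function(sp) {
    if (!sp@covariate %in% names(df)) stop("missing covariate: ", sp@covariate)
    evaluateBasis(sp, df[[sp@covariate]], warnClamp = warnClamp)
  }))
  B <- ncol(G)
  covOfCol <- rep(vapply(specs, function(sp) sp@covariate, ""),
                  vapply(specs, function(sp) sp@df, 0L))
  basisOfCol <- unlist(lapply(specs, function(sp) seq_len(sp@df)))
  l1u <- sort(unique(unname(hierarchy@l1ByL2)))
  l2u <- sort(unique(unname(hierarchy@l2ByL3)))
  l3u <- l3Regions(hierarchy)
  rowL3 <- df$l3
  rowUnit <- list(L1 = l1Of(hierarchy, rowL3), L2 = l2Of(hierarchy, rowL3),
                  L3 = rowL3)
  units <- list(L1 = l1u, L2 = l2u, L3 = l3u)
  R <- length(l1u) + length(l2u) + length(l3u)

  ti <- tj <- tx <- vector("list", 64); nb <- 0L
  addBlock <- function(i, j, x) {
    nb <<- nb + 1L
    if (nb > length(ti)) {
      length(ti) <<- length(tj) <<- length(tx) <<- 2L * nb
    }
    ti[[nb]] <<- i; tj[[nb]] <<- j; tx[[nb]] <<- x
  }
  info <- vector("list", 64); ni <- 0L
  addInfo <- function(d) { ni <<- ni + 1L; if (ni > length(info)) length(info) <<- 2L * ni
    info[[ni]] <<- d }

  ## global block
  nzg <- which(G != 0, arr.ind = TRUE)
  addBlock(nzg[, 1], nzg[, 2], G[nzg])
  addInfo(data.frame(covariate = covOfCol, basis_index = basisOfCol,
                     level = "global", region = NA_character_,
                     stringsAsFactors = FALSE))
  colOffset <- B
  ## interaction blocks: level, then covariate, then region, then basis
  for (lev in c("L1", "L2", "L3")) {
    uu <- units[[lev]]
    memberRows <- lapply(uu, function(u) which(rowUnit[[lev]] == u))
    names(memberRows) <- uu
    for (sp in specs) {
      cols <- which(covOfCol == sp@covariate)
      for (u in uu) {
        rows <- memberRows[[u]]
        if (length(rows)) {
          sub <- G[rows, cols, drop = FALSE]
          nz <- which(sub != 0, arr.ind = TRUE)
          if (nrow(nz)) {
            addBlock(rows[nz[, 1]], colOffset + nz[, 2], sub[nz])
          }
        }
        addInfo(data.frame(covariate = sp@covariate,
                           basis_index = seq_len(sp@df),
                           level = lev, region = u, stringsAsFactors = FALSE))
        colOffset <- colOffset + sp@df
      }
    }
  }
  ## intercept-adjustment indicators
  for (lev in c("L1", "L2", "L3")) {
    for (u in units[[lev]]) {
      rows <- which(rowUnit[[lev]] == u)
      colOffset <- colOffset + 1L
      if (length(rows)) addBlock(rows, rep.int(colOffset, length(rows)),
                                 rep.int(1, length(rows)))
      addInfo(data.frame(covariate = "intercept-adjustment",
                         basis_index = NA_integer_, level = lev, region = u,
                         stringsAsFactors = FALSE))
    }
  }
  p <- B * (1L + R) + R
  stopifnot(colOffset == p)
  X <- Matrix::sparseMatrix(
    i = unlist(ti[seq_len(nb)]), j = unlist(tj[seq_len(nb)]),
    x = unlist(tx[seq_len(nb)]), dims = c(n, p)
  )
  ci <- do.call(rbind, info[seq_len(ni)])
  rownames(ci) <- NULL
  new("DesignMatrix", X = methods::as(X, "CsparseMatrix"), columnInfo = ci,
      specs = specs)
}

#' Effective basis coefficients for one region and covariate
#'
#' Sums the global, L1, L2 and L3 coefficient components that apply to the
#' given L3 region, returning the length-df vector whose dot product with a
#' basis row is the region's partial effect of the covariate (the quantity
#' shown in partial-effect curves).
#'
#' @param beta coefficient vector aligned with the design columns.
#' @param design a \linkS4class{DesignMatrix}.
#' @param hierarchy the \linkS4class{EcoregionHierarchy} used to build it.
#' @param covariate covariate name.
#' @param l3 an L3 region id.
#' @return numeric vector of length df (the covariate's basis dimension).
#' @export
coefficientForRegion <- function(beta, design, hierarchy, covariate, l3) {
  ci <- columnInfo(design)
  if (length(beta) != nrow(ci)) stop("beta length must match design columns")
  if (!covariate %in% ci$covariate) stop("unknown covariate: ", covariate)
  if (!l3 %in% l3Regions(hierarchy)) stop("unknown region: ", l3)
  sel <- function(level, region) {
    k <- ci$covariate == covariate & ci$level == level &
      (if (level == "global") TRUE else !is.na(ci$region) & ci$region == region)
    idx <- which(k)
    idx[order(ci$basis_index[idx])]
  }
  out <- beta[sel("global", NA)]
  out <- out + beta[sel("L1", l1Of(hierarchy, l3))]
  out <- out + beta[sel("L2", l2Of(hierarchy, l3))]
  out + beta[sel("L3", l3)]
}
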