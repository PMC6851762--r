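#' @include diagnostics.R
NULL

#' Posterior predictive replication
#'
#' Draws one replicated data set per retained posterior draw.  For count
#' models, returns replicated cell counts \eqn{n^{rep}} on the requested
#' split; for size models, returns replicated exceedance sizes for the
#' catalog's events in the requested split (one replicate per event and
#' draw).
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @param panel the \linkS4class{SpaceTimePanel}.
#' @param design the \linkS4class{DesignMatrix} on the full panel.
#' @param catalog required for size models: events to replicate.
#' @param split "train", "test" or NULL (all months).
#' @param seed optional integer seed.
#' @return numeric matrix with one row per draw; columns are cells (count
#'   models, flattened order) or events (size models).
#' @export
posteriorPredict <- function(draws, panel, design, catalog = NULL,
                             split = "test", seed = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  model <- draws@model
  .withSeed(seed, {
    if (model$component == "count") {
      par <- .countCellParams(draws, panel, design, split)
      D <- ncol(par$mu)
      out <- matrix(NA_integer_, D, nrow(par$mu))
      for (d in seq_len(D)) {
        out[d, ] <- countRng(model$family, par$mu[, d],
                             delta = par$delta[d], pi = par$pi[, d])
      }
      out
    } else {
      if (is.null(catalog)) stop("size replication needs the event catalog")
      idx <- .eventCellIndex(catalog, panel)
      cells <- .panelRowIdx(panel, split)
      keep <- idx %in% cells
      if (!any(keep)) stop("no events in the requested split")
      par <- .sizeCellParams(draws, panel, design, rows = idx[keep])
      D <- ncol(par$loc)
      out <- matrix(NA_real_, D, nrow(par$loc))
      for (d in seq_len(D)) {
        out[d, ] <- sizeRng(model$family, nrow(par$loc), par$loc[, d],
                            par$aux[d, ])
      }
      out
    }
  })
}

#' Per-draw size-distribution parameters at panel cells
#'
#' Returns, for every retained draw, the located size parameter at each
#' cell of the requested split together with the draw's auxiliary
#' scalar(s) — the inputs the extremes module combines with replicated
#' counts into finite-sample maxima distributions.
#'
#' @inheritParams posteriorPredict
#' @return list with \code{loc} (cells x draws matrix), \code{aux}
#'   (draws x aux matrix) and \code{family}.
#' @export
sizeParamsAt <- function(draws, panel, design, split = "test") {
  .sizeCellParams(draws, panel, design, split = split)
}
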