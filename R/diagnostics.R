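#' @include fit.R
NULL

#' Split-chain potential scale reduction
#'
#' Split-\eqn{\widehat{R}}: each chain is split in half, and the classic
#' potential scale reduction statistic is computed over the resulting
#' half-chains for every scalar parameter.  Values of 1.1 or larger (or
#' undefined values from zero-variance chains) are flagged as convergence
#' failures.
#'
#' @param draws a \linkS4class{PosteriorDraws} with at least 2 chains.
#' @param parameters parameter names to include (default: all stored).
#' @return named numeric vector of statistics (one entry per scalar
#'   parameter, named like \code{betaMu[12]}), with attribute
#'   \code{"flagged"} listing entries >= 1.1 or undefined.
#' @export
computeRhat <- function(draws, parameters = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  if (nChains(draws) < 2) stop("split R-hat needs at least 2 chains")
  parameters <- parameters %||% drawNames(draws)
  out <- numeric(0)
  for (nm in parameters) {
    a <- drawsArray(draws, nm)
    d <- dim(a)
    half <- d[2] %/% 2
    if (half < 2) stop("too few iterations to split chains")
    ## stack first and second half-chains: (2*chains, half, dim)
    sp <- array(NA_real_, c(2 * d[1], half, d[3]))
    sp[seq_len(d[1]), , ] <- a[, seq_len(half), , drop = FALSE]
    sp[d[1] + seq_len(d[1]), , ] <- a[, half + seq_len(half), , drop = FALSE]
    m <- dim(sp)[1]; n <- half
    cm <- apply(sp, c(1, 3), mean)              # chain means (m x dim)
    cv <- apply(sp, c(1, 3), stats::var)        # chain variances
    W <- colMeans(cv)
    B <- n * apply(cm, 2, stats::var)
    varPlus <- (n - 1) / n * W + B / n
    r <- sqrt(varPlus / W)
    names(r) <- if (d[3] == 1) nm else sprintf("%s[%d]", nm, seq_len(d[3]))
    out <- c(out, r)
  }
  flagged <- names(out)[!is.finite(out) | out >= 1.1]
  attr(out, "flagged") <- flagged
  out
}

## per-draw count-model cell parameters (mu, pi) on the requested split,
## extrapolating spatiotemporal effects beyond training via the AR mean
.countCellParams <- function(draws, panel, design, split = "test") {
  model <- draws@model
  stopifnot(model$component == "count")
  rows <- .panelRowIdx(panel, split)
  X <- designMatrix(design)[rows, , drop = FALSE]
  s <- nrow(panel)
  cols <- .splitCols(panel, split)
  logOffset <- rep(log(SummarizedExperiment::rowData(panel)$area),
                   times = length(cols))
  B <- t(drawsMatrix(draws, "betaMu"))
  alpha <- as.vector(drawsMatrix(draws, "alphaMu"))
  Eta <- as.matrix(X %*% B)
  Eta <- sweep(Eta, 2, alpha, "+") + logOffset
  zi <- model$family %in% c("zip", "zinb")
  EtaPi <- NULL
  if (zi) {
    Bp <- t(drawsMatrix(draws, "betaPi"))
    EtaPi <- sweep(as.matrix(X %*% Bp), 2,
                   as.vector(drawsMatrix(draws, "alphaPi")), "+")
  }
  if (isTRUE(model$spatioTemporal)) {
    addPhi <- function(Eta, phiName, arName) {
      Phi <- t(drawsMatrix(draws, phiName))          # (S*TnTrain) x D
      tnTrain <- length(model$trainT)
      if (identical(split, "train")) {
        Eta + Phi
      } else {
        last <- Phi[(tnTrain - 1) * s + seq_len(s), , drop = FALSE]
        ar <- as.vector(drawsMatrix(draws, arName))
        tTest <- SummarizedExperiment::colData(panel)$t[cols]
        lag <- tTest - max(model$trainT)
        ext <- do.call(rbind, lapply(lag, function(k) {
          sweep(last, 2, ar^k, "*")
        }))
        Eta + ext
      }
    }
    Eta <- addPhi(Eta, "phiMu", "arMu")
    if (zi) EtaPi <- addPhi(EtaPi, "phiPi", "arPi")
  }
  list(mu = exp(Eta),
       pi = if (zi) stats::plogis(EtaPi) else NULL,
       delta = if (model$family %in% c("nb", "zinb")) {
         as.vector(drawsMatrix(draws, "delta"))
       } else NULL)
}

## per-draw size-model located parameter at panel cells (or event rows)
.sizeCellParams <- function(draws, panel, design, split = "test",
                            rows = NULL) {
  model <- draws@model
  stopifnot(model$component == "size")
  if (is.null(rows)) rows <- .panelRowIdx(panel, split)
  X <- designMatrix(design)[rows, , drop = FALSE]
  B <- t(drawsMatrix(draws, "beta"))
  alpha <- as.vector(drawsMatrix(draws, "alpha"))
  Eta <- sweep(as.matrix(X %*% B), 2, alpha, "+")
  if (isTRUE(model$spatioTemporal)) {
    s <- model$S
    Phi <- t(drawsMatrix(draws, "phi"))
    tnTrain <- length(model$trainT)
    cellT <- (rows - 1L) %/% s + 1L
    cellS <- (rows - 1L) %% s + 1L
    tOfCol <- SummarizedExperiment::colData(panel)$t
    ar <- as.vector(drawsMatrix(draws, "ar"))
    last <- Phi[(tnTrain - 1) * s + seq_len(s), , drop = FALSE]
    add <- matrix(0, nrow(Eta), ncol(Eta))
    for (i in seq_len(nrow(Eta))) {
      tAbs <- tOfCol[cellT[i]]
      if (tAbs <= max(model$trainT)) {
        trainPos <- match(tAbs, model$trainT)
        add[i, ] <- Phi[(trainPos - 1) * s + cellS[i], ]
      } else {
        add[i, ] <- last[cellS[i], ] * ar^(tAbs - max(model$trainT))
      }
    }
    Eta <- Eta + add
  }
  aux <- drawsMatrix(draws, "aux")
  colnames(aux) <- model$auxNames[seq_len(ncol(aux))]
  if (model$family == "tapered_pareto") {
    aux <- cbind(aux, y0 = model$y0)
  }
  list(loc = sizeLocation(model$family, Eta), aux = aux,
       family = model$family)
}

#' Holdout (test-set) log likelihood
#'
#' Per retained posterior draw, sums the model log likelihood over the
#' held-out test observations (test-month cells for count models; test
#' events for size models), and reports the posterior mean and standard
#' deviation across draws — the model-comparison statistic used to rank
#' families.
#'
#' @param draws a \linkS4class{PosteriorDraws}.
#' @param panel the \linkS4class{SpaceTimePanel}.
#' @param design the \linkS4class{DesignMatrix} built on the full panel.
#' @param catalog test events (required for size models).
#' @return list with mean, sd and the per-draw vector loglik.
#' @export
holdoutLogLik <- function(draws, panel, design, catalog = NULL) {
  stopifnot(is(draws, "PosteriorDraws"))
  model <- draws@model
  if (model$component == "count") {
    y <- as.integer(panelCounts(panel, "test"))
    par <- .countCellParams(draws, panel, design, "test")
    D <- ncol(par$mu)
    ll <- vapply(seq_len(D), function(d) {
      sum(countLogPmf(model$family, y, par$mu[, d],
                      delta = par$delta[d], pi = par$pi[, d]))
    }, 0.0)
  } else {
    if (is.null(catalog)) stop("size-model holdout needs the event catalog")
    idx <- .eventCellIndex(catalog, panel)
    testCells <- .panelRowIdx(panel, "test")
    inTest <- idx %in% testCells
    if (!any(inTest)) stop("no test events")
    y <- catalogEvents(catalog)$exceedance_ha[inTest]
    par <- .sizeCellParams(draws, panel, design, rows = idx[inTest])
    D <- nrow(drawsMatrix(draws, "alpha"))
    ll <- vapply(seq_len(D), function(d) {
      sum(sizeLogPdf(model$family, y, par$loc[, d], par$aux[d, ]))
    }, 0.0)
  }
  list(mean = mean(ll),
       sd = if (length(ll) > 1) stats::sd(ll) else 0,
       loglik = ll)
}
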