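#' @include size-models.R predict.R
NULL

#' CDF of the finite-sample maximum
#'
#' If each of n iid event sizes has CDF value F at z, the maximum of the
#' n events satisfies \eqn{\Pr(Z \le z) = F(z)^n}.  An empty month
#' (n = 0) has a vacuous maximum: probability 1.
#'
#' @param F_value CDF value(s) in [0, 1].
#' @param n nonnegative event count(s).
#' @return \code{F_value ^ n}, elementwise.
#' @examples
#' maximaCdf(0.9, 2)   # 0.81
#' maximaCdf(0.3, 0)   # 1
#' @export
maximaCdf <- function(F_value, n) {
  if (any(F_value < 0) || any(F_value > 1)) stop("F_value must be in [0, 1]")
  if (any(n < 0)) stop("n must be nonnegative")
  F_value^n
}

#' Quantile of the maximum of n lognormal sizes
#'
#' Closed form: \eqn{q = \exp(\mu + \sqrt{2}\,\sigma\,
#' \mathrm{erf}^{-1}(2P^{1/n} - 1))}, i.e.
#' \eqn{\exp(\mu + \sigma\,\Phi^{-1}(P^{1/n}))}, the value with
#' \eqn{F(q)^n = P} under a lognormal(\eqn{\mu, \sigma}) size
#' distribution.
#'
#' @param mu lognormal location.
#' @param sigma lognormal scale (>= 0; 0 gives the degenerate point
#'   exp(mu)).
#' @param n number of events (>= 1).
#' @param P probability in (0, 1).
#' @return the P-quantile of the maximum exceedance.
#' @examples
#' lognormalMaximaQuantile(0, 1, 1, 0.5)  # 1, the lognormal median
#' @export
lognormalMaximaQuantile <- function(mu, sigma, n, P) {
  if (any(P <= 0) || any(P >= 1)) stop("P must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  if (any(sigma < 0)) stop("sigma must be >= 0")
  exp(mu + sigma * stats::qnorm(P^(1 / n)))
}

#' Family-agnostic maxima quantile
#'
#' Inverts \eqn{F(q)^n = P} through the size-family registry:
#' \eqn{q = F^{-1}(P^{1/n})}.
#'
#' @param family a size family name.
#' @param P probability in (0, 1).
#' @param n number of events (>= 1).
#' @param loc located parameter (see \code{\link{sizeLocation}}).
#' @param aux named auxiliary scalar(s).
#' @export
maximaQuantile <- function(family, P, n, loc, aux) {
  if (any(P <= 0) || any(P >= 1)) stop("P must be in (0, 1)")
  if (any(n < 1)) stop("n must be >= 1")
  sizeQuantile(family, P^(1 / n), loc, aux)
}

#' Prediction intervals for monthly burned-area maxima
#'
#' Combines replicated counts with per-draw size parameters into the
#' posterior predictive distribution of the maximum exceedance per cell,
#' conditional on fires having occurred: only draws with
#' \eqn{n^{rep} \ge 1} contribute.  The predictive CDF at z is the
#' average of \eqn{F_d(z)^{n_d}} over qualifying draws d, and the
#' interval endpoints invert this mixture CDF at \eqn{(1 \mp level)/2}
#' by bracketed root finding.  Cells with no fire in any draw are
#' flagged and get no interval.
#'
#' @param countDraws draws x cells matrix of replicated counts (from
#'   \code{\link{posteriorPredict}}).
#' @param sizeParams list from \code{\link{sizeParamsAt}} for the same
#'   cells (loc: cells x draws; aux: draws x k).
#' @param level central interval level (default 0.99).
#' @return data.frame with one row per cell: lower, upper, nDraws (draws
#'   with at least one fire) and noFire flag.
#' @export
maximaInterval <- function(countDraws, sizeParams, level = 0.99) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  D <- nrow(countDraws); nCell <- ncol(countDraws)
  if (ncol(sizeParams$loc) != D || nrow(sizeParams$loc) != nCell) {
    stop("countDraws and sizeParams are misaligned")
  }
  pLo <- (1 - level) / 2; pHi <- (1 + level) / 2
  family <- sizeParams$family
  lower <- upper <- rep(NA_real_, nCell)
  nD <- integer(nCell)
  for (j in seq_len(nCell)) {
    has <- which(countDraws[, j] >= 1)
    nD[j] <- length(has)
    if (!length(has)) next
    n <- countDraws[has, j]
    loc <- sizeParams$loc[j, has]
    mixCdf <- function(z) {
      Fz <- vapply(seq_along(has), function(k) {
        sizeCdf(family, z, loc[k], sizeParams$aux[has[k], ])
      }, 0.0)
      mean(Fz^n)
    }
    ## bracket from per-draw maxima quantiles
    qs <- vapply(seq_along(has), function(k) {
      c(maximaQuantile(family, pLo, n[k], loc[k], sizeParams$aux[has[k], ]),
        maximaQuantile(family, pHi, n[k], loc[k], sizeParams$aux[has[k], ]))
    }, c(0.0, 0.0))
    solve1 <- function(p) {
      lo <- min(qs) * 0.5 + 1e-12; hi <- max(qs) * 2 + 1e-6
      while (mixCdf(hi) < p) hi <- hi * 4
      while (mixCdf(lo) > p && lo > 1e-300) lo <- lo / 4
      stats::uniroot(function(z) mixCdf(z) - p, c(lo, hi),
                     tol = 1e-8 * max(qs))$root
    }
    lower[j] <- solve1(pLo)
    upper[j] <- solve1(pHi)
  }
  data.frame(cell = seq_len(nCell), lower = lower, upper = upper,
             nDraws = nD, noFire = nD == 0L)
}

#' Posterior probability of a size exceedance
#'
#' Per draw, the probability that at least one fire exceeds the
#' threshold is \eqn{1 - \prod_{cells} F_{cell}(thr)^{n_{cell}}}
#' (cells are independent given the parameters).  Draws with no fires
#' contribute zero probability.  Summaries report the posterior median
#' and an 80\% credible band.
#'
#' @param countDraws draws x cells matrix of replicated counts.
#' @param sizeParams list from \code{\link{sizeParamsAt}} for the same
#'   cells.
#' @param threshold exceedance threshold (same scale as the size model,
#'   i.e. hectares over the catalog's size threshold).
#' @param scope "cell" (one probability series per cell) or "monthly"
#'   (product-aggregate the S cells of each month; needs \code{S}).
#' @param S number of regions per month (monthly scope).
#' @param band credible band mass (default 0.8).
#' @return data.frame with one row per cell or month: median, lo, hi.
#' @export
exceedanceProbability <- function(countDraws, sizeParams, threshold,
                                  scope = c("cell", "monthly"), S = NULL,
                                  band = 0.8) {
  scope <- match.arg(scope)
  if (threshold <= 0) stop("threshold must be > 0")
  D <- nrow(countDraws); nCell <- ncol(countDraws)
  if (ncol(sizeParams$loc) != D || nrow(sizeParams$loc) != nCell) {
    stop("countDraws and sizeParams are misaligned")
  }
  family <- sizeParams$family
  ## log F_cell(threshold)^n per draw and cell
  logFn <- matrix(0, D, nCell)
  for (d in seq_len(D)) {
    Fd <- sizeCdf(family, threshold, sizeParams$loc[, d],
                  sizeParams$aux[d, ])
    logFn[d, ] <- countDraws[d, ] * log(pmin(Fd, 1))
  }
  probFrom <- function(lp) 1 - exp(lp)
  qs <- c(0.5, (1 - band) / 2, (1 + band) / 2)
  if (scope == "cell") {
    p <- probFrom(logFn)
    out <- t(apply(p, 2, stats::quantile, probs = qs, names = FALSE))
    data.frame(unit = seq_len(nCell), median = out[, 1], lo = out[, 2],
               hi = out[, 3])
  } else {
    if (is.null(S)) stop("monthly scope needs S")
    if (nCell %% S != 0) stop("cells are not a whole number of months")
    months <- rep(seq_len(nCell %/% S), each = S)
    agg <- vapply(split(seq_len(nCell), months), function(ix) {
      rowSums(logFn[, ix, drop = FALSE])
    }, numeric(D))
    if (is.null(dim(agg))) agg <- matrix(agg, nrow = D)
    p <- probFrom(agg)
    out <- t(apply(p, 2, stats::quantile, probs = qs, names = FALSE))
    data.frame(unit = seq_len(ncol(p)), median = out[, 1], lo = out[, 2],
               hi = out[, 3])
  }
}
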