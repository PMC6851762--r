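#' @include AllClasses.R
NULL

.countFamilies <- c("poisson", "nb", "zip", "zinb")

#' Count-model linear predictors
#'
#' Computes the cell-level mean \eqn{\mu = \exp(\alpha^{(\mu)} + X\beta^{(\mu)} +
#' \phi^{(\mu)} + \log a)} and, for zero-inflated families, the
#' structural-zero probability \eqn{\pi = \mathrm{logit}^{-1}(\alpha^{(\pi)} +
#' X\beta^{(\pi)} + \phi^{(\pi)})}.  The log-area offset makes \eqn{\mu} a
#' rate times area.
#'
#' @param design a \linkS4class{DesignMatrix} (or sparse matrix) with one
#'   row per cell in flattened order.
#' @param params list with alphaMu, betaMu and optionally phiMu, and for
#'   zero-inflated families alphaPi, betaPi, phiPi; plus family.
#' @param logOffset per-cell log areas.
#' @return list with mu (> 0) and pi (in (0,1), or NULL for non-ZI
#'   families).
#' @export
countLinearPredictors <- function(design, params, logOffset) {
  X <- if (is(design, "DesignMatrix")) designMatrix(design) else design
  family <- match.arg(params$family, .countFamilies)
  n <- nrow(X)
  stopifnot(length(logOffset) == n)
  phiMu <- params$phiMu %||% numeric(n)
  etaMu <- params$alphaMu + as.numeric(X %*% params$betaMu) + phiMu + logOffset
  bad <- which(!is.finite(etaMu))
  if (length(bad)) stop("non-finite count linear predictor at cell(s) ",
                        paste(utils::head(bad, 5), collapse = ", "))
  mu <- exp(etaMu)
  pi <- NULL
  if (family %in% c("zip", "zinb")) {
    phiPi <- params$phiPi %||% numeric(n)
    etaPi <- params$alphaPi + as.numeric(X %*% params$betaPi) + phiPi
    bad <- which(!is.finite(etaPi))
    if (length(bad)) stop("non-finite zero-inflation predictor at cell(s) ",
                          paste(utils::head(bad, 5), collapse = ", "))
    pi <- stats::plogis(etaPi)
  }
  list(mu = mu, pi = pi)
}

## NB2 log pmf: mean mu, dispersion delta, variance mu + mu^2/delta
.nbLogPmf <- function(n, mu, delta) {
  stats::dnbinom(n, size = delta, mu = mu, log = TRUE)
}

#' Count log probability mass
#'
#' Log pmf for the four occurrence families.  The negative binomial uses
#' the mean-dispersion (NB2) form with variance \eqn{\mu + \mu^2/\delta}.
#' Zero-inflated families mix on the probability scale:
#' \eqn{P(0) = \pi + (1-\pi) g(0)} and \eqn{P(k) = (1-\pi) g(k)} for
#' \eqn{k > 0}, with \eqn{g} the base pmf; the zero case is computed with
#' log-sum-exp for stability.
#'
#' @param family one of "poisson", "nb", "zip", "zinb".
#' @param n nonnegative integer counts (vectorized).
#' @param mu positive means.
#' @param delta NB dispersion (> 0; NB families only).
#' @param pi structural-zero probabilities in [0, 1] (ZI families only).
#' @return log probabilities, recycled to common length.
#' @export
countLogPmf <- function(family, n, mu, delta = NULL, pi = NULL) {
  family <- match.arg(family, .countFamilies)
  if (any(n < 0) || any(n != round(n))) stop("counts must be nonnegative integers")
  base <- switch(family,
    poisson = , zip = function(k, m) stats::dpois(k, m, log = TRUE),
    nb = , zinb = {
      if (is.null(delta) || any(delta <= 0)) stop("delta must be > 0")
      function(k, m) .nbLogPmf(k, m, delta)
    })
  g <- base(n, mu)
  if (family %in% c("poisson", "nb")) return(g)
  if (is.null(pi) || any(pi < 0) || any(pi > 1)) stop("pi must be in [0, 1]")
  len <- length(g)
  pi <- rep_len(pi, len); nn <- rep_len(n, len)
  out <- log1p(-pi) + g
  z <- which(nn == 0)
  if (length(z)) {
    a <- log(pi[z]); b <- out[z]
    m <- pmax(a, b)
    out[z] <- ifelse(pi[z] == 0, b,
                     ifelse(pi[z] == 1, 0, m + log(exp(a - m) + exp(b - m))))
  }
  nz <- which(nn > 0 & pi == 1)
  if (length(nz)) out[nz] <- -Inf
  out
}

#' Simulate counts from an occurrence family
#'
#' @inheritParams countLogPmf
#' @param seed optional integer seed (RNG state is restored afterwards).
#' @return integer vector of draws, one per element of mu (recycled
#'   against pi).
#' @export
countRng <- function(family, mu, delta = NULL, pi = NULL, seed = NULL) {
  family <- match.arg(family, .countFamilies)
  .withSeed(seed, {
    n <- length(mu)
    base <- switch(family,
      poisson = , zip = stats::rpois(n, mu),
      nb = , zinb = {
        if (is.null(delta) || any(delta <= 0)) stop("delta must be > 0")
        stats::rnbinom(n, size = delta, mu = mu)
      })
    if (family %in% c("zip", "zinb")) {
      if (is.null(pi) || any(pi < 0) || any(pi > 1)) stop("pi must be in [0, 1]")
      zero <- stats::runif(n) < rep_len(pi, n)
      base[zero] <- 0L
    }
    as.integer(base)
  })
}
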