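#' @include AllClasses.R
NULL

#' Burned-area exceedance families
#'
#' Registry of the five exceedance-size families.  Each family attaches the
#' covariates to exactly one "located" parameter (per-event, via
#' \code{\link{sizeLocation}}) and carries global auxiliary scalar(s):
#' \describe{
#'   \item{lognormal}{located meanlog (identity link); aux \code{sdlog}.}
#'   \item{gamma}{located mean (log link); aux \code{shape};
#'     rate = shape/mean.}
#'   \item{weibull}{located scale (log link); aux \code{shape}.}
#'   \item{gpd_lomax}{located Lomax scale \eqn{\sigma^{(L)}} (log link);
#'     aux Lomax shape \code{kappaL}.  Equivalent to a generalized Pareto
#'     with positive shape, see \code{\link{lomaxToGpd}}.}
#'   \item{tapered_pareto}{located Pareto shape \eqn{\kappa} (log link);
#'     aux taper \code{theta} and lower bound \code{y0}.  Survival
#'     \eqn{S(y) = (y_0/y)^{\kappa} e^{(y_0 - y)/\theta}} for
#'     \eqn{y \ge y_0}.}
#' }
#'
#' @return character vector of family names.
#' @export
sizeFamilies <- function() {
  c("lognormal", "gamma", "weibull", "gpd_lomax", "tapered_pareto")
}

.sizeAuxNames <- list(
  lognormal = "sdlog", gamma = "shape", weibull = "shape",
  gpd_lomax = "kappaL", tapered_pareto = c("theta", "y0")
)

.checkSizeAux <- function(family, aux) {
  need <- .sizeAuxNames[[family]]
  if (!all(need %in% names(aux))) {
    stop(family, " needs aux scalar(s): ", paste(need, collapse = ", "))
  }
  if (any(aux[need] <= 0)) stop("aux scalars must be > 0")
  aux
}

#' Map the linear predictor to the located size parameter
#'
#' Identity link for the lognormal location; log link (exp) for the gamma
#' mean, Weibull scale, Lomax scale and tapered-Pareto shape.
#'
#' @param family a size family name.
#' @param eta per-event linear predictor \eqn{\alpha + X\beta + \phi}.
#' @return the per-event located parameter.
#' @export
sizeLocation <- function(family, eta) {
  family <- match.arg(family, sizeFamilies())
  if (any(!is.finite(eta))) stop("non-finite size linear predictor")
  if (family == "lognormal") eta else exp(eta)
}

#' Lomax to generalized-Pareto reparameterization
#'
#' A Lomax (Pareto type II) exceedance distribution is a generalized
#' Pareto distribution with positive shape: \eqn{\kappa^{(GPD)} =
#' 1/\kappa^{(L)}} and \eqn{\sigma^{(GPD)} = \sigma^{(L)}/\kappa^{(L)}}.
#'
#' @param sigmaL Lomax scale (> 0).
#' @param kappaL Lomax shape (> 0).
#' @return list with sigma and kappa (GPD scale and shape).
#' @examples
#' lomaxToGpd(2, 2)  # sigma 1, kappa 0.5
#' @export
lomaxToGpd <- function(sigmaL, kappaL) {
  if (any(sigmaL <= 0) || any(kappaL <= 0)) stop("inputs must be > 0")
  list(sigma = sigmaL / kappaL, kappa = 1 / kappaL)
}

#' Generalized Pareto log density (positive shape)
#'
#' \eqn{f(y) = \sigma^{-1} (1 + \kappa y/\sigma)^{-1/\kappa - 1}} for
#' \eqn{y > 0}; used as the cross-check for the Lomax parameterization.
#'
#' @param y exceedances (> 0).
#' @param sigma GPD scale (> 0).
#' @param kappa GPD shape (> 0).
#' @export
gpdLogPdf <- function(y, sigma, kappa) {
  if (any(sigma <= 0) || any(kappa <= 0)) stop("parameters must be > 0")
  -log(sigma) - (1 / kappa + 1) * log1p(kappa * y / sigma)
}

## tapered Pareto log survival; y >= y0
.tpLogSurv <- function(y, kappa, theta, y0) {
  kappa * (log(y0) - log(y)) + (y0 - y) / theta
}

#' Size-family log density, CDF, quantile and sampler
#'
#' All functions are vectorized over \code{y}/\code{p} and the located
#' parameter.  The tapered Pareto uses survival
#' \eqn{S(y) = (y_0/y)^\kappa e^{(y_0-y)/\theta}} and density
#' \eqn{f(y) = (\kappa/y + 1/\theta) S(y)}; its quantile is found by
#' bracketed root finding (tolerance 1e-12 on the log-survival scale).
#'
#' @param family a size family name (see \code{\link{sizeFamilies}}).
#' @param y positive exceedances (>= y0 for tapered Pareto).
#' @param loc located parameter from \code{\link{sizeLocation}}.
#' @param aux named auxiliary scalar(s) for the family.
#' @param p probabilities in (0, 1).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return log densities, probabilities, quantiles or draws respectively.
#' @name size-distributions
NULL

#' @rdname size-distributions
#' @export
sizeLogPdf <- function(family, y, loc, aux) {
  family <- match.arg(family, sizeFamilies())
  aux <- .checkSizeAux(family, aux)
  if (family == "tapered_pareto") {
    if (any(y < aux["y0"])) stop("tapered Pareto needs y >= y0")
  } else if (any(y <= 0)) stop("exceedances must be > 0")
  switch(family,
    lognormal = stats::dlnorm(y, meanlog = loc, sdlog = aux["sdlog"], log = TRUE),
    gamma = stats::dgamma(y, shape = aux["shape"], rate = aux["shape"] / loc,
                          log = TRUE),
    weibull = stats::dweibull(y, shape = aux["shape"], scale = loc, log = TRUE),
    gpd_lomax = {
      k <- aux["kappaL"]
      log(k) - log(loc) - (k + 1) * log1p(y / loc)
    },
    tapered_pareto = {
      k <- loc; th <- aux["theta"]; y0 <- aux["y0"]
      log(k / y + 1 / th) + .tpLogSurv(y, k, th, y0)
    })
}

#' @rdname size-distributions
#' @export
sizeCdf <- function(family, y, loc, aux) {
  family <- match.arg(family, sizeFamilies())
  aux <- .checkSizeAux(family, aux)
  switch(family,
    lognormal = stats::plnorm(y, meanlog = loc, sdlog = aux["sdlog"]),
    gamma = stats::pgamma(y, shape = aux["shape"], rate = aux["shape"] / loc),
    weibull = stats::pweibull(y, shape = aux["shape"], scale = loc),
    gpd_lomax = 1 - exp(-aux["kappaL"] * log1p(y / loc)),
    tapered_pareto = {
      out <- 1 - exp(.tpLogSurv(pmax(y, aux["y0"]), loc, aux["theta"], aux["y0"]))
      out[y <= aux["y0"]] <- 0
      unname(out)
    })
}

#' @rdname size-distributions
#' @export
sizeQuantile <- function(family, p, loc, aux) {
  family <- match.arg(family, sizeFamilies())
  aux <- .checkSizeAux(family, aux)
  if (any(p <= 0) || any(p >= 1)) stop("p must be in (0, 1)")
  switch(family,
    lognormal = stats::qlnorm(p, meanlog = loc, sdlog = aux["sdlog"]),
    gamma = stats::qgamma(p, shape = aux["shape"], rate = aux["shape"] / loc),
    weibull = stats::qweibull(p, shape = aux["shape"], scale = loc),
    gpd_lomax = loc * expm1(-log1p(-p) / aux["kappaL"]),
    tapered_pareto = {
      len <- max(length(p), length(loc))
      p <- rep_len(p, len); k <- rep_len(loc, len)
      th <- aux["theta"]; y0 <- aux["y0"]
      vapply(seq_len(len), function(i) {
        target <- log1p(-p[i])        # solve log S(y) = log(1 - p)
        f <- function(ly) .tpLogSurv(exp(ly), k[i], th, y0) - target
        up <- log(y0) + 1
        while (f(up) > 0) up <- up + 1
        exp(stats::uniroot(f, c(log(y0), up), tol = 1e-12)$root)
      }, 0.0)
    })
}

#' @rdname size-distributions
#' @export
sizeRng <- function(family, n, loc, aux, seed = NULL) {
  family <- match.arg(family, sizeFamilies())
  aux <- .checkSizeAux(family, aux)
  .withSeed(seed, {
    loc <- rep_len(loc, n)
    switch(family,
      lognormal = stats::rlnorm(n, meanlog = loc, sdlog = aux["sdlog"]),
      gamma = stats::rgamma(n, shape = aux["shape"], rate = aux["shape"] / loc),
      weibull = stats::rweibull(n, shape = aux["shape"], scale = loc),
      gpd_lomax = sizeQuantile(family, stats::runif(n), loc, aux),
      tapered_pareto = sizeQuantile(family, stats::runif(n), loc, aux))
  })
}
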