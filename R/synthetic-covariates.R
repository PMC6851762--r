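#' @include hierarchy.R
NULL

#' Simulate a region-month covariate panel
#'
#' Emulates monthly meteorological summaries and housing density for each
#' L3 region: each meteorological series is a region-specific seasonal
#' sinusoid plus AR(1) noise; precipitation and wind are kept positive via
#' a log link; humidity is kept in (0, 100) via a logistic link; housing
#' density follows a strictly positive, monotone increasing trend.  The
#' prior-12-month precipitation covariate is computed from twelve extra
#' burn-in months of simulated precipitation, so it is defined (and
#' internally consistent with \code{\link{rollingPriorPrecip}}) for every
#' panel month.
#'
#' @param hierarchy an \linkS4class{EcoregionHierarchy}.
#' @param nMonths number of months (>= 13).
#' @param seed integer seed.
#' @param arCoef AR(1) coefficient of the noise (default 0.7).
#' @param noiseSd named innovation standard deviations on the link scale
#'   for humidity, temperature, precipitation and wind.
#' @param year0 calendar year of month 1.
#' @return data.frame with one row per (l3, t): year, month and the six
#'   covariates humidity, temperature, precipitation, precip12, wind,
#'   housing.
#' @export
simulateCovariates <- function(hierarchy, nMonths, seed,
                               arCoef = 0.7,
                               noiseSd = c(humidity = 0.3, temperature = 1.5,
                                           precipitation = 0.4, wind = 0.2),
                               year0 = 2000L) {
  if (nMonths < 13) stop("nMonths must be >= 13")
  stopifnot(abs(arCoef) < 1)
  .withSeed(seed, {
    l3 <- l3Regions(hierarchy)
    s <- length(l3)
    tt <- seq_len(nMonths)
    month <- (tt - 1L) %% 12L + 1L
    year <- year0 + (tt - 1L) %/% 12L
    ar1 <- function(n, sd) {
      if (sd == 0) return(numeric(n))
      e <- stats::rnorm(n, 0, sd)
      stats::filter(e, arCoef, method = "recursive")
    }
    seasonal <- function(amp, phase, m) amp * cos(2 * pi * (m - phase) / 12)
    out <- vector("list", s)
    nExtra <- 12L
    mAll <- ((seq_len(nMonths + nExtra) - 1L) %% 12L) + 1L
    for (i in seq_len(s)) {
      ## region-specific climatology
      ## seasonal phases are drawn independently per region and variable so
      ## the six covariates are not mutually confounded in the synthetic
      ## panel (real meteorology is more collinear; see the vignette)
      tMean <- stats::rnorm(1, 15, 5)
      tAmp <- stats::runif(1, 5, 12)
      tPeak <- stats::runif(1, 1, 12)
      hMean <- stats::rnorm(1, 0, 0.4)        # logit scale, ~ 40-60%
      hAmp <- stats::runif(1, 0.3, 0.8)
      hPeak <- stats::runif(1, 1, 12)
      pMean <- stats::rnorm(1, 0.6, 0.3)      # log scale mean daily precip
      pAmp <- stats::runif(1, 0.2, 0.6)
      pPeak <- stats::runif(1, 1, 12)
      wMean <- stats::rnorm(1, 1.2, 0.2)      # log scale wind speed
      wAmp <- stats::runif(1, 0.1, 0.3)
      temperature <- tMean + seasonal(tAmp, tPeak, month) +
        ar1(nMonths, noiseSd["temperature"])
      humidity <- 100 * stats::plogis(
        hMean + seasonal(hAmp, hPeak, month) + ar1(nMonths, noiseSd["humidity"]))
      ## precipitation simulated with a 12-month burn-in so that the
      ## prior-12-month sum exists for every panel month; a yearly shock
      ## adds interannual wet/dry cycles (drought), without which the
      ## rolling 12-month sum would be nearly constant within a region
      nYears <- ceiling((nMonths + nExtra) / 12)
      yearShock <- stats::rnorm(nYears, 0, 0.35)
      precAll <- exp(pMean + seasonal(pAmp, pPeak, mAll) +
                       yearShock[(seq_len(nMonths + nExtra) - 1L) %/% 12L + 1L] +
                       ar1(nMonths + nExtra, noiseSd["precipitation"]))
      precipitation <- precAll[(nExtra + 1L):(nExtra + nMonths)]
      precip12 <- vapply(tt, function(k) {
        sum(precAll[(nExtra + k - 12L):(nExtra + k - 1L)])
      }, 0.0)
      wind <- exp(wMean + seasonal(wAmp, 4, month) +
                    ar1(nMonths, noiseSd["wind"]))
      h0 <- exp(stats::rnorm(1, 1, 1))        # units/km^2 at month 1
      growth <- stats::runif(1, 0.001, 0.004) # monotone monthly growth rate
      housing <- h0 * exp(growth * (tt - 1))
      out[[i]] <- data.frame(
        l3 = l3[i], t = tt, year = year, month = month,
        humidity = as.numeric(humidity), temperature = as.numeric(temperature),
        precipitation = precipitation, precip12 = precip12,
        wind = as.numeric(wind), housing = housing,
        stringsAsFactors = FALSE
      )
    }
    res <- do.call(rbind, out)
    ## flattened cell order: space fastest within month
    res <- res[order(res$t, match(res$l3, l3)), ]
    rownames(res) <- NULL
    res
  })
}
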