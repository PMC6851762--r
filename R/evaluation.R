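#' @include predict.R
NULL

.ppcStatistics <- c("prop_zero", "max", "sum")

#' Posterior predictive check statistic
#'
#' Computes a check statistic (proportion of zeros, maximum, or sum)
#' identically on every replicated data set and on the observed data, and
#' reports the two-sided posterior predictive tail probability.
#'
#' @param replicates draws x observations matrix of replicated data.
#' @param observed observed data vector (same observation order).
#' @param statistic "prop_zero", "max" or "sum".
#' @return list with statistic, replicateValues, observedValue and the
#'   two-sided tailProb.
#' @examples
#' ppcStatistic(matrix(rpois(300, 1), 30), rpois(10, 1), "prop_zero")
#' @export
ppcStatistic <- function(replicates, observed, statistic) {
  if (!statistic %in% .ppcStatistics) {
    stop("unknown statistic '", statistic, "'; use one of: ",
         paste(.ppcStatistics, collapse = ", "))
  }
  if (ncol(replicates) != length(observed)) {
    stop("replicates and observed are misaligned")
  }
  f <- switch(statistic,
    prop_zero = function(x) mean(x == 0),
    max = function(x) max(x),
    sum = function(x) sum(x))
  rep <- apply(replicates, 1, f)
  obs <- f(observed)
  tail <- 2 * min(mean(rep >= obs), mean(rep <= obs))
  list(statistic = statistic, replicateValues = rep, observedValue = obs,
       tailProb = min(tail, 1))
}

#' Central interval coverage with miss directions
#'
#' Per unit, forms the central (equal-tailed) interval from the empirical
#' draw quantiles (type-7 interpolation) and reports the fraction of
#' observations covered, and among the misses the fractions above the
#' upper and below the lower bound.
#'
#' @param draws draws x units matrix of predictive draws.
#' @param observed observed value per unit.
#' @param level interval level in (0, 1), e.g. 0.95.
#' @return list with coverage, missAbove, missBelow (fractions of the
#'   misses), covered (logical per unit), lower and upper bounds.
#' @export
intervalCoverage <- function(draws, observed, level) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  if (ncol(draws) != length(observed)) stop("draws and observed misaligned")
  pr <- c((1 - level) / 2, (1 + level) / 2)
  b <- apply(draws, 2, stats::quantile, probs = pr, names = FALSE, type = 7)
  covered <- observed >= b[1, ] & observed <= b[2, ]
  miss <- !covered
  nMiss <- sum(miss)
  list(coverage = mean(covered),
       missAbove = if (nMiss) sum(observed[miss] > b[2, miss]) / nMiss else 0,
       missBelow = if (nMiss) sum(observed[miss] < b[1, miss]) / nMiss else 0,
       covered = covered, lower = b[1, ], upper = b[2, ])
}

#' Per-variable contribution to the linear predictor
#'
#' The contribution of a driver variable is the dot product of the design
#' columns belonging to that variable (its global block plus all L1, L2
#' and L3 interaction blocks) with the corresponding coefficients —
#' computed per posterior draw, with posterior median and credible bands.
#' Passing \code{covariate = "intercept-adjustment"} gives the region
#' intercept-adjustment contribution, so the contributions of the six
#' variables plus the adjustments, the scalar intercept, the offset and
#' any spatiotemporal effect reconstruct the full linear predictor.
#'
#' @param design a \linkS4class{DesignMatrix}.
#' @param betaDraws draws x p matrix of coefficient draws (e.g.
#'   \code{drawsMatrix(fit, "betaMu")}).
#' @param covariate a covariate name or "intercept-adjustment".
#' @param band credible band mass (default 0.8).
#' @return list with draws (draws x rows contribution matrix), median, lo
#'   and hi (per design row).
#' @export
variableContribution <- function(design, betaDraws, covariate, band = 0.8) {
  ci <- columnInfo(design)
  if (ncol(betaDraws) != nrow(ci)) stop("betaDraws width must match design")
  cols <- which(ci$covariate == covariate)
  if (!length(cols)) stop("unknown covariate: ", covariate)
  contrib <- as.matrix(designMatrix(design)[, cols, drop = FALSE] %*%
                         t(betaDraws[, cols, drop = FALSE]))
  qs <- c(0.5, (1 - band) / 2, (1 + band) / 2)
  sm <- t(apply(contrib, 1, stats::quantile, probs = qs, names = FALSE))
  list(draws = t(contrib), median = sm[, 1], lo = sm[, 2], hi = sm[, 3])
}

#' Rank fitted families by holdout log likelihood
#'
#' @param results named list of \code{\link{holdoutLogLik}} results (one
#'   per fitted family).
#' @return data.frame sorted by decreasing posterior-mean holdout log
#'   likelihood (ties broken alphabetically by family name), with mean
#'   and sd columns.
#' @export
modelRankingReport <- function(results) {
  if (length(results) < 1) stop("no results to rank")
  df <- data.frame(
    family = names(results),
    mean = vapply(results, function(r) r$mean, 0.0),
    sd = vapply(results, function(r) r$sd, 0.0),
    stringsAsFactors = FALSE
  )
  df <- df[order(-df$mean, df$family), ]
  rownames(df) <- NULL
  df
}
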