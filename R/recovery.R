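#' @include fit.R diagnostics.R evaluation.R synthetic-fires.R
NULL

#' Parameter- and model-recovery experiment
#'
#' For each seed: simulate a study from the generative model (ZINB counts,
#' lognormal sizes, known sparse coefficients) on the toy hierarchy, fit
#' the true count and size families plus one deliberately wrong competitor
#' each (Poisson; gamma), and record (i) whether each true nonzero
#' coefficient is covered by its central 95\% credible interval, (ii) the
#' shrinkage of true-zero coefficients (median posterior-median magnitude
#' over zeros vs nonzeros), and (iii) whether the true families outrank
#' the competitors by posterior-mean holdout log likelihood.
#'
#' @param seeds integer vector of replicate seeds.
#' @param chains,iterations,warmup sampler configuration per fit.
#' @param control sampler control overrides.
#' @param nMonths panel length (default 120).
#' @param level credible level for the coverage bookkeeping (default
#'   0.95).
#' @return list with per-replicate results and pooled summaries:
#'   \code{coverage} (fraction of nonzero-coefficient intervals covering
#'   the truth), \code{shrinkRatio} (zero/nonzero posterior-median
#'   magnitude ratio), \code{countRankWins}, \code{sizeRankWins}.
#' @export
recoveryExperiment <- function(seeds, chains = 2L, iterations = 600L,
                               warmup = 300L, control = list(maxSteps = 32L),
                               nMonths = 120L, level = 0.95) {
  pr <- c((1 - level) / 2, (1 + level) / 2)
  reps <- lapply(seeds, function(sd) {
    sim <- simulateWildfireData(seed = sd, nMonths = nMonths)
    fitZ <- fitCountModel(sim$panel, sim$design, "zinb", chains = chains,
                          iterations = iterations, warmup = warmup,
                          seed = sd + 1L, control = control)
    fitP <- fitCountModel(sim$panel, sim$design, "poisson", chains = chains,
                          iterations = iterations, warmup = warmup,
                          seed = sd + 2L, control = control)
    fitL <- fitSizeModel(sim$catalog, sim$panel, sim$design, "lognormal",
                         chains = chains, iterations = iterations,
                         warmup = warmup, seed = sd + 3L, control = control)
    fitG <- fitSizeModel(sim$catalog, sim$panel, sim$design, "gamma",
                         chains = chains, iterations = iterations,
                         warmup = warmup, seed = sd + 4L, control = control)
    covOne <- function(draws, name, truth) {
      b <- drawsMatrix(draws, name)
      nz <- which(truth != 0)
      ci <- apply(b[, nz, drop = FALSE], 2, stats::quantile, probs = pr,
                  names = FALSE)
      covered <- truth[nz] >= ci[1, ] & truth[nz] <= ci[2, ]
      med <- apply(b, 2, stats::median)
      list(covered = covered,
           zeroMag = stats::median(abs(med[truth == 0])),
           nonzeroMag = stats::median(abs(med[nz])))
    }
    cMu <- covOne(fitZ, "betaMu", sim$truth@betaMu)
    cPi <- covOne(fitZ, "betaPi", sim$truth@betaPi)
    cSz <- covOne(fitL, "beta", sim$truth@betaSize)
    rankC <- modelRankingReport(list(
      zinb = holdoutLogLik(fitZ, sim$panel, sim$design),
      poisson = holdoutLogLik(fitP, sim$panel, sim$design)))
    rankS <- modelRankingReport(list(
      lognormal = holdoutLogLik(fitL, sim$panel, sim$design, sim$catalog),
      gamma = holdoutLogLik(fitG, sim$panel, sim$design, sim$catalog)))
    list(covered = c(cMu$covered, cPi$covered, cSz$covered),
         zeroMag = mean(c(cMu$zeroMag, cPi$zeroMag, cSz$zeroMag)),
         nonzeroMag = mean(c(cMu$nonzeroMag, cPi$nonzeroMag, cSz$nonzeroMag)),
         countWin = rankC$family[1] == "zinb",
         sizeWin = rankS$family[1] == "lognormal",
         countGap = rankC$mean[rankC$family == "zinb"] -
           rankC$mean[rankC$family == "poisson"],
         sizeGap = rankS$mean[rankS$family == "lognormal"] -
           rankS$mean[rankS$family == "gamma"])
  })
  covered <- unlist(lapply(reps, `[[`, "covered"))
  list(replicates = reps,
       coverage = mean(covered),
       nCovered = sum(covered), nCases = length(covered),
       shrinkRatio = mean(vapply(reps, `[[`, 0.0, "zeroMag")) /
         mean(vapply(reps, `[[`, 0.0, "nonzeroMag")),
       countRankWins = sum(vapply(reps, `[[`, TRUE, "countWin")),
       sizeRankWins = sum(vapply(reps, `[[`, TRUE, "sizeWin")),
       countHoldoutGap = mean(vapply(reps, `[[`, 0.0, "countGap")),
       sizeHoldoutGap = mean(vapply(reps, `[[`, 0.0, "sizeGap")),
       nReplicates = length(seeds))
}
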