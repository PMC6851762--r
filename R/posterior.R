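#' @include AllClasses.R AllGenerics.R count-models.R size-models.R priors.R
NULL

## ---------------------------------------------------------------------------
## Joint log-posterior builders.
##
## Both model components share the same coefficient structure: a
## regularized-horseshoe block over the spline columns (paired across the
## mu/pi components for zero-inflated counts), hierarchical-normal region
## intercept adjustments with one scale per hierarchy level, and optional
## AR(1) x ICAR spatiotemporal effects.  Everything is parameterized on an
## unconstrained scale (log for positive scales, atanh for correlations,
## non-centered standard-normal coordinates for the shrunk coefficients:
## beta_j = tau * lambda_tilde_j * z_j), which the gradient-based sampler
## requires; the funnel geometry of the horseshoe makes the non-centered
## form essential in practice.
## ---------------------------------------------------------------------------

.defaultHyper <- function() {
  list(p0 = 30, tauScale = NULL, slabShape = 2, slabRate = 8,
       alphaSd = 5, auxLogSd = 1.5, adjScaleSd = 1, phiTauSd = 1)
}

.mergeHyper <- function(hyper) {
  out <- .defaultHyper()
  for (nm in names(hyper)) out[[nm]] <- hyper[[nm]]
  out
}

## expected-nonzero heuristic for the global-scale prior
.tau0 <- function(pH, n, p0) {
  p0 <- min(p0, floor(pH / 2))
  p0 <- max(p0, 1)
  p0 / (pH - p0) / sqrt(n)
}

## parameter layout bookkeeping
.makeLayout <- function(spec) {
  len <- vapply(spec, identity, 0L)
  end <- cumsum(len)
  start <- end - len + 1L
  list(names = names(spec), start = start, end = end, n = sum(len))
}

.slice <- function(theta, layout, name) {
  i <- match(name, layout$names)
  theta[layout$start[i]:layout$end[i]]
}

## gradient of the half-Cauchy(0, scale) log pdf in log coordinates
## (including the exp jacobian term)
.hcLogGrad <- function(x, scale) {
  r2 <- (x / scale)^2
  list(lp = log(2 / pi) - log(scale) - log1p(r2) + log(x),
       g = 1 - 2 * r2 / (1 + r2))
}

## family-specific count likelihood value and derivatives wrt etaMu,
## etaPi (logit) and log(delta)
.countLikGrad <- function(family, y, etaMu, etaPi = NULL, logDelta = NULL) {
  mu <- exp(etaMu)
  nb <- family %in% c("nb", "zinb")
  zi <- family %in% c("zip", "zinb")
  if (nb) {
    delta <- exp(logDelta)
    if (!is.finite(delta) || delta <= 0) {
      return(list(ll = -Inf, gMu = 0 * mu, gPi = 0 * mu, gLogDelta = 0))
    }
    g0 <- stats::dnbinom(0L, size = delta, mu = mu, log = TRUE)
    gBase <- stats::dnbinom(y, size = delta, mu = mu, log = TRUE)
    dEtaBase <- delta * (y - mu) / (delta + mu)
    dEta0 <- -delta * mu / (delta + mu)
    dLdBase <- delta * (digamma(y + delta) - digamma(delta) +
                          log(delta / (delta + mu)) + 1 -
                          (y + delta) / (delta + mu))
    ## digamma terms cancel at y = 0
    dLd0 <- delta * (log(delta / (delta + mu)) + 1 - delta / (delta + mu))
  } else {
    g0 <- -mu
    gBase <- stats::dpois(y, mu, log = TRUE)
    dEtaBase <- y - mu
    dEta0 <- -mu
    dLdBase <- dLd0 <- NULL
  }
  if (!zi) {
    return(list(ll = sum(gBase), gMu = dEtaBase, gPi = NULL,
                gLogDelta = if (nb) sum(dLdBase) else NULL))
  }
  pi <- stats::plogis(etaPi)
  z <- y == 0L
  ll <- numeric(length(y))
  gMu <- numeric(length(y))
  gPi <- numeric(length(y))
  gLd <- if (nb) numeric(length(y)) else NULL
  ## nonzero counts: log(1 - pi) + g(y)
  ll[!z] <- log1p(-pi[!z]) + gBase[!z]
  gMu[!z] <- dEtaBase[!z]
  gPi[!z] <- -pi[!z]
  if (nb) gLd[!z] <- dLdBase[!z]
  ## zeros: log(pi + (1 - pi) g(0)) via log-sum-exp
  if (any(z)) {
    a <- log(pi[z]); b <- log1p(-pi[z]) + g0[z]
    m <- pmax(a, b)
    lse <- m + log(exp(a - m) + exp(b - m))
    ll[z] <- lse
    w <- exp(b - lse)                      # weight of the count branch
    gMu[z] <- w * dEta0[z]
    gPi[z] <- exp(a - lse) * (1 - pi[z]) - w * pi[z]
    if (nb) gLd[z] <- w * dLd0[z]
  }
  list(ll = sum(ll), gMu = gMu, gPi = gPi,
       gLogDelta = if (nb) sum(gLd) else NULL)
}

## family-specific size likelihood value and derivatives wrt eta and
## log(aux); aux is the single free auxiliary scalar (tapered-Pareto y0
## stays fixed)
.sizeLikGrad <- function(family, y, eta, logAux, y0 = 1) {
  aux <- exp(logAux)
  if (!is.finite(aux) || aux <= 0) {
    return(list(ll = -Inf, gEta = 0 * eta, gLogAux = 0))
  }
  switch(family,
    lognormal = {
      sdl <- aux
      r <- (log(y) - eta) / sdl
      list(ll = sum(stats::dlnorm(y, eta, sdl, log = TRUE)),
           gEta = r / sdl, gLogAux = sum(r^2 - 1))
    },
    gamma = {
      k <- aux; m <- exp(eta)
      ll <- sum(stats::dgamma(y, shape = k, rate = k / m, log = TRUE))
      list(ll = ll, gEta = k * (y / m - 1),
           gLogAux = sum(k * (log(k) + 1 - eta - digamma(k) + log(y) - y / m)))
    },
    weibull = {
      k <- aux; s <- exp(eta); r <- (y / s)^k
      ll <- sum(stats::dweibull(y, shape = k, scale = s, log = TRUE))
      list(ll = ll, gEta = k * (r - 1),
           gLogAux = sum(1 + k * log(y / s) * (1 - r)))
    },
    gpd_lomax = {
      k <- aux; s <- exp(eta); u <- y / s
      ll <- sum(log(k) - eta - (k + 1) * log1p(u))
      list(ll = ll, gEta = -1 + (k + 1) * u / (1 + u),
           gLogAux = sum(1 - k * log1p(u)))
    },
    tapered_pareto = {
      k <- exp(eta); th <- aux
      h <- k / y + 1 / th
      ll <- sum(log(h) + k * (log(y0) - log(y)) + (y0 - y) / th)
      list(ll = ll, gEta = k * ((1 / y) / h + log(y0 / y)),
           gLogAux = sum(-(1 / th) / h + (y - y0)) / th)
    })
}

## AR(1) x ICAR prior value and gradients for an S x Tn field in
## unconstrained coordinates (logTauPhi, atanhAr); returns gradient wrt
## the Phi entries too
.phiPriorGrad <- function(Phi, edgeIdx, logTauPhi, atanhAr, phiTauSd,
                          sumToZeroSd) {
  s <- nrow(Phi); tn <- ncol(Phi)
  tauPhi <- exp(logTauPhi); ar <- tanh(atanhAr)
  innov <- Phi
  if (tn > 1) innov[, -1] <- Phi[, -1, drop = FALSE] -
      ar * Phi[, -tn, drop = FALSE]
  d <- innov[edgeIdx[, 1], , drop = FALSE] - innov[edgeIdx[, 2], , drop = FALSE]
  ss <- sum(d^2)
  lp <- -ss / (2 * tauPhi^2)
  ## gInnov = -(Q innov)/tauPhi^2 accumulated over edges
  gInnov <- matrix(0, s, tn)
  dd <- d / tauPhi^2
  for (k in seq_len(nrow(edgeIdx))) {
    gInnov[edgeIdx[k, 1], ] <- gInnov[edgeIdx[k, 1], ] - dd[k, ]
    gInnov[edgeIdx[k, 2], ] <- gInnov[edgeIdx[k, 2], ] + dd[k, ]
  }
  gPhi <- gInnov
  if (tn > 1) {
    gPhi[, -tn] <- gPhi[, -tn, drop = FALSE] -
      ar * gInnov[, -1, drop = FALSE]
  }
  ## soft sum-to-zero per month
  cm <- colMeans(Phi)
  lp <- lp + sum(stats::dnorm(cm, 0, sumToZeroSd, log = TRUE))
  gPhi <- sweep(gPhi, 2, cm / sumToZeroSd^2 / s, "-")
  ## hyperparameters: tauPhi ~ half-normal(0, phiTauSd); ar ~ U(-1, 1)
  gLogTau <- ss / tauPhi^2 - tauPhi^2 / phiTauSd^2 + 1
  lp <- lp + stats::dnorm(tauPhi, 0, phiTauSd, log = TRUE) + log(2) + logTauPhi
  gAtanhAr <- 0
  if (tn > 1) {
    dAr <- -sum(gInnov[, -1, drop = FALSE] * Phi[, -tn, drop = FALSE])
    gAtanhAr <- dAr * (1 - ar^2) - 2 * ar
  } else {
    gAtanhAr <- -2 * ar
  }
  lp <- lp + log1p(-ar^2) - log(2)
  list(lp = lp, gPhi = gPhi, gLogTau = gLogTau, gAtanhAr = gAtanhAr)
}

## Build the count-model joint log posterior.  Returns lp/grad closures,
## the layout, an unpack() from unconstrained theta to natural parameters,
## and an init() for chain starting points.
.buildCountPosterior <- function(X, y, logOffset, family, colInfo,
                                 edgeIdx = NULL, S = NULL, Tn = NULL,
                                 spatioTemporal = FALSE, hyper = list()) {
  hyper <- .mergeHyper(hyper)
  family <- match.arg(family, .countFamilies)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(logOffset) == n)
  hsIdx <- which(colInfo$covariate != "intercept-adjustment")
  adjIdx <- which(colInfo$covariate == "intercept-adjustment")
  pH <- length(hsIdx); pA <- length(adjIdx)
  adjLvl <- match(colInfo$level[adjIdx], c("L1", "L2", "L3"))
  zi <- family %in% c("zip", "zinb")
  nb <- family %in% c("nb", "zinb")
  if (is.null(hyper$tauScale)) hyper$tauScale <- .tau0(pH, n, hyper$p0)
  if (spatioTemporal) stopifnot(!is.null(edgeIdx), S * Tn == n)

  spec <- c(list(alphaMu = 1L, zMu = pH, logLambda = pH, logTau = 1L,
                 logC = 1L),
            if (pA) list(zAdjMu = pA, logSigmaAdjMu = 3L),
            if (nb) list(logDelta = 1L),
            if (zi) c(list(alphaPi = 1L, zPi = pH),
                      if (pA) list(zAdjPi = pA, logSigmaAdjPi = 3L),
                      list(atanhRho = 1L)),
            if (spatioTemporal) c(list(phiMu = n, logTauPhiMu = 1L,
                                       atanhArMu = 1L),
                                  if (zi) list(phiPi = n, logTauPhiPi = 1L,
                                               atanhArPi = 1L)))
  layout <- .makeLayout(spec)
  Xt <- Matrix::t(X)

  unpack <- function(theta) {
    g <- function(nm) .slice(theta, layout, nm)
    lambda <- exp(g("logLambda")); tau <- exp(g("logTau")); cs <- exp(g("logC"))
    lt <- .lambdaTilde(lambda, tau, cs)
    sHs <- tau * lt
    betaMu <- numeric(p)
    betaMu[hsIdx] <- sHs * g("zMu")
    out <- list(alphaMu = g("alphaMu"), lambda = lambda, tau = tau, c = cs,
                sHs = sHs)
    if (pA) {
      sigA <- exp(g("logSigmaAdjMu"))
      betaMu[adjIdx] <- sigA[adjLvl] * g("zAdjMu")
      out$sigmaAdjMu <- sigA
    }
    out$betaMu <- betaMu
    if (nb) out$delta <- exp(g("logDelta"))
    if (zi) {
      rho <- tanh(g("atanhRho")); sq <- sqrt(1 - rho^2)
      betaPi <- numeric(p)
      betaPi[hsIdx] <- sHs * (rho * g("zMu") + sq * g("zPi"))
      if (pA) {
        sigP <- exp(g("logSigmaAdjPi"))
        betaPi[adjIdx] <- sigP[adjLvl] * g("zAdjPi")
        out$sigmaAdjPi <- sigP
      }
      out$alphaPi <- g("alphaPi"); out$betaPi <- betaPi; out$rho <- rho
    }
    if (spatioTemporal) {
      out$phiMu <- matrix(g("phiMu"), S, Tn)
      out$tauPhiMu <- exp(g("logTauPhiMu")); out$arMu <- tanh(g("atanhArMu"))
      if (zi) {
        out$phiPi <- matrix(g("phiPi"), S, Tn)
        out$tauPhiPi <- exp(g("logTauPhiPi")); out$arPi <- tanh(g("atanhArPi"))
      }
    }
    out
  }

  lpGrad <- function(theta) {
    if (any(!is.finite(theta))) {
      return(list(value = -Inf, grad = numeric(layout$n)))
    }
    gr <- numeric(layout$n)
    idx <- function(nm) {
      i <- match(nm, layout$names); layout$start[i]:layout$end[i]
    }
    gth <- function(nm) theta[idx(nm)]
    alphaMu <- gth("alphaMu")
    zMu <- gth("zMu"); logLambda <- gth("logLambda")
    logTau <- gth("logTau"); logC <- gth("logC")
    lambda <- exp(logLambda); tau <- exp(logTau); cs <- exp(logC)
    C2 <- cs^2 + tau^2 * lambda^2
    sHs <- tau * cs * lambda / sqrt(C2)
    w <- cs^2 / C2                      # dlog(s)/dlog(lambda) = dlog(s)/dlog(tau)
    betaMu <- numeric(p); betaMu[hsIdx] <- sHs * zMu
    if (pA) {
      zAdjMu <- gth("zAdjMu"); logSigAMu <- gth("logSigmaAdjMu")
      sigAMu <- exp(logSigAMu)
      betaMu[adjIdx] <- sigAMu[adjLvl] * zAdjMu
    }
    etaMu <- alphaMu + as.numeric(X %*% betaMu) + logOffset
    if (spatioTemporal) etaMu <- etaMu + gth("phiMu")
    zi2 <- zi
    if (zi2) {
      atanhRho <- gth("atanhRho"); rho <- tanh(atanhRho)
      sq <- sqrt(1 - rho^2)
      zPi <- gth("zPi"); alphaPi <- gth("alphaPi")
      betaPi <- numeric(p)
      betaPi[hsIdx] <- sHs * (rho * zMu + sq * zPi)
      if (pA) {
        zAdjPi <- gth("zAdjPi"); logSigAPi <- gth("logSigmaAdjPi")
        sigAPi <- exp(logSigAPi)
        betaPi[adjIdx] <- sigAPi[adjLvl] * zAdjPi
      }
      etaPi <- alphaPi + as.numeric(X %*% betaPi)
      if (spatioTemporal) etaPi <- etaPi + gth("phiPi")
    }
    if (any(!is.finite(etaMu)) || (zi2 && any(!is.finite(etaPi))) ||
        any(etaMu > 40)) {
      return(list(value = -Inf, grad = gr))
    }
    lik <- .countLikGrad(family, y, etaMu,
                         etaPi = if (zi2) etaPi else NULL,
                         logDelta = if (nb) gth("logDelta") else NULL)
    if (!is.finite(lik$ll)) return(list(value = -Inf, grad = gr))
    lp <- lik$ll
    gBetaMu <- as.numeric(Xt %*% lik$gMu)
    if (zi2) gBetaPi <- as.numeric(Xt %*% lik$gPi)
    ## intercepts
    lp <- lp + stats::dnorm(alphaMu, 0, hyper$alphaSd, log = TRUE)
    gr[idx("alphaMu")] <- sum(lik$gMu) - alphaMu / hyper$alphaSd^2
    ## horseshoe block
    gBmuH <- gBetaMu[hsIdx]
    bMuH <- betaMu[hsIdx]
    gz <- gBmuH * sHs - zMu
    lp <- lp + sum(stats::dnorm(zMu, log = TRUE))
    dLogS <- gBmuH * bMuH                  # contribution along dbeta = beta dlog s
    if (zi2) {
      gBpiH <- gBetaPi[hsIdx]; bPiH <- betaPi[hsIdx]
      gz <- gz + gBpiH * sHs * rho
      gzPi <- gBpiH * sHs * sq - zPi
      lp <- lp + sum(stats::dnorm(zPi, log = TRUE))
      dLogS <- dLogS + gBpiH * bPiH
      gr[idx("zPi")] <- gzPi
      ## rho
      dBpiDrho <- sHs * (zMu - rho / sq * zPi)
      gr[idx("atanhRho")] <- sum(gBpiH * dBpiDrho) * (1 - rho^2) - 2 * rho
      lp <- lp + log1p(-rho^2) - log(2)    # uniform(-1,1) + tanh jacobian
    }
    gr[idx("zMu")] <- gz
    hcL <- .hcLogGrad(lambda, 1)
    hcT <- .hcLogGrad(tau, hyper$tauScale)
    lp <- lp + sum(hcL$lp) + hcT$lp
    gr[idx("logLambda")] <- dLogS * w + hcL$g
    gr[idx("logTau")] <- sum(dLogS * w) + hcT$g
    ## slab: c^2 ~ inverse-gamma(shape, rate), log c coordinates
    a <- hyper$slabShape; b <- hyper$slabRate; c2 <- cs^2
    lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(c2) - b / c2 +
      log(2 * c2)
    gr[idx("logC")] <- sum(dLogS * (1 - w)) - 2 * (a + 1) + 2 * b / c2 + 2
    ## intercept adjustments: hierarchical normal per level
    if (pA) {
      gAdj <- gBetaMu[adjIdx]
      gr[idx("zAdjMu")] <- gAdj * sigAMu[adjLvl] - zAdjMu
      lp <- lp + sum(stats::dnorm(zAdjMu, log = TRUE))
      dSig <- vapply(1:3, function(l) {
        sum((gAdj * betaMu[adjIdx])[adjLvl == l])
      }, 0.0)
      lp <- lp + sum(stats::dnorm(sigAMu, 0, hyper$adjScaleSd, log = TRUE) +
                       log(2) + logSigAMu)
      gr[idx("logSigmaAdjMu")] <- dSig - sigAMu^2 / hyper$adjScaleSd^2 + 1
      if (zi2) {
        gAdjP <- gBetaPi[adjIdx]
        gr[idx("zAdjPi")] <- gAdjP * sigAPi[adjLvl] - zAdjPi
        lp <- lp + sum(stats::dnorm(zAdjPi, log = TRUE))
        dSigP <- vapply(1:3, function(l) {
          sum((gAdjP * betaPi[adjIdx])[adjLvl == l])
        }, 0.0)
        lp <- lp + sum(stats::dnorm(sigAPi, 0, hyper$adjScaleSd, log = TRUE) +
                         log(2) + logSigAPi)
        gr[idx("logSigmaAdjPi")] <- dSigP - sigAPi^2 / hyper$adjScaleSd^2 + 1
      }
    }
    if (zi2) {
      gr[idx("alphaPi")] <- sum(lik$gPi) - alphaPi / hyper$alphaSd^2
      lp <- lp + stats::dnorm(alphaPi, 0, hyper$alphaSd, log = TRUE)
    }
    if (nb) {
      logDelta <- gth("logDelta")
      lp <- lp + stats::dnorm(logDelta, 0, hyper$auxLogSd, log = TRUE)
      gr[idx("logDelta")] <- lik$gLogDelta - logDelta / hyper$auxLogSd^2
    }
    if (spatioTemporal) {
      Phi <- matrix(gth("phiMu"), S, Tn)
      pr <- .phiPriorGrad(Phi, edgeIdx, gth("logTauPhiMu"), gth("atanhArMu"),
                          hyper$phiTauSd, 0.001 * S)
      lp <- lp + pr$lp
      gr[idx("phiMu")] <- lik$gMu + as.vector(pr$gPhi)
      gr[idx("logTauPhiMu")] <- pr$gLogTau
      gr[idx("atanhArMu")] <- pr$gAtanhAr
      if (zi2) {
        PhiP <- matrix(gth("phiPi"), S, Tn)
        prP <- .phiPriorGrad(PhiP, edgeIdx, gth("logTauPhiPi"),
                             gth("atanhArPi"), hyper$phiTauSd, 0.001 * S)
        lp <- lp + prP$lp
        gr[idx("phiPi")] <- lik$gPi + as.vector(prP$gPhi)
        gr[idx("logTauPhiPi")] <- prP$gLogTau
        gr[idx("atanhArPi")] <- prP$gAtanhAr
      }
    }
    list(value = lp, grad = gr)
  }

  init <- function() {
    th <- numeric(layout$n)
    rnd <- function(n, a = 0.5) stats::runif(n, -a, a)
    set <- function(nm, v) {
      i <- match(nm, layout$names)
      th[layout$start[i]:layout$end[i]] <<- v
    }
    set("alphaMu", rnd(1, 2))
    set("zMu", rnd(pH, 0.1)); set("logLambda", rnd(pH))
    set("logTau", log(hyper$tauScale) + rnd(1)); set("logC", rnd(1))
    if (pA) { set("zAdjMu", rnd(pA, 0.1)); set("logSigmaAdjMu", rnd(3) - 1) }
    if (nb) set("logDelta", rnd(1))
    if (zi) {
      set("alphaPi", rnd(1, 2)); set("zPi", rnd(pH, 0.1))
      if (pA) { set("zAdjPi", rnd(pA, 0.1)); set("logSigmaAdjPi", rnd(3) - 1) }
      set("atanhRho", rnd(1))
    }
    if (spatioTemporal) {
      set("phiMu", rnd(n, 0.05)); set("logTauPhiMu", rnd(1) - 1)
      set("atanhArMu", rnd(1))
      if (zi) {
        set("phiPi", rnd(n, 0.05)); set("logTauPhiPi", rnd(1) - 1)
        set("atanhArPi", rnd(1))
      }
    }
    th
  }

  list(lpGrad = lpGrad, unpack = unpack, layout = layout, init = init,
       hyper = hyper, family = family, component = "count",
       spatioTemporal = spatioTemporal, hsIdx = hsIdx, adjIdx = adjIdx)
}

## Build the size-model joint log posterior over event-level exceedances.
.buildSizePosterior <- function(X, y, family, colInfo, cellIndex = NULL,
                                edgeIdx = NULL, S = NULL, Tn = NULL,
                                spatioTemporal = FALSE, hyper = list(),
                                y0 = 1) {
  hyper <- .mergeHyper(hyper)
  family <- match.arg(family, sizeFamilies())
  m <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == m)
  if (family == "tapered_pareto" && any(y < y0)) {
    stop("tapered Pareto needs all exceedances >= y0")
  }
  hsIdx <- which(colInfo$covariate != "intercept-adjustment")
  adjIdx <- which(colInfo$covariate == "intercept-adjustment")
  pH <- length(hsIdx); pA <- length(adjIdx)
  adjLvl <- match(colInfo$level[adjIdx], c("L1", "L2", "L3"))
  if (is.null(hyper$tauScale)) hyper$tauScale <- .tau0(pH, m, hyper$p0)
  nCell <- if (spatioTemporal) S * Tn else 0L
  if (spatioTemporal) stopifnot(!is.null(edgeIdx), !is.null(cellIndex))

  spec <- c(list(alpha = 1L, z = pH, logLambda = pH, logTau = 1L, logC = 1L),
            if (pA) list(zAdj = pA, logSigmaAdj = 3L),
            list(logAux = 1L),
            if (spatioTemporal) list(phi = nCell, logTauPhi = 1L,
                                     atanhAr = 1L))
  layout <- .makeLayout(spec)
  Xt <- Matrix::t(X)

  unpack <- function(theta) {
    g <- function(nm) .slice(theta, layout, nm)
    lambda <- exp(g("logLambda")); tau <- exp(g("logTau")); cs <- exp(g("logC"))
    sHs <- tau * .lambdaTilde(lambda, tau, cs)
    beta <- numeric(p)
    beta[hsIdx] <- sHs * g("z")
    out <- list(alpha = g("alpha"), lambda = lambda, tau = tau, c = cs,
                sHs = sHs)
    if (pA) {
      sigA <- exp(g("logSigmaAdj"))
      beta[adjIdx] <- sigA[adjLvl] * g("zAdj")
      out$sigmaAdj <- sigA
    }
    out$beta <- beta
    aux <- exp(g("logAux"))
    out$aux <- switch(family,
      lognormal = c(sdlog = unname(aux)), gamma = c(shape = unname(aux)),
      weibull = c(shape = unname(aux)), gpd_lomax = c(kappaL = unname(aux)),
      tapered_pareto = c(theta = unname(aux), y0 = y0))
    if (spatioTemporal) {
      out$phi <- matrix(g("phi"), S, Tn)
      out$tauPhi <- exp(g("logTauPhi")); out$ar <- tanh(g("atanhAr"))
    }
    out
  }

  lpGrad <- function(theta) {
    if (any(!is.finite(theta))) {
      return(list(value = -Inf, grad = numeric(layout$n)))
    }
    gr <- numeric(layout$n)
    idx <- function(nm) {
      i <- match(nm, layout$names); layout$start[i]:layout$end[i]
    }
    gth <- function(nm) theta[idx(nm)]
    alpha <- gth("alpha"); z <- gth("z")
    lambda <- exp(gth("logLambda")); tau <- exp(gth("logTau"))
    cs <- exp(gth("logC"))
    C2 <- cs^2 + tau^2 * lambda^2
    sHs <- tau * cs * lambda / sqrt(C2)
    w <- cs^2 / C2
    beta <- numeric(p); beta[hsIdx] <- sHs * z
    if (pA) {
      zAdj <- gth("zAdj"); logSigA <- gth("logSigmaAdj"); sigA <- exp(logSigA)
      beta[adjIdx] <- sigA[adjLvl] * zAdj
    }
    eta <- alpha + as.numeric(X %*% beta)
    if (spatioTemporal) eta <- eta + gth("phi")[cellIndex]
    if (any(!is.finite(eta)) || any(abs(eta) > 40)) {
      return(list(value = -Inf, grad = gr))
    }
    lik <- .sizeLikGrad(family, y, eta, gth("logAux"), y0 = y0)
    if (!is.finite(lik$ll)) return(list(value = -Inf, grad = gr))
    lp <- lik$ll + stats::dnorm(alpha, 0, hyper$alphaSd, log = TRUE)
    gBeta <- as.numeric(Xt %*% lik$gEta)
    gr[idx("alpha")] <- sum(lik$gEta) - alpha / hyper$alphaSd^2
    gH <- gBeta[hsIdx]; bH <- beta[hsIdx]
    gr[idx("z")] <- gH * sHs - z
    lp <- lp + sum(stats::dnorm(z, log = TRUE))
    dLogS <- gH * bH
    hcL <- .hcLogGrad(lambda, 1); hcT <- .hcLogGrad(tau, hyper$tauScale)
    lp <- lp + sum(hcL$lp) + hcT$lp
    gr[idx("logLambda")] <- dLogS * w + hcL$g
    gr[idx("logTau")] <- sum(dLogS * w) + hcT$g
    a <- hyper$slabShape; b <- hyper$slabRate; c2 <- cs^2
    lp <- lp + a * log(b) - lgamma(a) - (a + 1) * log(c2) - b / c2 +
      log(2 * c2)
    gr[idx("logC")] <- sum(dLogS * (1 - w)) - 2 * (a + 1) + 2 * b / c2 + 2
    if (pA) {
      gA <- gBeta[adjIdx]
      gr[idx("zAdj")] <- gA * sigA[adjLvl] - zAdj
      lp <- lp + sum(stats::dnorm(zAdj, log = TRUE))
      dSig <- vapply(1:3, function(l) sum((gA * beta[adjIdx])[adjLvl == l]), 0.0)
      lp <- lp + sum(stats::dnorm(sigA, 0, hyper$adjScaleSd, log = TRUE) +
                       log(2) + logSigA)
      gr[idx("logSigmaAdj")] <- dSig - sigA^2 / hyper$adjScaleSd^2 + 1
    }
    logAux <- gth("logAux")
    lp <- lp + stats::dnorm(logAux, 0, hyper$auxLogSd, log = TRUE)
    gr[idx("logAux")] <- lik$gLogAux - logAux / hyper$auxLogSd^2
    if (spatioTemporal) {
      Phi <- matrix(gth("phi"), S, Tn)
      pr <- .phiPriorGrad(Phi, edgeIdx, gth("logTauPhi"), gth("atanhAr"),
                          hyper$phiTauSd, 0.001 * S)
      lp <- lp + pr$lp
      gCell <- numeric(nCell)
      acc <- rowsum(lik$gEta, cellIndex)
      gCell[as.integer(rownames(acc))] <- acc[, 1]
      gr[idx("phi")] <- gCell + as.vector(pr$gPhi)
      gr[idx("logTauPhi")] <- pr$gLogTau
      gr[idx("atanhAr")] <- pr$gAtanhAr
    }
    list(value = lp, grad = gr)
  }

  init <- function() {
    th <- numeric(layout$n)
    rnd <- function(n, a = 0.5) stats::runif(n, -a, a)
    set <- function(nm, v) {
      i <- match(nm, layout$names)
      th[layout$start[i]:layout$end[i]] <<- v
    }
    set("alpha", rnd(1, 2) + if (family == "lognormal") mean(log(y)) else
      log(mean(y)) * (family != "tapered_pareto"))
    set("z", rnd(pH, 0.1)); set("logLambda", rnd(pH))
    set("logTau", log(hyper$tauScale) + rnd(1)); set("logC", rnd(1))
    if (pA) { set("zAdj", rnd(pA, 0.1)); set("logSigmaAdj", rnd(3) - 1) }
    set("logAux", rnd(1))
    if (spatioTemporal) {
      set("phi", rnd(nCell, 0.05)); set("logTauPhi", rnd(1) - 1)
      set("atanhAr", rnd(1))
    }
    th
  }

  list(lpGrad = lpGrad, unpack = unpack, layout = layout, init = init,
       hyper = hyper, family = family, component = "size",
       spatioTemporal = spatioTemporal, hsIdx = hsIdx, adjIdx = adjIdx,
       y0 = y0)
}
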