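#' @include posterior.R
NULL

## ---------------------------------------------------------------------------
## Adaptive Hamiltonian Monte Carlo.
##
## Standard HMC with a Metropolis accept step (detailed balance), a
## diagonal mass matrix estimated from the second half of warmup, dual
## averaging of the step size toward a target acceptance statistic, and a
## jittered number of leapfrog steps (uniform on 1..maxSteps) so that
## trajectories are not resonant.  Trajectories whose energy error
## exceeds `divergenceTol` are counted as divergent and rejected.
## ---------------------------------------------------------------------------

.hmcControl <- function(control = list()) {
  out <- list(targetAccept = 0.8, maxSteps = 24L, initStepSize = 0.05,
              divergenceTol = 1000, gamma = 0.05, t0 = 10, kappa = 0.75)
  for (nm in names(control)) out[[nm]] <- control[[nm]]
  out
}

.hmcChain <- function(lpGrad, theta0, nIter, nWarmup, control) {
  d <- length(theta0)
  ctl <- control
  eps <- ctl$initStepSize
  muAdapt <- log(10 * eps)
  logEpsBar <- 0; hBar <- 0
  invMass <- rep(1, d)          # posterior variance estimate (M^-1)
  sqrtMass <- rep(1, d)         # sqrt(M) for momentum draws
  cur <- lpGrad(theta0)
  if (!is.finite(cur$value)) stop("failure to initialize: log density not finite")
  theta <- theta0
  keep <- matrix(NA_real_, nIter - nWarmup, d)
  accepts <- 0; divergences <- 0
  winStart <- floor(nWarmup / 2) + 1
  winBuf <- matrix(NA_real_, max(nWarmup - winStart + 1, 1), d)
  winN <- 0
  for (it in seq_len(nIter)) {
    p0 <- stats::rnorm(d) * sqrtMass
    h0 <- -cur$value + 0.5 * sum(p0^2 * invMass)
    L <- sample.int(ctl$maxSteps, 1)
    th <- theta; p <- p0; g <- cur$grad
    ok <- TRUE
    for (l in seq_len(L)) {
      p <- p + 0.5 * eps * g
      th <- th + eps * invMass * p
      prop <- lpGrad(th)
      if (!is.finite(prop$value)) { ok <- FALSE; break }
      g <- prop$grad
      p <- p + 0.5 * eps * g
    }
    if (ok) {
      h1 <- -prop$value + 0.5 * sum(p^2 * invMass)
      dH <- h1 - h0
      aProb <- if (is.finite(dH)) min(1, exp(-dH)) else 0
      if (!is.finite(dH) || dH > ctl$divergenceTol) divergences <- divergences + 1
    } else {
      aProb <- 0
      divergences <- divergences + 1
    }
    if (stats::runif(1) < aProb) {
      theta <- th; cur <- prop; accepts <- accepts + 1
    }
    if (it <= nWarmup) {
      ## dual averaging (Hoffman & Gelman 2014 scheme)
      m <- it
      hBar <- (1 - 1 / (m + ctl$t0)) * hBar +
        (ctl$targetAccept - aProb) / (m + ctl$t0)
      logEps <- muAdapt - sqrt(m) / ctl$gamma * hBar
      eta <- m^(-ctl$kappa)
      logEpsBar <- eta * logEps + (1 - eta) * logEpsBar
      eps <- exp(logEps)
      if (it >= winStart) {
        winN <- winN + 1
        winBuf[winN, ] <- theta
      }
      if (it == nWarmup) {
        if (winN >= 10) {
          v <- apply(winBuf[seq_len(winN), , drop = FALSE], 2, stats::var)
          v[!is.finite(v) | v <= 1e-10] <- 1e-10
          invMass <- v
          sqrtMass <- 1 / sqrt(v)
        }
        eps <- exp(logEpsBar)
      }
    } else {
      keep[it - nWarmup, ] <- theta
    }
  }
  list(draws = keep, acceptRate = accepts / nIter,
       divergences = divergences, stepSize = eps)
}

## Run several chains; returns array (chains, retained, dim) plus
## per-chain diagnostics.  Seeded deterministically per chain.
.hmcSample <- function(lpGrad, initFun, chains, nIter, nWarmup, seed,
                       control = list()) {
  ctl <- .hmcControl(control)
  nKeep <- nIter - nWarmup
  stopifnot(nKeep > 0)
  out <- NULL
  diag <- list()
  for (ch in seq_len(chains)) {
    res <- .withSeed(seed + 1000L * ch, {
      th0 <- initFun()
      .hmcChain(lpGrad, th0, nIter, nWarmup, ctl)
    })
    if (is.null(out)) {
      out <- array(NA_real_, c(chains, nKeep, ncol(res$draws)))
    }
    out[ch, , ] <- res$draws
    diag[[ch]] <- res[c("acceptRate", "divergences", "stepSize")]
  }
  list(theta = out, diagnostics = diag)
}

## MAP + diagonal Laplace approximation: the fast screening pass.  The
## mode is found by L-BFGS on the joint log density; "draws" are sampled
## from a mean-field Gaussian centred at the mode whose per-coordinate
## precisions come from a central-difference diagonal Hessian.
.laplaceSample <- function(lpGrad, initFun, chains, nKeep, seed,
                           maxit = 500) {
  .withSeed(seed, {
    th0 <- initFun()
    fn <- function(th) {
      v <- lpGrad(th)$value
      if (!is.finite(v)) 1e10 else -v
    }
    gr <- function(th) -lpGrad(th)$grad
    opt <- stats::optim(th0, fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    mode <- opt$par
    d <- length(mode)
    h <- numeric(d)
    step <- 1e-4
    for (i in seq_len(d)) {
      e <- numeric(d); e[i] <- step
      h[i] <- (lpGrad(mode + e)$grad[i] - lpGrad(mode - e)$grad[i]) / (2 * step)
    }
    prec <- pmax(-h, 1e-6)
    sd <- 1 / sqrt(prec)
    out <- array(NA_real_, c(chains, nKeep, d))
    for (ch in seq_len(chains)) {
      out[ch, , ] <- matrix(stats::rnorm(nKeep * d, mean = rep(mode, each = nKeep),
                                         sd = rep(sd, each = nKeep)),
                            nKeep, d)
    }
    list(theta = out,
         diagnostics = list(list(convergence = opt$convergence,
                                 logPosteriorAtMode = -opt$value)))
  })
}
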