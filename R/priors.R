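#' @include AllClasses.R AllGenerics.R
NULL

.halfCauchyLogPdf <- function(x, scale = 1) {
  if (any(x <= 0) || any(scale <= 0)) stop("half-Cauchy needs positive values")
  log(2 / pi) - log(scale) - log1p((x / scale)^2)
}

## regularized local scale: lambda_tilde^2 = c^2 lambda^2 / (c^2 + tau^2 lambda^2)
.lambdaTilde <- function(lambda, tau, c) {
  c * lambda / sqrt(c^2 + tau^2 * lambda^2)
}

#' Regularized horseshoe log density
#'
#' Sparsity-inducing shrinkage prior: \eqn{\beta_j \sim N(0, \tau^2
#' \tilde\lambda_j^2)} with \eqn{\tilde\lambda_j^2 = c^2 \lambda_j^2 /
#' (c^2 + \tau^2 \lambda_j^2)}.  Small-\eqn{\lambda_j} coefficients are
#' shrunk hard toward zero while the slab width \eqn{c} caps the prior
#' standard deviation of large coefficients.  With
#' \code{includeHyperpriors = TRUE} the kernel adds half-Cauchy(0, 1)
#' terms for each \eqn{\lambda_j}, a half-Cauchy(0, tauScale) term for
#' \eqn{\tau}, and an inverse-gamma(slabShape, slabRate) term for
#' \eqn{c^2}.
#'
#' @param beta coefficient vector.
#' @param lambda positive local scales (same length as beta).
#' @param tau positive global scale.
#' @param c positive slab scale.
#' @param tauScale scale of the half-Cauchy prior on tau.
#' @param slabShape,slabRate inverse-gamma hyperparameters for c^2.
#' @param includeHyperpriors include the hyperprior terms (default TRUE).
#' @return scalar log density (up to constants from any omitted terms).
#' @export
regularizedHorseshoeLogDensity <- function(beta, lambda, tau, c,
                                           tauScale = 1,
                                           slabShape = 2, slabRate = 8,
                                           includeHyperpriors = TRUE) {
  if (length(lambda) != length(beta)) stop("lambda must match beta in length")
  if (any(lambda <= 0) || tau <= 0 || c <= 0) stop("scales must be > 0")
  sd <- tau * .lambdaTilde(lambda, tau, c)
  out <- sum(stats::dnorm(beta, 0, sd, log = TRUE))
  if (includeHyperpriors) {
    out <- out + sum(.halfCauchyLogPdf(lambda, 1)) +
      .halfCauchyLogPdf(tau, tauScale)
    c2 <- c^2
    out <- out + slabShape * log(slabRate) - lgamma(slabShape) -
      (slabShape + 1) * log(c2) - slabRate / c2
  }
  out
}

#' Paired (bivariate) horseshoe log density
#'
#' Shares one local scale \eqn{\lambda_j} between the count-mean and
#' zero-inflation coefficients of column j: \eqn{(\beta^{(\mu)}_j,
#' \beta^{(\pi)}_j)} is bivariate normal with common standard deviation
#' \eqn{\tau \tilde\lambda_j} and correlation \eqn{\rho}, allowing
#' information sharing between the two model components.
#'
#' @param betaMu,betaPi coefficient vectors (equal length).
#' @param lambda shared positive local scales.
#' @param tau,c global and slab scales (> 0).
#' @param rho cross-component correlation, |rho| < 1.
#' @param includeHyperpriors also add the lambda/tau/c hyperprior terms as
#'   in \code{\link{regularizedHorseshoeLogDensity}} (default FALSE: the
#'   bivariate normal term only).
#' @inheritParams regularizedHorseshoeLogDensity
#' @return scalar log density.
#' @export
pairedHorseshoeLogDensity <- function(betaMu, betaPi, lambda, tau, c, rho,
                                      tauScale = 1, slabShape = 2,
                                      slabRate = 8,
                                      includeHyperpriors = FALSE) {
  if (length(betaMu) != length(betaPi)) stop("betaMu/betaPi length mismatch")
  if (length(lambda) != length(betaMu)) stop("lambda must match beta in length")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (any(lambda <= 0) || tau <= 0 || c <= 0) stop("scales must be > 0")
  s <- tau * .lambdaTilde(lambda, tau, c)
  q <- (betaMu^2 - 2 * rho * betaMu * betaPi + betaPi^2) / (s^2 * (1 - rho^2))
  out <- sum(-log(2 * pi) - 2 * log(s) - 0.5 * log1p(-rho^2) - q / 2)
  if (includeHyperpriors) {
    out <- out + sum(.halfCauchyLogPdf(lambda, 1)) +
      .halfCauchyLogPdf(tau, tauScale)
    c2 <- c^2
    out <- out + slabShape * log(slabRate) - lgamma(slabShape) -
      (slabShape + 1) * log(c2) - slabRate / c2
  }
  out
}

.asEdgeIndex <- function(adjacency, n) {
  if (is(adjacency, "EcoregionHierarchy")) {
    e <- adjacency@edges
    idx <- matrix(match(e, l3Regions(adjacency)), ncol = 2)
    if (n != length(l3Regions(adjacency))) {
      stop("phi length must equal the number of L3 regions")
    }
    return(idx)
  }
  e <- adjacency
  if (!is.matrix(e) || ncol(e) != 2) stop("adjacency must be a 2-column matrix")
  storage.mode(e) <- "integer"
  if (any(e < 1) || any(e > n)) stop("edge index out of range")
  if (!.graphConnected(as.character(seq_len(n)),
                       matrix(as.character(e), ncol = 2))) {
    stop("adjacency graph must be connected")
  }
  e
}

#' Intrinsic CAR (ICAR) log density for one time step
#'
#' Pairwise-difference kernel
#' \eqn{-\frac{1}{2\tau_\phi^2}\sum_{(i,j)\in E}(\phi_i-\phi_j)^2}
#' (each unordered edge once), equal to \eqn{-\phi^\top Q \phi /
#' (2\tau_\phi^2)} with \eqn{Q} the graph Laplacian.  The kernel is
#' improper (invariant to adding a constant); identifiability is restored
#' by a soft sum-to-zero term: spatial mean \eqn{\sim N(0, 0.001 S)}.
#'
#' @param phi effect vector over the S regions.
#' @param adjacency an \linkS4class{EcoregionHierarchy} (phi ordered as
#'   \code{l3Regions}) or a 2-column integer edge matrix over 1..S (must
#'   describe a connected graph).
#' @param tauPhi innovation scale (> 0).
#' @param sumToZero include the soft constraint term (default TRUE).
#' @param sumToZeroSd its standard deviation (default 0.001 * S).
#' @return scalar log density, up to an additive constant.
#' @export
icarLogDensity <- function(phi, adjacency, tauPhi, sumToZero = TRUE,
                           sumToZeroSd = 0.001 * length(phi)) {
  if (tauPhi <= 0) stop("tauPhi must be > 0")
  e <- .asEdgeIndex(adjacency, length(phi))
  d <- phi[e[, 1]] - phi[e[, 2]]
  out <- -sum(d^2) / (2 * tauPhi^2)
  if (sumToZero) out <- out + stats::dnorm(mean(phi), 0, sumToZeroSd, log = TRUE)
  out
}

#' AR(1) x ICAR spatiotemporal log density
#'
#' Temporally autoregressive, spatially intrinsically autoregressive
#' effects: the ICAR kernel is applied to the first column of
#' \eqn{\Phi} and to the innovations
#' \eqn{\Phi_{\cdot,t} - \eta\,\Phi_{\cdot,t-1}} for \eqn{t \ge 2}, with a
#' soft sum-to-zero term on every column.
#'
#' @param Phi S x T matrix of spatiotemporal adjustments.
#' @param adjacency as in \code{\link{icarLogDensity}}.
#' @param arCoef AR(1) coefficient, |arCoef| < 1.
#' @param tauPhi innovation scale (> 0).
#' @param sumToZeroSd soft-constraint sd (default 0.001 * S).
#' @return scalar log density, up to an additive constant.
#' @export
arIcarLogDensity <- function(Phi, adjacency, arCoef, tauPhi,
                             sumToZeroSd = 0.001 * nrow(Phi)) {
  if (abs(arCoef) >= 1) stop("|arCoef| must be < 1")
  if (tauPhi <= 0) stop("tauPhi must be > 0")
  Phi <- as.matrix(Phi)
  e <- .asEdgeIndex(adjacency, nrow(Phi))
  innov <- Phi
  if (ncol(Phi) > 1) {
    innov[, -1] <- Phi[, -1, drop = FALSE] -
      arCoef * Phi[, -ncol(Phi), drop = FALSE]
  }
  d <- innov[e[, 1], , drop = FALSE] - innov[e[, 2], , drop = FALSE]
  -sum(d^2) / (2 * tauPhi^2) +
    sum(stats::dnorm(colMeans(Phi), 0, sumToZeroSd, log = TRUE))
}

## Draw one ICAR-distributed spatial field (sum-to-zero, unit scale) using
## the Laplacian pseudo-inverse; used by the synthetic-data generator.
.icarDraw <- function(edgeIdx, s) {
  Q <- matrix(0, s, s)
  for (k in seq_len(nrow(edgeIdx))) {
    i <- edgeIdx[k, 1]; j <- edgeIdx[k, 2]
    Q[i, i] <- Q[i, i] + 1; Q[j, j] <- Q[j, j] + 1
    Q[i, j] <- Q[i, j] - 1; Q[j, i] <- Q[j, i] - 1
  }
  eg <- eigen(Q, symmetric = TRUE)
  pos <- eg$values > 1e-8 * max(eg$values)
  z <- stats::rnorm(sum(pos))
  as.numeric(eg$vectors[, pos, drop = FALSE] %*% (z / sqrt(eg$values[pos])))
}
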