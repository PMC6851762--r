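#' @include AllClasses.R
NULL

#' Fit a B-spline specification to training values
#'
#' Boundary knots at the training minimum and maximum; interior knots at
#' \code{df - degree - 1} equally spaced quantiles of the training values.
#' The resulting basis has dimension \code{df} and its span includes the
#' constant function (the basis is a partition of unity), so the model
#' keeps its separate scalar intercept.
#'
#' @param values training covariate values (raw scale).
#' @param covariate covariate name.
#' @param df basis dimension (default 5).
#' @param degree B-spline degree (default 3, cubic).
#' @param logTransform log-transform values first (used for housing
#'   density); requires positive values.
#' @return a \linkS4class{SplineSpec}.
#' @examples
#' sp <- makeSplineSpec(runif(100), "wind", df = 5)
#' @export
makeSplineSpec <- function(values, covariate, df = 5L, degree = 3L,
                           logTransform = FALSE) {
  df <- as.integer(df); degree <- as.integer(degree)
  if (df < degree + 1L) stop("df must be at least degree + 1")
  if (logTransform) {
    if (any(values <= 0)) stop("logTransform requires positive values")
    values <- log(values)
  }
  values <- values[is.finite(values)]
  if (length(unique(values)) < df) {
    stop("need at least df distinct training values for '", covariate, "'")
  }
  b <- range(values)
  if (diff(b) <= 0) stop("constant input: no spread in '", covariate, "'")
  nInterior <- df - degree - 1L
  interior <- if (nInterior > 0) {
    q <- stats::quantile(values, probs = seq_len(nInterior) / (nInterior + 1),
                         names = FALSE, type = 7)
    if (anyDuplicated(q) || any(q <= b[1]) || any(q >= b[2])) {
      stop("degenerate interior knots for '", covariate,
           "' (tied quantiles); use fewer df or more spread")
    }
    q
  } else numeric()
  new("SplineSpec", covariate = covariate, df = df, degree = degree,
      boundary = b, interior = interior, logTransform = logTransform)
}

#' Evaluate a B-spline basis
#'
#' Values outside the boundary knots are clamped to the boundary before
#' evaluation (bounded extrapolation) with a warning.  Inside the
#' boundary the basis rows sum to one (partition of unity).
#'
#' @param spec a \linkS4class{SplineSpec}.
#' @param x covariate values (raw scale; log-transformed internally if the
#'   spec says so).
#' @param warnClamp warn when values are clamped (default TRUE).
#' @return numeric matrix, length(x) rows by \code{df} columns.
#' @export
evaluateBasis <- function(spec, x, warnClamp = TRUE) {
  stopifnot(is(spec, "SplineSpec"))
  if (any(!is.finite(x))) stop("non-finite covariate values")
  if (spec@logTransform) {
    if (any(x <= 0)) stop("logTransform requires positive values")
    x <- log(x)
  }
  b <- spec@boundary
  out <- x < b[1] | x > b[2]
  if (any(out)) {
    if (warnClamp) {
      warning(sprintf("%d value(s) of '%s' outside training range; clamped",
                      sum(out), spec@covariate))
    }
    x <- pmin(pmax(x, b[1]), b[2])
  }
  ord <- spec@degree + 1L
  knots <- c(rep(b[1], ord), spec@interior, rep(b[2], ord))
  m <- splines::splineDesign(knots, x, ord = ord, outer.ok = FALSE)
  colnames(m) <- paste0(spec@covariate, "_b", seq_len(spec@df))
  m
}
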