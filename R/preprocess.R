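#' @include AllClasses.R AllGenerics.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowData colData
#' @importFrom S4Vectors DataFrame
NULL

#' Aggregate daily covariate records to monthly means
#'
#' @param daily data.frame with columns l3, year, month, value (one row
#'   per region-day).
#' @return data.frame with columns l3, year, month, value (arithmetic
#'   mean), one row per region-month, complete over the observed region
#'   and month sets.
#' @export
aggregateDailyToMonthly <- function(daily) {
  need <- c("l3", "year", "month", "value")
  if (!all(need %in% names(daily))) {
    stop("daily needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(daily$value))) stop("non-finite daily values")
  key <- interaction(daily$l3, daily$year, daily$month, drop = FALSE)
  agg <- stats::aggregate(value ~ l3 + year + month, data = daily, FUN = mean)
  ## the output grid must be complete: every region must have every
  ## observed (year, month)
  ym <- unique(daily[, c("year", "month")])
  regions <- unique(daily$l3)
  have <- paste(agg$l3, agg$year, agg$month)
  want <- paste(rep(regions, each = nrow(ym)), ym$year, ym$month)
  missing <- setdiff(want, have)
  if (length(missing)) {
    stop("no daily values for region-month cell(s): ",
         paste(utils::head(missing, 5), collapse = "; "))
  }
  agg <- agg[order(agg$year, agg$month, agg$l3), ]
  rownames(agg) <- NULL
  agg
}

#' Prior-12-month cumulative precipitation
#'
#' Value at month t is the sum over months t-12, ..., t-1 (the current
#' month is excluded).  The first 12 months have no full lag window and
#' are returned as NA (flagged unavailable).
#'
#' @param monthly numeric vector of monthly values, length >= 13.
#' @return numeric vector of the same length; NA for months 1-12.
#' @examples
#' rollingPriorPrecip(rep(1, 24))[13:24]  # all 12
#' @export
rollingPriorPrecip <- function(monthly) {
  if (length(monthly) < 13) stop("series must have length >= 13")
  if (any(!is.finite(monthly))) stop("non-finite monthly values")
  cs <- c(0, cumsum(monthly))
  out <- rep(NA_real_, length(monthly))
  t <- 13:length(monthly)
  out[t] <- cs[t] - cs[t - 12]
  out
}

#' Interpolate decadal housing densities to arbitrary times
#'
#' Piecewise linear in continuous time between anchors; beyond the last
#' anchor the line through the last two anchors is extended (and likewise
#' before the first anchor).
#'
#' @param anchorTimes strictly increasing anchor times (decimal years),
#'   at least two.
#' @param anchorValues densities at the anchors.
#' @param atTimes times at which to evaluate (e.g. month midpoints).
#' @return densities at \code{atTimes}.
#' @examples
#' interpolateHousing(c(2000, 2010), c(10, 20), 2005)   # 15
#' interpolateHousing(c(2000, 2010), c(10, 20), 2016)   # 26
#' @export
interpolateHousing <- function(anchorTimes, anchorValues, atTimes) {
  if (length(anchorTimes) < 2) stop("need at least two anchor points")
  if (length(anchorTimes) != length(anchorValues)) stop("anchor length mismatch")
  if (is.unsorted(anchorTimes, strictly = TRUE)) {
    stop("anchor times must be strictly increasing")
  }
  n <- length(anchorTimes)
  out <- stats::approx(anchorTimes, anchorValues, xout = atTimes,
                       rule = 1)$y
  lo <- atTimes < anchorTimes[1]
  hi <- atTimes > anchorTimes[n]
  if (any(lo)) {
    sl <- (anchorValues[2] - anchorValues[1]) / (anchorTimes[2] - anchorTimes[1])
    out[lo] <- anchorValues[1] + sl * (atTimes[lo] - anchorTimes[1])
  }
  if (any(hi)) {
    sl <- (anchorValues[n] - anchorValues[n - 1]) /
      (anchorTimes[n] - anchorTimes[n - 1])
    out[hi] <- anchorValues[n] + sl * (atTimes[hi] - anchorTimes[n])
  }
  out
}

#' An empty fire catalog
#'
#' @param thresholdHa size threshold in hectares (default 405).
#' @return a \linkS4class{FireCatalog} with zero events.
#' @export
emptyFireCatalog <- function(thresholdHa = 405) {
  new("FireCatalog",
      events = data.frame(event_id = character(), year = integer(),
                          month = integer(), l3 = character(),
                          size_ha = numeric(), exceedance_ha = numeric(),
                          stringsAsFactors = FALSE),
      thresholdHa = thresholdHa)
}

#' Filter raw fire events by size threshold
#'
#' Retains events whose burned area strictly exceeds the threshold
#' (default 405 ha, about 1,000 acres) and computes the exceedance
#' size_ha - threshold for the survivors.  Strict inequality keeps every
#' exceedance positive, as all five size likelihoods require.
#'
#' @param raw data.frame with columns event_id, year, month, l3, size_ha.
#' @param thresholdHa the size threshold (ha).
#' @return a \linkS4class{FireCatalog}.
#' @examples
#' raw <- data.frame(event_id = c("a", "b", "c"), year = 2000, month = 6,
#'                   l3 = "L3_01", size_ha = c(1000, 300, 500))
#' catalogEvents(filterEvents(raw))$exceedance_ha  # 595, 95
#' @export
filterEvents <- function(raw, thresholdHa = 405) {
  need <- c("event_id", "year", "month", "l3", "size_ha")
  if (!all(need %in% names(raw))) {
    stop("raw events need columns: ", paste(need, collapse = ", "))
  }
  if (any(raw$size_ha <= 0)) stop("event sizes must be positive")
  keep <- raw$size_ha > thresholdHa
  ev <- raw[keep, need, drop = FALSE]
  ev$exceedance_ha <- ev$size_ha - thresholdHa
  rownames(ev) <- NULL
  new("FireCatalog", events = ev, thresholdHa = thresholdHa)
}

#' Assemble the complete space-time panel
#'
#' Builds the S x T \linkS4class{SpaceTimePanel} from a covariate table
#' and tallies the catalog's events into cell counts (zero where no
#' events).  Months up to \code{splitMonth} are labelled train, later
#' months test.
#'
#' @param catalog a \linkS4class{FireCatalog} (may be empty).
#' @param covariates data.frame with columns l3, t, year, month and the
#'   six covariates, covering every region-month exactly once.
#' @param hierarchy an \linkS4class{EcoregionHierarchy}.
#' @param splitMonth last training time index.
#' @return a \linkS4class{SpaceTimePanel}.
#' @export
assemblePanel <- function(catalog, covariates, hierarchy, splitMonth) {
  need <- c("l3", "t", "year", "month", .panelCovariateNames)
  if (!all(need %in% names(covariates))) {
    stop("covariates need columns: ", paste(need, collapse = ", "))
  }
  l3 <- l3Regions(hierarchy)
  tt <- sort(unique(covariates$t))
  if (!splitMonth %in% tt) stop("splitMonth outside the covariate range")
  if (!all(covariates$l3 %in% l3)) {
    stop("covariate region(s) not in hierarchy: ",
         paste(setdiff(unique(covariates$l3), l3), collapse = ", "))
  }
  s <- length(l3); tn <- length(tt)
  if (nrow(covariates) != s * tn ||
      anyDuplicated(paste(covariates$l3, covariates$t))) {
    stop("covariates must cover every region-month exactly once")
  }
  i <- match(covariates$l3, l3)
  j <- match(covariates$t, tt)
  mat <- function(v) {
    m <- matrix(NA_real_, s, tn, dimnames = list(l3, paste0("t", tt)))
    m[cbind(i, j)] <- v
    m
  }
  assays <- lapply(.panelCovariateNames, function(nm) mat(covariates[[nm]]))
  names(assays) <- .panelCovariateNames
  ymKey <- paste(covariates$year, covariates$month)
  tOfYm <- covariates$t[!duplicated(ymKey)]
  names(tOfYm) <- ymKey[!duplicated(ymKey)]
  counts <- matrix(0L, s, tn, dimnames = list(l3, paste0("t", tt)))
  ev <- catalogEvents(catalog)
  if (nrow(ev)) {
    badRegion <- !ev$l3 %in% l3
    evT <- tOfYm[paste(ev$year, ev$month)]
    badTime <- is.na(evT)
    if (any(badRegion) || any(badTime)) {
      stop("events outside the panel: ",
           paste(utils::head(ev$event_id[badRegion | badTime], 10),
                 collapse = ", "))
    }
    tab <- table(factor(ev$l3, levels = l3), factor(evT, levels = tt))
    counts[] <- as.integer(tab)
  }
  ymOfT <- covariates[!duplicated(covariates$t), c("t", "year", "month")]
  ymOfT <- ymOfT[match(tt, ymOfT$t), ]
  cd <- S4Vectors::DataFrame(
    year = ymOfT$year, month = ymOfT$month, t = tt,
    split = ifelse(tt <= splitMonth, "train", "test")
  )
  rd <- S4Vectors::DataFrame(
    l3 = l3, l2 = l2Of(hierarchy, l3), l1 = l1Of(hierarchy, l3),
    area = unname(regionArea(hierarchy))
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = c(list(counts = counts), assays), rowData = rd, colData = cd
  )
  panel <- methods::new("SpaceTimePanel", se)
  attr(panel, "edges") <- adjacencyEdges(hierarchy)
  panel
}
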