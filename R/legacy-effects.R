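#' @include AllClasses.R AllGenerics.R constructors.R drought-metrics.R lag-analysis.R
NULL

#' Climate-normal NPP baseline
#'
#' Per-cell mean annual NPP over climate-normal years, i.e. years whose
#' standardized annual CWD lies in [-1, 1]. Cells with fewer than
#' `minNormalYears` qualifying years are masked: a baseline estimated from
#' a handful of years is noise.
#'
#' @param annualNPP an [AnnualField-class] of annual NPP (gC m-2 yr-1).
#' @param z the matching [StandardizedAnnualField-class] of annual CWD.
#' @param minNormalYears minimum qualifying years (default 5).
#' @return A [ClimateNormalBaseline-class].
#' @export
climateNormalBaseline <- function(annualNPP, z, minNormalYears = 5L) {
  .checkAligned(annualNPP, z, "grid")
  if (dim(annualNPP@values)[1L] != dim(z@values)[1L])
    stop("annual NPP and Z fields cover different numbers of years")
  normal <- normalYearMask(z)
  nppM <- .cellMat(annualNPP)
  nrmM <- matrix(normal, nrow = dim(normal)[1L])
  nYears <- colSums(nrmM & is.finite(nppM), na.rm = TRUE)
  sel <- nrmM & is.finite(nppM)
  sel[is.na(sel)] <- FALSE
  tmp <- nppM
  tmp[!sel] <- NA_real_
  base <- colMeans(tmp, na.rm = TRUE)
  base[nYears < minNormalYears] <- NA_real_
  base[!is.finite(base)] <- NA_real_
  d <- dim(annualNPP@values)
  new("ClimateNormalBaseline",
      meanNPP = matrix(base, d[2L], d[3L]),
      nNormalYears = matrix(as.integer(nYears), d[2L], d[3L]),
      minNormalYears = as.integer(minNormalYears))
}

#' Absolute recovery trajectory (climate-normal baseline)
#'
#' For every retained (non-excluded) drought event, the NPP anomaly in the
#' drought year (the event's last year) and the four subsequent years is
#' the difference between annual NPP and the cell's climate-normal mean
#' NPP, in gC m-2 yr-1. Multiple events at a cell are averaged together but
#' never across cells; truncated events contribute only the years they
#' cover.
#'
#' @param annualNPP an [AnnualField-class] of annual NPP.
#' @param baseline a [ClimateNormalBaseline-class].
#' @param catalog a [DroughtCatalog-class].
#' @return A [RecoveryTrajectory-class] in gC m-2 yr-1.
#' @export
absoluteTrajectory <- function(annualNPP, baseline, catalog) {
  nppM <- .cellMat(annualNPP)
  baseV <- as.vector(baseline@meanNPP)
  .buildTrajectory(catalog, nYears = nrow(nppM),
                   units = "gC m-2 yr-1", baselineTag = "climate_normal",
                   anomalyFun = function(cell, year) {
                     b <- baseV[cell]
                     if (is.na(b)) return(NA_real_)
                     nppM[year, cell] - b
                   })
}

## Shared event-walk: anomalyFun(cell, year) -> anomaly for one cell-year.
.buildTrajectory <- function(catalog, nYears, units, baselineTag,
                             anomalyFun) {
  ev <- retainedEvents(catalog)
  if (nrow(ev) == 0L) {
    return(new("RecoveryTrajectory",
               anomalies = matrix(numeric(), 0L, 5L), cells = integer(),
               lat = numeric(), lon = numeric(), units = units,
               nEvents = integer(), nAvail = matrix(integer(), 0L, 5L),
               baseline = baselineTag))
  }
  cells <- sort(unique(ev$cell))
  anom <- matrix(NA_real_, length(cells), 5L)
  nAv <- matrix(0L, length(cells), 5L)
  nEv <- integer(length(cells))
  latc <- lonc <- numeric(length(cells))
  for (ci in seq_along(cells)) {
    rows <- ev[ev$cell == cells[ci], , drop = FALSE]
    latc[ci] <- rows$lat[1L]; lonc[ci] <- rows$lon[1L]
    acc <- matrix(NA_real_, nrow(rows), 5L)
    for (ei in seq_len(nrow(rows))) {
      for (k in 0:4) {
        yr <- rows$end_year[ei] + k
        if (yr > nYears) next
        acc[ei, k + 1L] <- anomalyFun(rows$cell[ei], yr)
      }
    }
    nEv[ci] <- nrow(rows)
    nAv[ci, ] <- colSums(!is.na(acc))
    anom[ci, ] <- colMeans(acc, na.rm = TRUE)
  }
  anom[!is.finite(anom)] <- NA_real_
  keep <- rowSums(!is.na(anom)) > 0L
  new("RecoveryTrajectory",
      anomalies = anom[keep, , drop = FALSE],
      cells = as.integer(cells[keep]),
      lat = latc[keep], lon = lonc[keep], units = units,
      nEvents = nEv[keep], nAvail = nAv[keep, , drop = FALSE],
      baseline = baselineTag)
}

#' Spherical grid-cell areas
#'
#' Area of regular lat/lon cells on a sphere of radius 6,371,000 m:
#' A = R^2 * dLambda * (sin(phi2) - sin(phi1)) with phi1/phi2 the cell's
#' bounding latitudes.
#'
#' @param lat cell-center latitudes (degrees).
#' @param dLat,dLon cell sizes in degrees (default 0.5).
#' @return Numeric vector of areas (m^2), one per latitude.
#' @export
#' @examples
#' cellArea(0)   # ~3.09e9 m^2 for a 0.5-degree cell at the equator
cellArea <- function(lat, dLat = 0.5, dLon = 0.5) {
  R <- 6371000
  r <- pi / 180
  phi1 <- (lat - dLat / 2) * r
  phi2 <- (lat + dLat / 2) * r
  R^2 * (dLon * r) * (sin(phi2) - sin(phi1))
}

#' Regional integral of an anomaly map
#'
#' Area-weighted integral of a per-cell anomaly (gC m-2 yr-1) over the
#' unmasked cells, in PgC yr-1: sum(anomaly * cellArea) / 1e15.
#'
#' @param anomaly numeric matrix (nLat, nLon), gC m-2 yr-1; NA cells are
#'   skipped.
#' @param lat,lon cell-center degrees matching the matrix.
#' @param dLat,dLon cell sizes in degrees.
#' @return list(pgc: integral in PgC yr-1, area: total unmasked area m^2).
#' @export
regionalIntegral <- function(anomaly, lat, lon, dLat = 0.5, dLon = 0.5) {
  stopifnot(nrow(anomaly) == length(lat), ncol(anomaly) == length(lon))
  areas <- matrix(cellArea(lat, dLat, dLon), nrow = length(lat),
                  ncol = length(lon))
  ok <- !is.na(anomaly)
  list(pgc = sum(anomaly[ok] * areas[ok]) / 1e15,
       area = sum(areas[ok]))
}

#' Per-cell regression of annual NPP on annual CWD
#'
#' Ordinary least squares over the full record at each cell, with the
#' Pearson correlation, its nominal p-value, and Benjamini-Hochberg
#' adjusted p-values across all valid cells. A cell is selected for the
#' percent-anomaly analysis when the adjusted p is below alpha and
#' r > rThreshold (strict inequality). Cells with zero CWD variance are
#' masked.
#'
#' @param annualNPP,annualCWD aligned [AnnualField-class] objects.
#' @param alpha FDR level (default 0.05).
#' @param rThreshold correlation threshold for selection (default 0.3,
#'   matching the criterion used to select tree-ring chronologies in the
#'   observational benchmark).
#' @param domain optional logical (nLat, nLon) restriction of the family.
#' @return A [RegressionBaseline-class].
#' @export
fitCwdNppRegression <- function(annualNPP, annualCWD, alpha = 0.05,
                                rThreshold = 0.3, domain = NULL) {
  .checkAligned(annualNPP, annualCWD, "grid")
  nppM <- .cellMat(annualNPP)
  cwdM <- .cellMat(annualCWD)
  if (nrow(nppM) != nrow(cwdM))
    stop("annual NPP and CWD cover different numbers of years")
  n <- nrow(nppM)
  valid <- as.vector(annualNPP@mask & annualCWD@mask)
  if (!is.null(domain)) valid <- valid & as.vector(domain)

  mx <- colMeans(cwdM); my <- colMeans(nppM)
  sxx <- colSums(sweep(cwdM, 2L, mx, "-")^2)
  syy <- colSums(sweep(nppM, 2L, my, "-")^2)
  sxy <- colSums(sweep(cwdM, 2L, mx, "-") * sweep(nppM, 2L, my, "-"))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  r <- sxy / sqrt(sxx * syy)
  bad <- !valid | !is.finite(r) | sxx == 0
  slope[bad] <- intercept[bad] <- r[bad] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  pAdj <- fdrAdjust(p)
  sel <- !is.na(pAdj) & pAdj < alpha & r > rThreshold

  d <- dim(annualNPP@values)
  mat <- function(v) matrix(v, d[2L], d[3L])
  new("RegressionBaseline", slope = mat(slope), intercept = mat(intercept),
      r = mat(r), pValue = mat(p), pAdj = mat(pAdj), selected = mat(sel),
      alpha = alpha, rThreshold = rThreshold)
}

#' Percent recovery trajectory (CWD-regression baseline)
#'
#' For selected cells (significant NPP~CWD correlation with r above the
#' threshold), the anomaly at event year y_k is the percent difference
#' between simulated NPP and the NPP expected from that year's annual CWD:
#' 100 * (NPP - NPPhat) / NPPhat with NPPhat = slope * CWD + intercept. A
#' non-zero value measures how far NPP is operating outside its typical
#' relationship with climate; the drought year uses the event's last-year
#' CWD. Cell-years with non-positive predicted NPP are masked with a
#' warning.
#'
#' @param annualNPP,annualCWD aligned [AnnualField-class] objects.
#' @param baseline a [RegressionBaseline-class] from
#'   [fitCwdNppRegression()].
#' @param catalog a [DroughtCatalog-class].
#' @return A [RecoveryTrajectory-class] in percent.
#' @export
percentTrajectory <- function(annualNPP, baseline, annualCWD, catalog) {
  nppM <- .cellMat(annualNPP)
  cwdM <- .cellMat(annualCWD)
  slope <- as.vector(baseline@slope)
  inter <- as.vector(baseline@intercept)
  selected <- as.vector(baseline@selected)
  nBadPred <- 0L
  out <- .buildTrajectory(catalog, nYears = nrow(nppM),
                          units = "percent", baselineTag = "cwd_regression",
                          anomalyFun = function(cell, year) {
                            if (!isTRUE(selected[cell])) return(NA_real_)
                            pred <- slope[cell] * cwdM[year, cell] + inter[cell]
                            if (!is.finite(pred) || pred <= 0) {
                              nBadPred <<- nBadPred + 1L
                              return(NA_real_)
                            }
                            100 * (nppM[year, cell] - pred) / pred
                          })
  if (nBadPred > 0L)
    warning(nBadPred,
            " cell-years with non-positive predicted NPP were masked")
  out
}

#' Restrict trajectories to one forest type
#'
#' Keeps the cells whose dominant forest class (highest fractional cover)
#' matches `class` and whose purity (that maximum fraction) is at least
#' `minPurity`. The default minPurity = 0 reproduces the dominant-class
#' stratification of the main analysis; a high threshold gives the
#' high-purity sensitivity variant. An empty selection returns an empty
#' trajectory, not an error.
#'
#' @param trajectory a [RecoveryTrajectory-class].
#' @param forest a [ForestTypeMap-class] on the trajectory's grid.
#' @param class one of `forestClasses(forest)`.
#' @param minPurity minimum dominant-class cover fraction (default 0).
#' @return A [RecoveryTrajectory-class] with the retained cells.
#' @export
stratifyByForest <- function(trajectory, forest, class, minPurity = 0) {
  class <- match.arg(class, forestClasses(forest))
  classIdx <- match(class, forestClasses(forest))
  dom <- as.vector(dominantClass(forest))
  pur <- as.vector(purity(forest))
  keepCell <- which(!is.na(dom) & dom == classIdx & pur >= minPurity)
  keep <- trajectory@cells %in% keepCell
  new("RecoveryTrajectory",
      anomalies = trajectory@anomalies[keep, , drop = FALSE],
      cells = trajectory@cells[keep],
      lat = trajectory@lat[keep], lon = trajectory@lon[keep],
      units = trajectory@units, nEvents = trajectory@nEvents[keep],
      nAvail = trajectory@nAvail[keep, , drop = FALSE],
      baseline = trajectory@baseline)
}
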