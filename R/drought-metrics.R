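#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' Climatic water deficit from precipitation and PET
#'
#' CWD = precipitation minus potential evapotranspiration, elementwise on
#' aligned monthly grids. Negative values indicate plant water stress. The
#' output mask is the intersection of the input masks.
#'
#' @param precip,pet aligned [MonthlyField-class] objects in the same units
#'   (mm month-1).
#' @return A [MonthlyField-class] named "cwd".
#' @export
#' @examples
#' p  <- monthlyField(array(100, c(12, 1, 1)), 45, 5, units = "mm month-1")
#' e  <- monthlyField(array(80,  c(12, 1, 1)), 45, 5, units = "mm month-1")
#' fieldValues(computeCWD(p, e))[1, 1, 1]   # 20
computeCWD <- function(precip, pet) {
  .checkAligned(precip, pet)
  if (nzchar(precip@units) && nzchar(pet@units) &&
      !identical(precip@units, pet@units))
    stop("precip and pet units differ: '", precip@units, "' vs '",
         pet@units, "'")
  monthlyField(precip@values - pet@values, precip@lat, precip@lon,
               startYear = precip@startYear, units = precip@units,
               varname = "cwd", mask = precip@mask & pet@mask)
}

#' Nearest-neighbour regridding
#'
#' Maps a field from its native grid to a target regular grid by assigning
#' each target cell the value of the source cell whose center is nearest in
#' great-circle distance. Values are replicated, never interpolated (used
#' for bringing 1.0-degree PET onto the 0.5-degree analysis grid). Target
#' cells farther from every source center than the source grid spacing are
#' masked and counted in a warning.
#'
#' @param field a [MonthlyField-class] (or [AnnualField-class]) on the
#'   source grid.
#' @param targetLat,targetLon strictly increasing cell-center degrees of
#'   the target grid.
#' @return A field of the same class on the target grid.
#' @export
regridNearest <- function(field, targetLat, targetLon) {
  srcLat <- field@lat; srcLon <- field@lon
  ## regular grids: candidate source cells are the few nearest in each axis;
  ## great-circle distance decides among them
  latCand <- .nearestIdx(targetLat, srcLat, k = 2L)
  lonCand <- .nearestIdx(targetLon, srcLon, k = 2L)
  dLatMax <- if (length(srcLat) > 1L) max(diff(srcLat)) else Inf
  dLonMax <- if (length(srcLon) > 1L) max(diff(srcLon)) else Inf
  maxDist <- .gcDist(0, 0, dLatMax, dLonMax)  # coverage tolerance

  nT <- dim(field@values)[1L]
  out <- array(NA_real_, c(nT, length(targetLat), length(targetLon)))
  mask <- matrix(FALSE, length(targetLat), length(targetLon))
  nOutside <- 0L
  for (j in seq_along(targetLon)) {
    for (i in seq_along(targetLat)) {
      cand <- expand.grid(li = latCand[[i]], lj = lonCand[[j]])
      d <- .gcDist(targetLat[i], targetLon[j],
                   srcLat[cand$li], srcLon[cand$lj])
      b <- which.min(d)
      if (d[b] > maxDist + 1e-9) {
        nOutside <- nOutside + 1L
        next
      }
      out[, i, j] <- field@values[, cand$li[b], cand$lj[b]]
      mask[i, j] <- field@mask[cand$li[b], cand$lj[b]]
    }
  }
  if (nOutside > 0L)
    warning(nOutside, " target cells outside source coverage were masked")
  if (is(field, "MonthlyField"))
    monthlyField(out, targetLat, targetLon, startYear = field@startYear,
                 units = field@units, varname = field@varname, mask = mask)
  else
    annualField(out, targetLat, targetLon, startYear = field@startYear,
                units = field@units, varname = field@varname, mask = mask,
                derivation = field@derivation)
}

.nearestIdx <- function(x, grid, k = 2L) {
  lapply(x, function(v) {
    o <- order(abs(grid - v))
    o[seq_len(min(k, length(o)))]
  })
}

## great-circle distance (km) on a sphere, vectorized over point 2
.gcDist <- function(lat1, lon1, lat2, lon2) {
  r <- pi / 180
  a <- sin((lat2 - lat1) * r / 2)^2 +
    cos(lat1 * r) * cos(lat2 * r) * sin((lon2 - lon1) * r / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Annual totals of a monthly field
#'
#' Sums each calendar year's 12 months per cell. A cell-year containing any
#' masked (non-finite) month is set to NA; cells masked in the input stay
#' masked.
#'
#' @param monthly a [MonthlyField-class] covering whole calendar years.
#' @param fun aggregation over the 12 months: "sum" (default; e.g. CWD or
#'   NPP in per-month units giving per-year totals) or "mean".
#' @return An [AnnualField-class].
#' @export
annualTotal <- function(monthly, fun = c("sum", "mean")) {
  fun <- match.arg(fun)
  d <- dim(monthly@values)
  if (d[1L] %% 12L != 0L)
    stop("monthly field must cover whole calendar years")
  nY <- d[1L] %/% 12L
  m <- matrix(monthly@values, nrow = 12L)      # 12 x (nY * nCell)
  agg <- if (fun == "sum") colSums(m) else colMeans(m)
  agg[colSums(!is.finite(m)) > 0L] <- NA_real_
  out <- array(agg, c(nY, d[2L], d[3L]))
  annualField(out, monthly@lat, monthly@lon, startYear = monthly@startYear,
              units = sub("month-1", "yr-1", monthly@units, fixed = TRUE),
              varname = monthly@varname,
              mask = monthly@mask & apply(is.finite(out), c(2L, 3L), all),
              derivation = fun)
}

#' Per-cell Z-scoring of an annual field
#'
#' Standardizes each cell's annual series over the full record: subtract
#' the mean and divide by the sample standard deviation (n - 1 denominator).
#' Cells with zero variance (degenerate series) are masked rather than
#' producing NaN, and their count is reported via an attribute and a
#' message.
#'
#' @param annual an [AnnualField-class] with >= 2 years.
#' @param quiet suppress the degenerate-cell message.
#' @return A [StandardizedAnnualField-class]; attribute "nDegenerate"
#'   carries the zero-variance cell count.
#' @export
#' @examples
#' af <- annualField(array(c(1, 2, 3), c(3, 1, 1)), 45, 5)
#' fieldValues(zscoreAnnual(af))[, 1, 1]   # -1 0 1
zscoreAnnual <- function(annual, quiet = FALSE) {
  d <- dim(annual@values)
  if (d[1L] < 2L) stop("need at least 2 years to Z-score")
  m <- matrix(annual@values, nrow = d[1L])
  mu <- colMeans(m)
  sdv <- apply(m, 2L, stats::sd)
  degen <- is.finite(sdv) & sdv == 0
  sdv[degen | !is.finite(sdv)] <- NA_real_
  z <- sweep(sweep(m, 2L, mu, "-"), 2L, sdv, "/")
  mask <- annual@mask & matrix(!degen & is.finite(sdv), d[2L], d[3L])
  nDegen <- sum(degen & as.vector(annual@mask))
  if (nDegen > 0L && !quiet)
    message(nDegen, " zero-variance cells masked during Z-scoring")
  out <- new("StandardizedAnnualField",
             values = array(z, d), lat = annual@lat, lon = annual@lon,
             startYear = annual@startYear, units = "z-score",
             varname = annual@varname, mask = mask,
             derivation = annual@derivation,
             cellMean = matrix(mu, d[2L], d[3L]),
             cellSD = matrix(sdv, d[2L], d[3L]))
  attr(out, "nDegenerate") <- nDegen
  out
}

#' Identify extreme drought events
#'
#' Flags, per cell, runs of consecutive years with standardized annual CWD
#' at or below `threshold` (default -2). Each run is one event whose
#' analysis anchor ("drought year") is the run's last year. An event is
#' excluded when another extreme year occurs within `exclusionWindow` years
#' after its end (the recovery window would be contaminated by the next
#' drought); events whose post-drought window extends past the record end
#' are retained but flagged truncated, with the number of available
#' post-drought years recorded.
#'
#' @param z a [StandardizedAnnualField-class] (annual CWD in Z units).
#' @param threshold extreme-drought Z threshold (years with Z <= threshold).
#' @param exclusionWindow integer, post-drought years scanned for follow-up
#'   extremes (default 4).
#' @return A [DroughtCatalog-class].
#' @export
#' @examples
#' set.seed(1)
#' z <- zscoreAnnual(annualField(array(rnorm(61), c(61, 1, 1)), 45, 5))
#' identifyDroughtEvents(z)
identifyDroughtEvents <- function(z, threshold = -2, exclusionWindow = 4L) {
  exclusionWindow <- as.integer(exclusionWindow)
  m <- .cellMat(z)
  nY <- nrow(m)
  coords <- .cellCoords(z@lat, z@lon)
  res <- vector("list", ncol(m))
  for (cc in seq_len(ncol(m))) {
    zi <- m[, cc]
    if (all(is.na(zi))) next
    ext <- !is.na(zi) & zi <= threshold
    if (!any(ext)) next
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    starts <- starts[keep]; ends <- ends[keep]
    extYears <- which(ext)
    n <- length(starts)
    excl <- logical(n); reason <- character(n)
    trunc <- logical(n); nAvail <- integer(n)
    for (k in seq_len(n)) {
      win <- seq(ends[k] + 1L, min(ends[k] + exclusionWindow, nY))
      if (ends[k] >= nY) win <- integer()
      if (any(ext[win])) {
        excl[k] <- TRUE
        reason[k] <- sprintf("followed by extreme drought within %d years",
                             exclusionWindow)
      }
      nAvail[k] <- min(exclusionWindow, nY - ends[k])
      trunc[k] <- nAvail[k] < exclusionWindow
    }
    res[[cc]] <- data.frame(
      cell = coords$cell[cc], lat = coords$lat[cc], lon = coords$lon[cc],
      start_year = starts, end_year = ends, excluded = excl,
      reason = reason, truncated = trunc, n_post_available = nAvail
    )
  }
  ev <- do.call(rbind, res[!vapply(res, is.null, logical(1))])
  if (is.null(ev))
    ev <- data.frame(cell = integer(), lat = numeric(), lon = numeric(),
                     start_year = integer(), end_year = integer(),
                     excluded = logical(), reason = character(),
                     truncated = logical(), n_post_available = integer())
  new("DroughtCatalog", events = ev, threshold = threshold,
      exclusionWindow = exclusionWindow, nYears = as.integer(nY))
}

#' Normal-hydrology year mask
#'
#' TRUE where the standardized annual CWD lies in the closed interval
#' [-1, 1] ("climate-normal" years used for the baseline NPP).
#'
#' @param z a [StandardizedAnnualField-class].
#' @param lower,upper interval bounds (inclusive).
#' @return Logical array with the field's (year, lat, lon) dimensions; NA at
#'   masked cells.
#' @export
normalYearMask <- function(z, lower = -1, upper = 1) {
  d <- dim(z@values)
  m <- matrix(z@values, nrow = d[1L])
  m[, !as.vector(z@mask)] <- NA_real_
  array(m >= lower & m <= upper, d)
}

#' Remove the mean seasonal cycle
#'
#' De-seasonalizes a monthly field: for each cell and calendar month,
#' subtracts that month's full-record mean. The output has per-calendar-
#' month means of zero at every valid cell. Idempotent.
#'
#' @param monthly a [MonthlyField-class] covering whole calendar years.
#' @return A [MonthlyField-class] of anomalies (same units).
#' @export
deseasonalize <- function(monthly) {
  d <- dim(monthly@values)
  nY <- d[1L] %/% 12L
  m <- matrix(monthly@values, nrow = 12L)       # 12 x (nY * nCell)
  g <- matrix(m, nrow = 12L * nY)               # back interpretation below
  ## compute per (month, cell) means across years
  arr <- array(monthly@values, c(12L, nY, d[2L] * d[3L]))
  clim <- apply(arr, c(1L, 3L), mean)           # 12 x nCell
  anom <- sweep(arr, c(1L, 3L), clim, "-")
  monthlyField(array(anom, d), monthly@lat, monthly@lon,
               startYear = monthly@startYear, units = monthly@units,
               varname = paste0(monthly@varname, "_anom"),
               mask = monthly@mask)
}

#' Analysis-domain mask
#'
#' Logical mask of cells whose centers fall inside the study's two boxes:
#' the contiguous United States (25-50 N, 125-60 W) and Europe (36-70 N,
#' 10 W-36 E), bounds inclusive.
#'
#' @param lat,lon cell-center degrees (longitudes in -180..180).
#' @param boxes a list of numeric vectors c(latMin, latMax, lonMin, lonMax);
#'   defaults to the US + Europe analysis boxes.
#' @return Logical matrix (length(lat), length(lon)).
#' @export
domainMask <- function(lat, lon,
                       boxes = list(us = c(25, 50, -125, -60),
                                    europe = c(36, 70, -10, 36))) {
  out <- matrix(FALSE, length(lat), length(lon))
  for (b in boxes) {
    inLat <- lat >= b[1] & lat <= b[2]
    inLon <- lon >= b[3] & lon <= b[4]
    out <- out | outer(inLat, inLon, "&")
  }
  out
}
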