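#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' Export a drought catalog as CSV
#'
#' Writes one row per event: cell_lat, cell_lon, start_year, end_year,
#' excluded, reason (plus truncation flags), with years as calendar years
#' when `startYear` is given.
#'
#' @param catalog a [DroughtCatalog-class].
#' @param path output file path.
#' @param startYear optional calendar year of year index 1; indices are
#'   written unchanged when omitted.
#' @return The path, invisibly.
#' @export
exportCatalogCSV <- function(catalog, path, startYear = NULL) {
  ev <- catalog@events
  off <- if (is.null(startYear)) 0L else as.integer(startYear) - 1L
  out <- data.frame(
    cell_lat = ev$lat, cell_lon = ev$lon,
    start_year = ev$start_year + off, end_year = ev$end_year + off,
    excluded = ev$excluded, reason = ev$reason,
    truncated = ev$truncated, n_post_available = ev$n_post_available
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Export recovery trajectories as tidy CSV
#'
#' One row per cell and year offset: cell, lat, lon, year_offset, anomaly,
#' units, n_events.
#'
#' @param trajectory a [RecoveryTrajectory-class].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
exportTrajectoryCSV <- function(trajectory, path) {
  n <- nrow(trajectory@anomalies)
  out <- data.frame(
    cell = rep(trajectory@cells, each = 5L),
    lat = rep(trajectory@lat, each = 5L),
    lon = rep(trajectory@lon, each = 5L),
    year_offset = rep(0:4, times = n),
    anomaly = as.vector(t(trajectory@anomalies)),
    units = trajectory@units,
    n_events = rep(trajectory@nEvents, each = 5L)
  )
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a gridded field to CF-style NetCDF
#'
#' Optional NetCDF export (dims time, lat, lon; monthly time axis in months
#' since January of the start year). Requires the `ncdf4` package.
#'
#' @param field a [MonthlyField-class] or [AnnualField-class].
#' @param path output .nc path.
#' @return The path, invisibly.
#' @export
writeFieldNetCDF <- function(field, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF export requires the 'ncdf4' package")
  nT <- dim(field@values)[1L]
  monthly <- is(field, "MonthlyField")
  tUnits <- if (monthly)
    sprintf("months since %d-01-01", field@startYear)
  else sprintf("years since %d-01-01", field@startYear)
  dimT <- ncdf4::ncdim_def("time", tUnits, seq_len(nT) - 1, unlim = TRUE)
  dimLat <- ncdf4::ncdim_def("lat", "degrees_north", field@lat)
  dimLon <- ncdf4::ncdim_def("lon", "degrees_east", field@lon)
  var <- ncdf4::ncvar_def(field@varname, field@units,
                          list(dimLon, dimLat, dimT), missval = -9999,
                          prec = "double")
  nc <- ncdf4::nc_create(path, var)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vals <- aperm(field@values, c(3L, 2L, 1L))    # (lon, lat, time)
  vals[is.na(vals)] <- -9999
  ncdf4::ncvar_put(nc, var, vals)
  invisible(path)
}

#' Read a monthly field from CF-style NetCDF
#'
#' Counterpart of [writeFieldNetCDF()] for monthly fields written with
#' dims (lon, lat, time). Requires the `ncdf4` package.
#'
#' @param path .nc path.
#' @param varname variable to read.
#' @param startYear calendar year of the first time step (default parsed
#'   from the time units when possible, else 1948).
#' @return A [MonthlyField-class].
#' @export
readMonthlyFieldNetCDF <- function(path, varname, startYear = NULL) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("NetCDF import requires the 'ncdf4' package")
  nc <- ncdf4::nc_open(path)
  on.exit(ncdf4::nc_close(nc), add = TRUE)
  vals <- ncdf4::ncvar_get(nc, varname, collapse_degen = FALSE)
  lat <- as.numeric(ncdf4::ncvar_get(nc, "lat"))
  lon <- as.numeric(ncdf4::ncvar_get(nc, "lon"))
  units <- ncdf4::ncatt_get(nc, varname, "units")$value
  if (is.null(startYear)) {
    tu <- nc$dim$time$units
    m <- regmatches(tu, regexpr("[0-9]{4}", tu))
    startYear <- if (length(m)) as.integer(m) else 1948L
  }
  vals[vals == -9999] <- NA_real_
  monthlyField(aperm(vals, c(3L, 2L, 1L)), lat, lon,
               startYear = startYear,
               units = if (is.character(units)) units else "",
               varname = varname)
}
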