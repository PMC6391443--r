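#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a monthly gridded field
#'
#' @param values numeric array, dim (nMonths, nLat, nLon); nMonths must be a
#'   multiple of 12 and time runs January..December of consecutive years.
#' @param lat,lon strictly increasing cell-center degrees.
#' @param startYear calendar year of the first time step.
#' @param units units string (e.g. "mm month-1", "gC m-2 month-1").
#' @param varname variable name (e.g. "pr", "pet", "npp").
#' @param mask optional logical (nLat, nLon) validity mask; defaults to
#'   cells with no non-finite values.
#' @return A [MonthlyField-class].
#' @export
#' @examples
#' fld <- monthlyField(array(rnorm(12 * 4), c(12, 2, 2)),
#'                     lat = c(40, 40.5), lon = c(10, 10.5),
#'                     startYear = 2000, units = "mm month-1",
#'                     varname = "pr")
#' fld
monthlyField <- function(values, lat, lon, startYear = 1948L,
                         units = "", varname = "", mask = NULL) {
  values <- .asArray3(values, length(lat), length(lon))
  if (is.null(mask)) mask <- .finiteMask(values)
  new("MonthlyField", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), startYear = as.integer(startYear),
      units = units, varname = varname, mask = mask)
}

#' Construct an annual gridded field
#'
#' @inheritParams monthlyField
#' @param values numeric array, dim (nYears, nLat, nLon).
#' @param derivation how the annual values were derived ("sum", "mean",
#'   or "input").
#' @return An [AnnualField-class].
#' @export
annualField <- function(values, lat, lon, startYear = 1948L,
                        units = "", varname = "", mask = NULL,
                        derivation = "input") {
  values <- .asArray3(values, length(lat), length(lon))
  if (is.null(mask)) mask <- .finiteMask(values)
  new("AnnualField", values = values, lat = as.numeric(lat),
      lon = as.numeric(lon), startYear = as.integer(startYear),
      units = units, varname = varname, mask = mask,
      derivation = derivation)
}

#' Construct a forest-type fractional cover map
#'
#' @param fractions numeric array (nLat, nLon, nClass) of cover fractions.
#' @param classes class labels; defaults to the three analysis classes.
#' @param lat,lon cell-center degrees.
#' @return A [ForestTypeMap-class].
#' @export
forestTypeMap <- function(fractions,
                          classes = c("needle_evergreen",
                                      "broadleaf_deciduous", "mixed"),
                          lat, lon) {
  new("ForestTypeMap", fractions = fractions, classes = classes,
      lat = as.numeric(lat), lon = as.numeric(lon))
}

#' Tree-ring legacy benchmark
#'
#' Observational benchmark for percent NPP (growth) depression in
#' post-drought years 1..4. Year 1 defaults to a 9% reduction, the value
#' reported from tree-ring analyses; years 2-4 are configurable defaults
#' describing a decaying legacy and should be overridden when better
#' estimates are available.
#'
#' @param values numeric length-4 percent depressions (positive = growth
#'   reduced below expectation).
#' @param source provenance tag carried through reports.
#' @return A [Benchmark-class].
#' @export
#' @examples
#' treeRingBenchmark()
treeRingBenchmark <- function(values = c(9, 5, 2, 0),
                              source = "tree-ring synthesis (year 1 reported; years 2-4 assumed decay)") {
  new("Benchmark", values = as.numeric(values), source = source)
}

## ---- internal helpers ------------------------------------------------

.asArray3 <- function(values, nLat, nLon) {
  if (length(dim(values)) != 3L)
    stop("'values' must be a 3-d array (time, lat, lon)")
  storage.mode(values) <- "double"
  values
}

.finiteMask <- function(values) {
  apply(is.finite(values), c(2L, 3L), all)
}

## Reshape (time, lat, lon) -> (time x nCell), cells column-major
## (lat index fastest). Invalid cells become NA columns.
.cellMat <- function(field) {
  v <- field@values
  d <- dim(v)
  m <- matrix(v, nrow = d[1L])
  m[, !as.vector(field@mask)] <- NA_real_
  m
}

## Per-cell coordinate table in the same column-major cell order.
.cellCoords <- function(lat, lon) {
  data.frame(
    cell = seq_len(length(lat) * length(lon)),
    lat  = rep(lat, times = length(lon)),
    lon  = rep(lon, each = length(lat))
  )
}

.checkAligned <- function(a, b, what = c("grid", "time")) {
  if ("grid" %in% what) {
    if (!isTRUE(all.equal(a@lat, b@lat)))
      stop("fields are not aligned on the latitude axis")
    if (!isTRUE(all.equal(a@lon, b@lon)))
      stop("fields are not aligned on the longitude axis")
  }
  if ("time" %in% what) {
    if (dim(a@values)[1L] != dim(b@values)[1L] ||
        a@startYear != b@startYear)
      stop("fields are not aligned on the time axis")
  }
  invisible(TRUE)
}
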