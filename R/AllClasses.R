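#' @import methods
NULL

## Central containers. Gridded fields are stored as plain arrays with
## dimensions (time, lat, lon); a shared logical mask (nLat x nLon) marks
## valid cells. Latitude/longitude are cell-center degrees on a regular grid.

#' Gridded field (virtual base)
#'
#' Virtual parent of [MonthlyField-class] and [AnnualField-class]. Holds a
#' numeric array with dimensions (time, lat, lon), cell-center coordinates on
#' a regular grid, the variable's units, and a per-cell validity mask.
#'
#' @slot values numeric array, dim (nTime, nLat, nLon).
#' @slot lat,lon numeric, strictly increasing cell-center degrees.
#' @slot units character scalar.
#' @slot varname character scalar.
#' @slot mask logical matrix (nLat, nLon); TRUE marks a valid cell.
#'
#' @exportClass GriddedField
setClass("GriddedField",
  representation("VIRTUAL",
    values  = "array",
    lat     = "numeric",
    lon     = "numeric",
    units   = "character",
    varname = "character",
    mask    = "matrix"
  )
)

.validGriddedField <- function(object) {
  msg <- character()
  d <- dim(object@values)
  if (length(d) != 3L)
    msg <- c(msg, "'values' must be a 3-d array (time, lat, lon)")
  else {
    if (d[2L] != length(object@lat))
      msg <- c(msg, "dim(values)[2] must equal length(lat)")
    if (d[3L] != length(object@lon))
      msg <- c(msg, "dim(values)[3] must equal length(lon)")
    if (!identical(dim(object@mask), c(d[2L], d[3L])))
      msg <- c(msg, "'mask' must be an nLat x nLon logical matrix")
  }
  if (length(object@lat) > 1L && any(diff(object@lat) <= 0))
    msg <- c(msg, "'lat' must be strictly increasing")
  if (length(object@lon) > 1L && any(diff(object@lon) <= 0))
    msg <- c(msg, "'lon' must be strictly increasing")
  if (!is.logical(object@mask))
    msg <- c(msg, "'mask' must be logical")
  if (length(msg)) msg else TRUE
}

setValidity("GriddedField", .validGriddedField)

#' Monthly gridded field
#'
#' A masked monthly raster of one variable (e.g. precipitation, PET, NPP) on
#' a regular lat/lon grid. Time is a contiguous sequence of calendar months
#' starting in January of `startYear`; whole calendar years are required by
#' the annual aggregation functions.
#'
#' @slot startYear integer, calendar year of the first (January) time step.
#'
#' @seealso [monthlyField()], [annualTotal()], [deseasonalize()]
#' @exportClass MonthlyField
setClass("MonthlyField",
  contains = "GriddedField",
  representation(startYear = "integer")
)

setValidity("MonthlyField", function(object) {
  if (dim(object@values)[1L] %% 12L != 0L)
    "number of time steps must be a multiple of 12 (whole calendar years)"
  else TRUE
})

#' Annual gridded field
#'
#' Per-year values derived from a [MonthlyField-class] by summing or
#' averaging the 12 months of each calendar year.
#'
#' @slot startYear integer, first calendar year.
#' @slot derivation character, "sum" or "mean" of months (or "input" for
#'   fields supplied directly on an annual axis).
#'
#' @exportClass AnnualField
setClass("AnnualField",
  contains = "GriddedField",
  representation(startYear = "integer", derivation = "character")
)

#' Standardized annual field
#'
#' A per-cell Z-scored [AnnualField-class]: for every valid cell the full
#' record is centred and scaled so that its mean is 0 and its sample standard
#' deviation is 1. Cells with zero variance are masked. Used as the drought
#' index: annual climatic water deficit (CWD) in Z units.
#'
#' @slot cellMean,cellSD matrices (nLat, nLon) with the statistics removed.
#'
#' @seealso [zscoreAnnual()], [identifyDroughtEvents()]
#' @exportClass StandardizedAnnualField
setClass("StandardizedAnnualField",
  contains = "AnnualField",
  representation(cellMean = "matrix", cellSD = "matrix")
)

#' Catalog of extreme drought events
#'
#' Per-cell runs of years whose standardized annual CWD is at or below the
#' extreme-drought threshold (default -2, i.e. two standard deviations below
#' the cell mean). Consecutive extreme years are merged into one event whose
#' analysis anchor ("drought year") is the last year of the run. Events
#' followed by another extreme year within the exclusion window (default 4
#' years) are flagged `excluded`; events whose post-drought window runs past
#' the end of the record are flagged `truncated` with the number of
#' available post-drought years.
#'
#' @slot events data.frame with columns cell, lat, lon, start_year,
#'   end_year, excluded, reason, truncated, n_post_available.
#' @slot threshold numeric, Z threshold (years with Z <= threshold are
#'   extreme).
#' @slot exclusionWindow integer, post-drought years checked for a follow-up
#'   extreme year.
#' @slot nYears integer, record length in years.
#'
#' @seealso [identifyDroughtEvents()], [exportCatalogCSV()]
#' @exportClass DroughtCatalog
setClass("DroughtCatalog",
  representation(
    events          = "data.frame",
    threshold       = "numeric",
    exclusionWindow = "integer",
    nYears          = "integer"
  )
)

setValidity("DroughtCatalog", function(object) {
  ev <- object@events
  need <- c("cell", "lat", "lon", "start_year", "end_year", "excluded",
            "reason", "truncated", "n_post_available")
  if (!all(need %in% names(ev)))
    return(paste("events must have columns:", paste(need, collapse = ", ")))
  if (nrow(ev) && any(ev$end_year < ev$start_year))
    return("end_year must be >= start_year")
  TRUE
})

#' Per-model lag-correlation map
#'
#' For one model: per grid cell, the maximum Pearson correlation between
#' monthly de-seasonalized NPP and CWD anomalies over lags 0..maxLag months,
#' the lag achieving it, the nominal p-value of that correlation, the
#' FDR-adjusted (Benjamini-Hochberg) p-value across all in-domain cells, and
#' the resulting significance flag (p_adj < alpha).
#'
#' @slot rMax,lagOpt,pValue,pAdj numeric matrices (nLat, nLon).
#' @slot significant logical matrix (nLat, nLon).
#' @slot maxLag integer, largest lag searched (months).
#' @slot alpha numeric, FDR level.
#' @slot model character, model identifier.
#'
#' @seealso [lagCorrelationMap()], [ensembleLagMap()]
#' @exportClass LagCorrelationResult
setClass("LagCorrelationResult",
  representation(
    rMax        = "matrix",
    lagOpt      = "matrix",
    pValue      = "matrix",
    pAdj        = "matrix",
    significant = "matrix",
    maxLag      = "integer",
    alpha       = "numeric",
    model       = "character"
  )
)

setValidity("LagCorrelationResult", function(object) {
  r <- object@rMax[object@significant & !is.na(object@rMax)]
  l <- object@lagOpt[!is.na(object@lagOpt)]
  if (length(r) && (min(r) < -1 - 1e-12 || max(r) > 1 + 1e-12))
    return("rMax must lie in [-1, 1]")
  if (length(l) && (min(l) < 0 || max(l) > object@maxLag))
    return("lagOpt must lie in [0, maxLag]")
  TRUE
})

#' Climate-normal NPP baseline
#'
#' Per-cell mean annual NPP over years of normal hydrologic conditions
#' (standardized annual CWD within [-1, 1]). Cells with fewer than
#' `minNormalYears` qualifying years are masked (NA).
#'
#' @slot meanNPP numeric matrix (nLat, nLon), gC m-2 yr-1.
#' @slot nNormalYears integer matrix (nLat, nLon).
#' @slot minNormalYears integer.
#'
#' @seealso [climateNormalBaseline()], [absoluteTrajectory()]
#' @exportClass ClimateNormalBaseline
setClass("ClimateNormalBaseline",
  representation(
    meanNPP        = "matrix",
    nNormalYears   = "matrix",
    minNormalYears = "integer"
  )
)

#' Per-cell NPP ~ CWD regression baseline
#'
#' Ordinary least squares of annual NPP on annual CWD per grid cell over the
#' full record. A cell is `selected` for the percent-anomaly analysis when
#' its correlation is significant after FDR adjustment and r > rThreshold
#' (strict).
#'
#' @slot slope,intercept,r,pValue,pAdj numeric matrices (nLat, nLon).
#' @slot selected logical matrix (nLat, nLon).
#' @slot alpha numeric FDR level; @slot rThreshold numeric (default 0.3).
#'
#' @seealso [fitCwdNppRegression()], [percentTrajectory()]
#' @exportClass RegressionBaseline
setClass("RegressionBaseline",
  representation(
    slope      = "matrix",
    intercept  = "matrix",
    r          = "matrix",
    pValue     = "matrix",
    pAdj       = "matrix",
    selected   = "matrix",
    alpha      = "numeric",
    rThreshold = "numeric"
  )
)

#' Five-year drought recovery trajectory
#'
#' Per retained grid cell, the mean NPP anomaly for the drought year (index
#' 0) and the four subsequent post-drought years, in either absolute units
#' (gC m-2 yr-1, climate-normal baseline) or percent of the NPP expected
#' from CWD (regression baseline). Multiple events at one cell are averaged
#' together but never across cells; `nAvail` counts the events contributing
#' to each year offset (events near the record end contribute only the years
#' they cover).
#'
#' @slot anomalies numeric matrix (nCell, 5), columns = year offsets 0..4.
#' @slot cells integer vector of cell indices into the source grid.
#' @slot lat,lon numeric per-cell coordinates.
#' @slot units character, "gC m-2 yr-1" or "percent".
#' @slot nEvents integer vector, events averaged per cell.
#' @slot nAvail integer matrix (nCell, 5), events contributing per offset.
#' @slot baseline character, "climate_normal" or "cwd_regression".
#'
#' @seealso [absoluteTrajectory()], [percentTrajectory()],
#'   [stratifyByForest()], [modelMeanTrajectory()]
#' @exportClass RecoveryTrajectory
setClass("RecoveryTrajectory",
  representation(
    anomalies = "matrix",
    cells     = "integer",
    lat       = "numeric",
    lon       = "numeric",
    units     = "character",
    nEvents   = "integer",
    nAvail    = "matrix",
    baseline  = "character"
  )
)

setValidity("RecoveryTrajectory", function(object) {
  n <- nrow(object@anomalies)
  if (ncol(object@anomalies) != 5L)
    return("anomalies must have 5 columns (drought year + 4 post years)")
  if (length(object@cells) != n || length(object@nEvents) != n)
    return("cells/nEvents length must match nrow(anomalies)")
  if (!identical(dim(object@nAvail), dim(object@anomalies)))
    return("nAvail must match anomalies in shape")
  TRUE
})

#' Forest-type fractional cover map
#'
#' Per-cell fractional cover for a fixed set of forest classes (needle-leaf
#' evergreen, broadleaf deciduous, mixed). The dominant class is the one
#' with the highest cover; purity is that maximum fraction.
#'
#' @slot fractions numeric array (nLat, nLon, nClass), rows sum to <= 1.
#' @slot classes character vector of class labels.
#' @slot lat,lon numeric cell-center degrees.
#'
#' @seealso [forestTypeMap()], [syntheticForestMap()], [stratifyByForest()]
#' @exportClass ForestTypeMap
setClass("ForestTypeMap",
  representation(
    fractions = "array",
    classes   = "character",
    lat       = "numeric",
    lon       = "numeric"
  )
)

setValidity("ForestTypeMap", function(object) {
  d <- dim(object@fractions)
  if (length(d) != 3L || d[3L] != length(object@classes))
    return("fractions must be (nLat, nLon, nClass)")
  fr <- object@fractions[!is.na(object@fractions)]
  if (length(fr) && (min(fr) < 0 || max(fr) > 1 + 1e-9))
    return("fractions must lie in [0, 1]")
  TRUE
})

#' Ensemble trajectory summary
#'
#' Ensemble mean of per-model spatial-mean recovery trajectories with
#' bootstrap percentile confidence intervals (models resampled with
#' replacement) and empirical across-model percentile bands.
#'
#' @slot meanTrajectory,ciLow,ciHigh numeric length-5 vectors.
#' @slot percentiles numeric matrix (nProb, 5).
#' @slot probs numeric, probabilities of the percentile bands.
#' @slot perModel numeric matrix (nModels, 5) of model-mean trajectories.
#' @slot units character.
#' @slot nModels,nBoot integers.
#'
#' @seealso [bootstrapCI()], [ensemblePercentiles()],
#'   [benchmarkComparison()]
#' @exportClass EnsembleSummary
setClass("EnsembleSummary",
  representation(
    meanTrajectory = "numeric",
    ciLow          = "numeric",
    ciHigh         = "numeric",
    percentiles    = "matrix",
    probs          = "numeric",
    perModel       = "matrix",
    units          = "character",
    nModels        = "integer",
    nBoot          = "integer"
  )
)

setValidity("EnsembleSummary", function(object) {
  ok <- is.na(object@ciLow) | is.na(object@ciHigh) |
    (object@ciLow <= object@meanTrajectory + 1e-9 &
       object@meanTrajectory <= object@ciHigh + 1e-9)
  if (!all(ok)) return("ciLow <= mean <= ciHigh must hold per year")
  TRUE
})

#' Observational legacy benchmark
#'
#' Percent NPP depression for post-drought years 1..4 derived from tree-ring
#' observations, supplied as configuration constants. The year-1 default is
#' a 9% growth reduction; later years are configurable estimates (the source
#' prints only year 1), so treat them as adjustable defaults rather than
#' measured truth.
#'
#' @slot values numeric length-4, percent depression (positive = reduced
#'   growth) for post-drought years 1..4.
#' @slot source character provenance tag.
#'
#' @seealso [treeRingBenchmark()], [benchmarkComparison()]
#' @exportClass Benchmark
setClass("Benchmark",
  representation(values = "numeric", source = "character")
)

setValidity("Benchmark", function(object) {
  if (length(object@values) != 4L || any(!is.finite(object@values)))
    return("benchmark needs 4 finite percent values (years 1..4)")
  TRUE
})

#' Synthetic pseudo-model ensemble configuration
#'
#' Parameters of the seeded generator that emulates a multi-model ensemble
#' of monthly NPP responding to CWD anomalies with a known lag and known
#' multiplicative post-drought legacy depressions. See [generateClimate()]
#' and [synthesizeNPP()] for the generative model.
#'
#' @slot nLat,nLon integer grid dimensions (>= 1).
#' @slot years integer record length (default 61, emulating 1948-2008).
#' @slot nModels integer ensemble size.
#' @slot meanNPP numeric, baseline NPP level (gC m-2 month-1).
#' @slot seasonalAmplitude numeric, NPP seasonal cycle amplitude
#'   (gC m-2 month-1).
#' @slot cwdSensitivity numeric, NPP response (gC m-2 month-1) per CWD
#'   Z-unit.
#' @slot responseLagMonths integer in 0..60, months between a CWD anomaly
#'   and the NPP response.
#' @slot legacyProfile numeric length-4, fractional NPP depression in
#'   post-drought years 1..4 (e.g. c(0.09, 0.05, 0.02, 0)).
#' @slot droughtYearDepression numeric fraction in [0, 1).
#' @slot ar1Coef numeric in [0, 1), lag-1 autocorrelation of the monthly
#'   NPP noise.
#' @slot noiseSD numeric, marginal SD of the AR(1) NPP noise
#'   (gC m-2 month-1).
#' @slot forcedDroughtYears integer vector of year indices (1-based) forced
#'   to extreme drought (annual CWD Z <= -2) by scaling precipitation down.
#' @slot precipMean,precipSeasAmp,precipLogSD,petMean,petSeasAmp numeric
#'   climate-generator parameters: mean monthly precipitation (mm),
#'   fractional seasonal amplitude, SD of the per-cell-per-year lognormal
#'   precipitation multiplier, mean monthly PET (mm), PET fractional
#'   seasonal amplitude.
#' @slot droughtThreshold numeric, Z threshold at which the generated
#'   ecosystem expresses drought depression/legacy (default -2).
#' @slot seed integer RNG seed.
#'
#' @seealso [syntheticConfig()]
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nLat                  = "integer",
    nLon                  = "integer",
    years                 = "integer",
    nModels               = "integer",
    meanNPP               = "numeric",
    seasonalAmplitude     = "numeric",
    cwdSensitivity        = "numeric",
    responseLagMonths     = "integer",
    legacyProfile         = "numeric",
    droughtYearDepression = "numeric",
    ar1Coef               = "numeric",
    noiseSD               = "numeric",
    forcedDroughtYears    = "integer",
    precipMean            = "numeric",
    precipSeasAmp         = "numeric",
    precipLogSD           = "numeric",
    petMean               = "numeric",
    petSeasAmp            = "numeric",
    droughtThreshold      = "numeric",
    seed                  = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nLat < 1L || object@nLon < 1L)
    msg <- c(msg, "grid dimensions must be >= 1")
  if (object@years < 2L)
    msg <- c(msg, "need at least 2 years")
  if (object@responseLagMonths < 0L || object@responseLagMonths > 60L)
    msg <- c(msg, "responseLagMonths must be in 0..60")
  if (length(object@legacyProfile) != 4L)
    msg <- c(msg, "legacyProfile must have length 4")
  fr <- c(object@legacyProfile, object@droughtYearDepression)
  if (any(fr < 0) || any(fr >= 1))
    msg <- c(msg, "fractional depressions must lie in [0, 1)")
  if (object@ar1Coef < 0 || object@ar1Coef >= 1)
    msg <- c(msg, "ar1Coef must lie in [0, 1)")
  if (object@noiseSD < 0)
    msg <- c(msg, "noiseSD must be >= 0")
  if (length(object@forcedDroughtYears) &&
      (min(object@forcedDroughtYears) < 1L ||
       max(object@forcedDroughtYears) > object@years))
    msg <- c(msg, "forcedDroughtYears must be year indices within the record")
  if (length(msg)) msg else TRUE
})

#' Ground-truth record of a synthetic ensemble
#'
#' Serializable record of the exact parameters realized by
#' [synthesizeNPP()]: the injected lag and sensitivity per cell, the legacy
#' profile, and the realized extreme-drought years (forced plus naturally
#' occurring) at each cell.
#'
#' @slot lag,sensitivity numeric matrices (nLat, nLon).
#' @slot legacyProfile numeric length-4 fractional depressions.
#' @slot droughtYearDepression numeric fraction.
#' @slot droughtYears list, one integer vector of year indices per cell
#'   (column-major cell order).
#' @slot forcedDroughtYears integer vector from the configuration.
#'
#' @exportClass TruthRecord
setClass("TruthRecord",
  representation(
    lag                   = "matrix",
    sensitivity           = "matrix",
    legacyProfile         = "numeric",
    droughtYearDepression = "numeric",
    droughtYears          = "list",
    forcedDroughtYears    = "integer"
  )
)
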