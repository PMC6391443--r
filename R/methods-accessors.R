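#' @include AllClasses.R AllGenerics.R constructors.R
NULL

#' @rdname field-accessors
setMethod("fieldValues", "GriddedField", function(x) x@values)

#' @rdname field-accessors
setMethod("latitudes", "GriddedField", function(x) x@lat)

#' @rdname field-accessors
setMethod("longitudes", "GriddedField", function(x) x@lon)

#' @rdname field-accessors
setMethod("fieldUnits", "GriddedField", function(x) x@units)

#' @rdname field-accessors
setMethod("validMask", "GriddedField", function(x) x@mask)

#' @rdname field-accessors
setMethod("startYear", "GriddedField", function(x) x@startYear)

#' @rdname field-accessors
setMethod("cellMatrix", "GriddedField", function(x) .cellMat(x))

#' @rdname field-accessors
setMethod("latitudes", "ForestTypeMap", function(x) x@lat)

#' @rdname field-accessors
setMethod("longitudes", "ForestTypeMap", function(x) x@lon)

setMethod("events", "DroughtCatalog", function(x) x@events)

setMethod("retainedEvents", "DroughtCatalog", function(x) {
  x@events[!x@events$excluded, , drop = FALSE]
})

setMethod("anomalies", "RecoveryTrajectory", function(x) x@anomalies)

setMethod("anomalies", "EnsembleSummary", function(x) x@meanTrajectory)

setMethod("forestClasses", "ForestTypeMap", function(x) x@classes)

setMethod("dominantClass", "ForestTypeMap", function(x) {
  d <- dim(x@fractions)
  apply(x@fractions, c(1L, 2L), function(fr) {
    if (all(is.na(fr))) NA_integer_ else which.max(fr)
  })
})

setMethod("purity", "ForestTypeMap", function(x) {
  apply(x@fractions, c(1L, 2L), function(fr) {
    if (all(is.na(fr))) NA_real_ else max(fr, na.rm = TRUE)
  })
})

## ---- show methods ----------------------------------------------------

setMethod("show", "MonthlyField", function(object) {
  d <- dim(object@values)
  cat(sprintf("MonthlyField '%s' [%s]: %d months (%d-%d), %d x %d grid, %d valid cells\n",
              object@varname, object@units, d[1L], object@startYear,
              object@startYear + d[1L] %/% 12L - 1L, d[2L], d[3L],
              sum(object@mask)))
})

setMethod("show", "AnnualField", function(object) {
  d <- dim(object@values)
  cat(sprintf("AnnualField '%s' [%s, %s of months]: %d years (%d-%d), %d x %d grid, %d valid cells\n",
              object@varname, object@units, object@derivation, d[1L],
              object@startYear, object@startYear + d[1L] - 1L,
              d[2L], d[3L], sum(object@mask)))
})

setMethod("show", "StandardizedAnnualField", function(object) {
  d <- dim(object@values)
  cat(sprintf("StandardizedAnnualField '%s' (Z units): %d years, %d x %d grid, %d valid cells\n",
              object@varname, d[1L], d[2L], d[3L], sum(object@mask)))
})

setMethod("show", "DroughtCatalog", function(object) {
  ev <- object@events
  cat(sprintf("DroughtCatalog: %d events at %d cells (threshold Z <= %g, exclusion window %d yr)\n",
              nrow(ev), length(unique(ev$cell)), object@threshold,
              object@exclusionWindow))
  cat(sprintf("  excluded: %d; truncated post-drought window: %d\n",
              sum(ev$excluded), sum(ev$truncated)))
})

setMethod("show", "LagCorrelationResult", function(object) {
  ok <- object@significant & !is.na(object@rMax)
  cat(sprintf("LagCorrelationResult (model '%s'): lags 0-%d months, FDR alpha %g\n",
              object@model, object@maxLag, object@alpha))
  cat(sprintf("  %d / %d cells significant; median lag %s, median r %s\n",
              sum(ok, na.rm = TRUE), sum(!is.na(object@rMax)),
              if (any(ok)) sprintf("%g", stats::median(object@lagOpt[ok])) else "-",
              if (any(ok)) sprintf("%.3f", stats::median(object@rMax[ok])) else "-"))
})

setMethod("show", "RecoveryTrajectory", function(object) {
  cat(sprintf("RecoveryTrajectory [%s, %s baseline]: %d cells, %d events\n",
              object@units, object@baseline, nrow(object@anomalies),
              sum(object@nEvents)))
  if (nrow(object@anomalies)) {
    m <- colMeans(object@anomalies, na.rm = TRUE)
    cat("  cell-mean anomalies (yr 0..4): ",
        paste(sprintf("%.2f", m), collapse = ", "), "\n", sep = "")
  }
})

setMethod("show", "EnsembleSummary", function(object) {
  cat(sprintf("EnsembleSummary [%s]: %d models, %d bootstrap resamples\n",
              object@units, object@nModels, object@nBoot))
  for (k in 1:5)
    cat(sprintf("  yr %d: %7.2f  [%7.2f, %7.2f]\n", k - 1L,
                object@meanTrajectory[k], object@ciLow[k], object@ciHigh[k]))
})

setMethod("show", "Benchmark", function(object) {
  cat(sprintf("Benchmark (%s): %% depression yr 1..4 = %s\n", object@source,
              paste(sprintf("%g", object@values), collapse = ", ")))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf("SyntheticConfig: %d x %d grid, %d years, %d models, seed %d\n",
              object@nLat, object@nLon, object@years, object@nModels,
              object@seed))
  cat(sprintf("  lag %d months, sensitivity %g, legacy %s, drought-year depression %g\n",
              object@responseLagMonths, object@cwdSensitivity,
              paste(object@legacyProfile, collapse = "/"),
              object@droughtYearDepression))
})

setMethod("show", "ForestTypeMap", function(object) {
  tab <- table(factor(dominantClass(object), levels = seq_along(object@classes),
                      labels = object@classes))
  cat("ForestTypeMap:", paste(sprintf("%s=%d", names(tab), tab),
                              collapse = ", "), "\n")
})
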