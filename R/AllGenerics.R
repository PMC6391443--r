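#' @include AllClasses.R
NULL

#' Accessors for gridded fields and analysis results
#'
#' `fieldValues()` returns the raw array; `latitudes()`/`longitudes()` the
#' cell-center coordinates; `fieldUnits()` the units string; `validMask()`
#' the logical validity mask; `startYear()` the first calendar year;
#' `cellMatrix()` the field reshaped to a (time x nCell) matrix with cells
#' in column-major (lat fastest) order, invalid cells set to NA.
#'
#' @param x a [GriddedField-class] derivative (or, where documented, another
#'   droughtLegacy object).
#' @return See each generic's description.
#' @name field-accessors
#' @aliases fieldValues latitudes longitudes fieldUnits validMask startYear
#'   cellMatrix
#'
#' @examples
#' fld <- monthlyField(array(1, c(24, 2, 2)), lat = c(40, 40.5),
#'                     lon = c(-100, -99.5), startYear = 2000,
#'                     units = "mm", varname = "pr")
#' dim(cellMatrix(fld))   # 24 x 4
#' latitudes(fld)
NULL

#' @rdname field-accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))

#' @rdname field-accessors
#' @export
setGeneric("latitudes", function(x) standardGeneric("latitudes"))

#' @rdname field-accessors
#' @export
setGeneric("longitudes", function(x) standardGeneric("longitudes"))

#' @rdname field-accessors
#' @export
setGeneric("fieldUnits", function(x) standardGeneric("fieldUnits"))

#' @rdname field-accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' @rdname field-accessors
#' @export
setGeneric("startYear", function(x) standardGeneric("startYear"))

#' @rdname field-accessors
#' @export
setGeneric("cellMatrix", function(x) standardGeneric("cellMatrix"))

#' Events table of a drought catalog
#'
#' @param x a [DroughtCatalog-class].
#' @return `events()` returns the full events data.frame;
#'   `retainedEvents()` only the rows usable for recovery analysis
#'   (not excluded).
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname events
#' @export
setGeneric("retainedEvents", function(x) standardGeneric("retainedEvents"))

#' Trajectory anomaly matrix
#'
#' @param x a [RecoveryTrajectory-class] or [EnsembleSummary-class].
#' @return For a trajectory, the (nCell x 5) anomaly matrix; for an
#'   ensemble summary, the length-5 ensemble mean trajectory.
#' @export
setGeneric("anomalies", function(x) standardGeneric("anomalies"))

#' Dominant forest class per cell
#'
#' @param x a [ForestTypeMap-class].
#' @return `dominantClass()`: integer matrix (nLat, nLon) indexing into
#'   `forestClasses(x)`; `purity()`: the dominant class's cover fraction;
#'   `forestClasses()`: the class labels.
#' @export
setGeneric("dominantClass", function(x) standardGeneric("dominantClass"))

#' @rdname dominantClass
#' @export
setGeneric("purity", function(x) standardGeneric("purity"))

#' @rdname dominantClass
#' @export
setGeneric("forestClasses", function(x) standardGeneric("forestClasses"))
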