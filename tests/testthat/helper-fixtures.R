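## Small deterministic fixtures used across test files.

## monthly field from a time x cell matrix laid out on a tiny grid
mkMonthly <- function(m, nLat = 1L, nLon = 1L, lat = NULL, lon = NULL,
                      units = "mm month-1", varname = "x") {
  if (is.null(lat)) lat <- seq(40, by = 0.5, length.out = nLat)
  if (is.null(lon)) lon <- seq(-100, by = 0.5, length.out = nLon)
  monthlyField(array(m, c(NROW(m), length(lat), length(lon))), lat, lon,
               startYear = 1948L, units = units, varname = varname)
}

mkAnnual <- function(m, nLat = 1L, nLon = 1L, lat = NULL, lon = NULL,
                     units = "gC m-2 yr-1", varname = "npp") {
  if (is.null(lat)) lat <- seq(40, by = 0.5, length.out = nLat)
  if (is.null(lon)) lon <- seq(-100, by = 0.5, length.out = nLon)
  annualField(array(m, c(NROW(m), length(lat), length(lon))), lat, lon,
              startYear = 1948L, units = units, varname = varname)
}

## Z field built from a year x cell matrix by inverting the z-scoring:
## feed values that standardize to (approximately) themselves is fiddly,
## so instead construct the StandardizedAnnualField directly.
mkZ <- function(zmat, nLat = 1L, nLon = 1L, lat = NULL, lon = NULL) {
  if (is.null(lat)) lat <- seq(40, by = 0.5, length.out = nLat)
  if (is.null(lon)) lon <- seq(-100, by = 0.5, length.out = nLon)
  nY <- NROW(zmat)
  new("StandardizedAnnualField",
      values = array(zmat, c(nY, length(lat), length(lon))),
      lat = lat, lon = lon, startYear = 1948L, units = "z-score",
      varname = "cwd", mask = matrix(TRUE, length(lat), length(lon)),
      derivation = "sum",
      cellMean = matrix(0, length(lat), length(lon)),
      cellSD = matrix(1, length(lat), length(lon)))
}

## small noise-free synthetic world shared by several tests
noiseFreeConfig <- function(lag = 3L, seed = 101L, nLat = 2L, nLon = 2L) {
  syntheticConfig(nLat = nLat, nLon = nLon, nModels = 1L, seed = seed,
                  noiseSD = 0, ar1Coef = 0, responseLagMonths = lag,
                  legacyProfile = c(0, 0, 0, 0), droughtYearDepression = 0,
                  meanNPP = 120)
}

## naive loop-based oracles -------------------------------------------

oracleLaggedCor <- function(npp, cwd, maxLag) {
  n <- length(npp)
  sapply(0:maxLag, function(k) {
    a <- npp[(k + 1):n]
    b <- cwd[1:(n - k)]
    suppressWarnings(cor(a, b))
  })
}

oracleDeseason <- function(x) {
  out <- x
  for (m in 1:12) {
    idx <- seq(m, length(x), by = 12)
    out[idx] <- x[idx] - mean(x[idx])
  }
  out
}
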