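#' @include AllClasses.R AllGenerics.R constructors.R drought-metrics.R
NULL

#' Configure a synthetic pseudo-model ensemble
#'
#' Builds the configuration of the seeded generator used to exercise the
#' full drought-recovery pipeline with known ground truth. The generated
#' world is deliberately simple: precipitation is a sinusoidal seasonal
#' cycle modulated by a per-cell-per-year lognormal multiplier (interannual
#' variability), PET has its own fixed seasonal cycle, and monthly NPP
#' responds linearly to the standardized monthly CWD anomaly with a known
#' lag, plus AR(1) noise. Extreme-drought years (annual CWD Z at or below
#' `droughtThreshold`) multiply NPP by (1 - droughtYearDepression) in the
#' drought year and by (1 - legacyProfile[k]) in post-drought year k,
#' emulating legacy effects of known size.
#'
#' @param nLat,nLon grid dimensions (default 5 x 5).
#' @param years record length in years (default 61, emulating 1948-2008).
#' @param nModels ensemble size (default 12).
#' @param meanNPP baseline NPP level, gC m-2 month-1 (default 50, i.e.
#'   600 gC m-2 yr-1, a typical temperate forest).
#' @param seasonalAmplitude NPP seasonal amplitude, gC m-2 month-1
#'   (default 20).
#' @param cwdSensitivity NPP response per CWD Z-unit, gC m-2 month-1
#'   (default 10).
#' @param responseLagMonths lag between CWD anomaly and NPP response,
#'   months 0..60 (default 0).
#' @param legacyProfile fractional NPP depression in post-drought years
#'   1..4 (default c(0.09, 0.05, 0.02, 0)).
#' @param droughtYearDepression fractional depression in the drought year
#'   itself (default 0.15).
#' @param ar1Coef lag-1 autocorrelation of the monthly NPP noise
#'   (default 0.3).
#' @param noiseSD marginal SD of the AR(1) noise, gC m-2 month-1
#'   (default 5).
#' @param forcedDroughtYears year indices forced to extreme drought by
#'   scaling precipitation down (default c(15, 35, 50)).
#' @param precipMean,precipSeasAmp mean monthly precipitation (mm) and its
#'   fractional seasonal amplitude.
#' @param precipLogSD SD of the lognormal interannual precipitation
#'   multiplier (default 0.25).
#' @param petMean,petSeasAmp mean monthly PET (mm) and its fractional
#'   seasonal amplitude.
#' @param droughtThreshold Z threshold at which the generated ecosystem
#'   expresses depression/legacy (default -2, matching the detection
#'   threshold).
#' @param seed integer RNG seed.
#' @return A validated [SyntheticConfig-class].
#' @export
#' @examples
#' cfg <- syntheticConfig(nLat = 3, nLon = 3, nModels = 2, seed = 7)
#' cfg
syntheticConfig <- function(nLat = 5L, nLon = 5L, years = 61L,
                            nModels = 12L, meanNPP = 50,
                            seasonalAmplitude = 20, cwdSensitivity = 10,
                            responseLagMonths = 0L,
                            legacyProfile = c(0.09, 0.05, 0.02, 0),
                            droughtYearDepression = 0.15,
                            ar1Coef = 0.3, noiseSD = 5,
                            forcedDroughtYears = c(15L, 35L, 50L),
                            precipMean = 70, precipSeasAmp = 0.4,
                            precipLogSD = 0.25,
                            petMean = 60, petSeasAmp = 0.6,
                            droughtThreshold = -2, seed = 42L) {
  new("SyntheticConfig",
      nLat = as.integer(nLat), nLon = as.integer(nLon),
      years = as.integer(years), nModels = as.integer(nModels),
      meanNPP = meanNPP, seasonalAmplitude = seasonalAmplitude,
      cwdSensitivity = cwdSensitivity,
      responseLagMonths = as.integer(responseLagMonths),
      legacyProfile = as.numeric(legacyProfile),
      droughtYearDepression = droughtYearDepression,
      ar1Coef = ar1Coef, noiseSD = noiseSD,
      forcedDroughtYears = as.integer(forcedDroughtYears),
      precipMean = precipMean, precipSeasAmp = precipSeasAmp,
      precipLogSD = precipLogSD, petMean = petMean,
      petSeasAmp = petSeasAmp, droughtThreshold = droughtThreshold,
      seed = as.integer(seed))
}

## synthetic grid lives inside the US analysis box
.synthGrid <- function(config) {
  list(lat = seq(35, by = 0.5, length.out = config@nLat),
       lon = seq(-110, by = 0.5, length.out = config@nLon))
}

.precipSeasonal <- function(config) {
  m <- 1:12
  config@precipMean * (1 + config@precipSeasAmp * sin(2 * pi * (m - 4) / 12))
}

.petSeasonal <- function(config) {
  m <- 1:12
  config@petMean * (1 + config@petSeasAmp * sin(2 * pi * (m - 6) / 12))
}

#' Generate synthetic climate fields
#'
#' Monthly precipitation, temperature and PET on the configured grid.
#' Precipitation factorizes into a seasonal pattern times a per-cell,
#' per-year lognormal multiplier (mean 1); PET repeats a fixed seasonal
#' cycle; temperature is a seasonal cycle plus independent annual and
#' monthly Gaussian anomalies. Each year listed in `forcedDroughtYears` is
#' realized as an extreme drought at every cell by scaling that year's
#' precipitation down (bisection) until the annual CWD Z-score is at or
#' below -2.05, safely under the -2 detection threshold. Deterministic
#' under the configured seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return list(precip, temp, pet): [MonthlyField-class] objects (mm
#'   month-1; temperature in K).
#' @export
#' @examples
#' cl <- generateClimate(syntheticConfig(nLat = 2, nLon = 2, seed = 1))
#' cl$precip
generateClimate <- function(config) {
  validObject(config)
  grid <- .synthGrid(config)
  nY <- config@years
  nCell <- config@nLat * config@nLon
  n <- nY * 12L

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config@seed)

  sP <- .precipSeasonal(config)
  sPET <- .petSeasonal(config)

  ## per-cell, per-year lognormal multipliers (mean 1)
  sdl <- config@precipLogSD
  Ym <- matrix(exp(stats::rnorm(nY * nCell, sd = sdl) - sdl^2 / 2),
               nrow = nY)

  ## force listed years to extreme drought per cell
  if (length(config@forcedDroughtYears)) {
    SP <- sum(sP); SPET <- sum(sPET)
    zOf <- function(y, f) {
      a <- SP * y - SPET
      (a[f] - mean(a)) / stats::sd(a)
    }
    for (cc in seq_len(nCell)) {
      y0 <- Ym[, cc]
      for (pass in 1:12) {
        done <- TRUE
        for (f in config@forcedDroughtYears) {
          if (zOf(Ym[, cc], f) <= -2.05) next
          done <- FALSE
          yTest <- Ym[, cc]
          yTest[f] <- 0
          if (zOf(yTest, f) > -2.05)
            stop("cannot force extreme drought in year ", f,
                 ": Z > -2.05 even at zero precipitation")
          lo <- 0; hi <- Ym[f, cc]
          for (it in 1:60) {
            mid <- (lo + hi) / 2
            yTest[f] <- mid
            if (zOf(yTest, f) <= -2.2) lo <- mid else hi <- mid
          }
          Ym[f, cc] <- lo
        }
        if (done) break
      }
      for (f in config@forcedDroughtYears)
        if (zOf(Ym[, cc], f) > -2.05)
          stop("drought forcing failed to converge for year ", f)
    }
  }

  ## precip(t, c) = seasonal(month) * yearMultiplier(year, c)
  precip <- array(NA_real_, c(n, config@nLat, config@nLon))
  seasRep <- rep(sP, nY)
  yearIdx <- rep(seq_len(nY), each = 12L)
  pm <- seasRep * Ym[yearIdx, , drop = FALSE]       # n x nCell
  precip[] <- pm

  pet <- array(rep(rep(sPET, nY), times = nCell),
               c(n, config@nLat, config@nLon))

  tasSeason <- 283 + 10 * sin(2 * pi * ((1:12) - 6) / 12)
  tasAnnual <- matrix(stats::rnorm(nY * nCell, sd = 0.8), nrow = nY)
  tas <- rep(tasSeason, nY) + tasAnnual[yearIdx, , drop = FALSE] +
    matrix(stats::rnorm(n * nCell, sd = 0.5), nrow = n)
  tasArr <- array(tas, c(n, config@nLat, config@nLon))

  list(
    precip = monthlyField(precip, grid$lat, grid$lon, startYear = 1948L,
                          units = "mm month-1", varname = "pr"),
    temp = monthlyField(tasArr, grid$lat, grid$lon, startYear = 1948L,
                        units = "K", varname = "tas"),
    pet = monthlyField(pet, grid$lat, grid$lon, startYear = 1948L,
                       units = "mm month-1", varname = "pet")
  )
}

#' Synthesize a pseudo-model NPP ensemble
#'
#' For each pseudo-model, monthly NPP is built as
#' seasonal cycle + cwdSensitivity x Z(t - lag) + AR(1) noise, where Z is
#' the per-cell standardized monthly CWD anomaly of the supplied climate
#' and the lag is applied as a circular shift (the lagged driver wraps
#' around the record, so it is defined for every month and carries no
#' seasonal imprint). The result is then multiplied by
#' (1 - droughtYearDepression) in every extreme-drought year (annual CWD
#' Z <= droughtThreshold, forced or naturally occurring) and by
#' (1 - legacyProfile[k]) in the k-th post-drought year, and floored at
#' zero. Models differ only in their noise realization (per-model
#' sub-seed).
#'
#' @param climate list(precip, temp, pet) from [generateClimate()].
#' @param config the same [SyntheticConfig-class].
#' @return list(npp: list of [MonthlyField-class] (one per model),
#'   truth: [TruthRecord-class]).
#' @export
synthesizeNPP <- function(climate, config) {
  validObject(config)
  cwd <- computeCWD(climate$precip, climate$pet)
  n <- dim(cwd@values)[1L]
  nCell <- config@nLat * config@nLon
  nY <- config@years
  L <- config@responseLagMonths

  anom <- .cellMat(deseasonalize(cwd))              # n x nCell
  sdv <- apply(anom, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf            # degenerate: no signal
  Z <- sweep(anom, 2L, sdv, "/")

  ## circular lag shift: row t takes row ((t - L - 1) mod n) + 1
  idx <- ((seq_len(n) - 1L - L) %% n) + 1L
  Zlag <- Z[idx, , drop = FALSE]

  ## realized extreme-drought years per cell and legacy multipliers
  zAnnual <- .cellMat(zscoreAnnual(annualTotal(cwd), quiet = TRUE))
  mult <- matrix(1, nY, nCell)
  droughtYears <- vector("list", nCell)
  for (cc in seq_len(nCell)) {
    zi <- zAnnual[, cc]
    dy <- which(!is.na(zi) & zi <= config@droughtThreshold)
    droughtYears[[cc]] <- as.integer(dy)
    for (d in dy) {
      mult[d, cc] <- mult[d, cc] * (1 - config@droughtYearDepression)
      for (k in 1:4) {
        if (d + k <= nY)
          mult[d + k, cc] <- mult[d + k, cc] * (1 - config@legacyProfile[k])
      }
    }
  }
  multMonthly <- mult[rep(seq_len(nY), each = 12L), , drop = FALSE]

  seasonal <- config@meanNPP +
    config@seasonalAmplitude * sin(2 * pi * ((1:12) - 5) / 12)
  det <- rep(seasonal, nY) + config@cwdSensitivity * Zlag

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  models <- vector("list", config@nModels)
  phi <- config@ar1Coef
  innovSD <- config@noiseSD * sqrt(1 - phi^2)
  for (mdl in seq_len(config@nModels)) {
    set.seed(config@seed + 1000L + mdl)
    if (config@noiseSD > 0) {
      eps <- matrix(stats::rnorm(n * nCell, sd = innovSD), nrow = n)
      noise <- if (phi > 0)
        apply(eps, 2L, function(e)
          as.numeric(stats::filter(e, phi, method = "recursive")))
      else eps
    } else noise <- 0
    npp <- pmax((det + noise) * multMonthly, 0)
    models[[mdl]] <- monthlyField(
      array(npp, c(n, config@nLat, config@nLon)),
      climate$precip@lat, climate$precip@lon, startYear = 1948L,
      units = "gC m-2 month-1",
      varname = sprintf("npp_model%02d", mdl))
  }

  truth <- new("TruthRecord",
               lag = matrix(as.numeric(L), config@nLat, config@nLon),
               sensitivity = matrix(config@cwdSensitivity, config@nLat,
                                    config@nLon),
               legacyProfile = config@legacyProfile,
               droughtYearDepression = config@droughtYearDepression,
               droughtYears = droughtYears,
               forcedDroughtYears = config@forcedDroughtYears)
  list(npp = models, truth = truth)
}

#' Synthetic forest-type map
#'
#' Assigns cells round-robin to the three analysis forest classes
#' (needle-leaf evergreen, broadleaf deciduous, mixed) in column-major cell
#' order, giving the dominant class the configured purity and splitting the
#' remainder between the other two.
#'
#' @param config a [SyntheticConfig-class] (only the grid is used), or NULL
#'   if `lat`/`lon` are supplied.
#' @param purityLevel dominant-class cover fraction (default 0.8).
#' @param lat,lon alternative explicit grid.
#' @return A [ForestTypeMap-class].
#' @export
syntheticForestMap <- function(config = NULL, purityLevel = 0.8,
                               lat = NULL, lon = NULL) {
  if (!is.null(config)) {
    grid <- .synthGrid(config)
    lat <- grid$lat; lon <- grid$lon
  }
  classes <- c("needle_evergreen", "broadleaf_deciduous", "mixed")
  nLat <- length(lat); nLon <- length(lon)
  nCell <- nLat * nLon
  fr <- array((1 - purityLevel) / 2, c(nLat, nLon, 3L))
  domIdx <- ((seq_len(nCell) - 1L) %% 3L) + 1L
  for (k in 1:3) {
    sel <- matrix(domIdx == k, nLat, nLon)
    slice <- fr[, , k]
    slice[sel] <- purityLevel
    fr[, , k] <- slice
  }
  forestTypeMap(fr, classes, lat, lon)
}
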