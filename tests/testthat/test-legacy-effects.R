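test_that("climate-normal baseline averages only normal years", {
  z <- mkZ(matrix(c(-2.5, 0, 0.5, -1, 1, 2, 0, 0, -0.3, 0.9), 10, 1))
  nppConst <- mkAnnual(matrix(500, 10, 1))
  b <- climateNormalBaseline(nppConst, z)
  expect_equal(b@meanNPP[1, 1], 500)

  ## drought years at 400, normal years at 500 -> baseline 500
  nppv <- ifelse(as.vector(fieldValues(z)) <= -2, 400, 500)
  b2 <- climateNormalBaseline(mkAnnual(matrix(nppv, 10, 1)), z)
  expect_equal(b2@meanNPP[1, 1], 500)
  expect_equal(b2@nNormalYears[1, 1], sum(abs(fieldValues(z)) <= 1))

  ## random case equals the loop oracle; short records are masked
  set.seed(31)
  zr <- matrix(rnorm(20 * 4), 20, 4)
  nr <- matrix(rnorm(20 * 4, 600, 50), 20, 4)
  zf <- mkZ(zr, nLat = 2, nLon = 2)
  b3 <- climateNormalBaseline(mkAnnual(nr, nLat = 2, nLon = 2), zf)
  for (cc in 1:4) {
    keep <- zr[, cc] >= -1 & zr[, cc] <= 1
    want <- if (sum(keep) >= 5) mean(nr[keep, cc]) else NA_real_
    expect_equal(as.vector(b3@meanNPP)[cc], want)
  }
})

test_that("absolute trajectories subtract the baseline and average events per cell", {
  ## flat NPP at the baseline except a dip in the drought year
  zz <- rep(0, 15); zz[6] <- -2.4
  z <- mkZ(matrix(zz, 15, 1))
  npp <- rep(500, 15); npp[6] <- 420
  ct <- identifyDroughtEvents(z)
  b <- climateNormalBaseline(mkAnnual(matrix(npp, 15, 1)), z)
  tr <- absoluteTrajectory(mkAnnual(matrix(npp, 15, 1)), b, ct)
  expect_equal(as.vector(anomalies(tr)), c(-80, 0, 0, 0, 0),
               tolerance = 1e-9)

  ## two events at one cell average their trajectories
  zz2 <- rep(0, 20); zz2[4] <- -2.2; zz2[14] <- -2.9
  z2 <- mkZ(matrix(zz2, 20, 1))
  npp2 <- rep(500, 20)
  npp2[4:8] <- c(440, 480, 500, 500, 500)    # anomalies -60, -20, 0 ...
  npp2[14:18] <- c(420, 460, 500, 500, 500)  # anomalies -80, -40, 0 ...
  ct2 <- identifyDroughtEvents(z2)
  b2 <- climateNormalBaseline(mkAnnual(matrix(npp2, 20, 1)), z2)
  base <- b2@meanNPP[1, 1]
  tr2 <- absoluteTrajectory(mkAnnual(matrix(npp2, 20, 1)), b2, ct2)
  want <- (c(440, 480, 500, 500, 500) + c(420, 460, 500, 500, 500)) / 2 - base
  expect_equal(as.vector(anomalies(tr2)), want, tolerance = 1e-9)
  expect_equal(tr2@nEvents, 2L)
})

test_that("a 15% drought-year depression on a ~500 baseline yields ~-75 gC m-2", {
  cfg <- syntheticConfig(nLat = 5, nLon = 5, nModels = 1, seed = 32,
                         meanNPP = 500 / 12, seasonalAmplitude = 10,
                         cwdSensitivity = 0, noiseSD = 2,
                         legacyProfile = c(0, 0, 0, 0),
                         droughtYearDepression = 0.15)
  cl <- generateClimate(cfg)
  g <- synthesizeNPP(cl, cfg)
  z <- zscoreAnnual(annualTotal(computeCWD(cl$precip, cl$pet)),
                    quiet = TRUE)
  ct <- identifyDroughtEvents(z)
  aN <- annualTotal(g$npp[[1]])
  b <- climateNormalBaseline(aN, z)
  tr <- absoluteTrajectory(aN, b, ct)
  y0 <- mean(anomalies(tr)[, 1])
  expect_lt(abs(y0 - (-75)), 7)   # 0.15 x 500, noise band
})

test_that("excluded events never contribute to a trajectory", {
  zz <- rep(0, 20); zz[5] <- -2.5; zz[7] <- -2.5
  z <- mkZ(matrix(zz, 20, 1))
  npp <- rep(500, 20); npp[5] <- 100   # huge dip only in the excluded event
  ct <- identifyDroughtEvents(z)
  expect_true(events(ct)$excluded[events(ct)$end_year == 5])
  b <- climateNormalBaseline(mkAnnual(matrix(npp, 20, 1)), z)
  tr <- absoluteTrajectory(mkAnnual(matrix(npp, 20, 1)), b, ct)
  ## only the year-7 event remains; its trajectory never sees year 5
  expect_equal(tr@nEvents, 1L)
  expect_true(all(abs(anomalies(tr)) < 1e-9))
})

test_that("cell areas and regional integrals reproduce the closed-form arithmetic", {
  ## equatorial 0.5-degree cell against the spherical-cap formula
  R <- 6371000
  a0 <- R^2 * (0.5 * pi / 180) * (sin(0.25 * pi / 180) - sin(-0.25 * pi / 180))
  expect_equal(cellArea(0), a0, tolerance = 1e-12)
  expect_equal(signif(cellArea(0), 3), 3.09e9)

  ## uniform -75.7 gC m-2 over 7.266e12 m2 integrates to -0.55 PgC
  expect_equal(-75.7 * 7.266e12 / 1e15, -0.55, tolerance = 1e-3)
  lat <- seq(30, 49.5, by = 0.5); lon <- seq(-100, -80.5, by = 0.5)
  anom <- matrix(-75.7, length(lat), length(lon))
  ri <- regionalIntegral(anom, lat, lon)
  expect_equal(ri$pgc, -75.7 * ri$area / 1e15, tolerance = 1e-12)

  ## zero anomaly integrates to zero
  expect_equal(regionalIntegral(anom * 0, lat, lon)$pgc, 0)

  ## cross-check the cell area against an independent spherical polygon area
  skip_if_not_installed("geosphere")
  poly <- cbind(c(-0.25, 0.25, 0.25, -0.25), c(44.75, 44.75, 45.25, 45.25))
  expect_equal(cellArea(45),
               geosphere::areaPolygon(poly, a = 6371000, f = 0),
               tolerance = 1e-4)
})

test_that("per-cell NPP~CWD regression recovers exact lines and rejects nulls", {
  set.seed(33)
  cwd <- matrix(rnorm(61 * 4, 0, 50), 61, 4)
  npp <- 2 * cwd + 100
  reg <- fitCwdNppRegression(mkAnnual(npp, nLat = 2, nLon = 2),
                             mkAnnual(cwd, nLat = 2, nLon = 2))
  expect_equal(as.vector(reg@slope), rep(2, 4), tolerance = 1e-10)
  expect_equal(as.vector(reg@intercept), rep(100, 4), tolerance = 1e-8)
  expect_equal(as.vector(reg@r), rep(1, 4), tolerance = 1e-12)
  expect_true(all(reg@selected))

  ## independent NPP and CWD are essentially never selected
  hits <- 0L
  for (rep in 1:20) {
    nppI <- matrix(rnorm(61 * 4, 500, 30), 61, 4)
    regI <- fitCwdNppRegression(mkAnnual(nppI, nLat = 2, nLon = 2),
                                mkAnnual(cwd, nLat = 2, nLon = 2))
    hits <- hits + sum(regI@selected)
  }
  expect_lte(hits, 4L)

  ## r = 0.3 exactly is NOT selected (strict inequality)
  x <- as.vector(scale(rnorm(61)))
  e <- as.vector(scale(residuals(lm(rnorm(61) ~ x))))
  y <- 0.3 * x + sqrt(1 - 0.09) * e     # cor(y, x) = 0.3 exactly
  expect_equal(cor(y, x), 0.3, tolerance = 1e-12)
  regE <- fitCwdNppRegression(mkAnnual(matrix(y, 61, 1)),
                              mkAnnual(matrix(x, 61, 1)))
  expect_false(regE@selected[1, 1])

  ## zero CWD variance masks the cell
  regZ <- fitCwdNppRegression(mkAnnual(matrix(rnorm(61), 61, 1)),
                              mkAnnual(matrix(1, 61, 1)))
  expect_true(is.na(regZ@slope[1, 1]))
})

test_that("percent trajectories measure departure from the CWD-predicted NPP", {
  set.seed(34)
  cwdv <- pmax(pmin(rnorm(61, 0, 40), 60), -60)   # one controlled extreme
  cwdv[20] <- -150
  ## NPP exactly on the regression line -> 0% everywhere
  nppOn <- 1.5 * cwdv + 800
  z <- mkZ(matrix(scale(cwdv), 61, 1))
  ct <- identifyDroughtEvents(z)
  reg <- fitCwdNppRegression(mkAnnual(matrix(nppOn, 61, 1)),
                             mkAnnual(matrix(cwdv, 61, 1)))
  tr <- percentTrajectory(mkAnnual(matrix(nppOn, 61, 1)), reg,
                          mkAnnual(matrix(cwdv, 61, 1)), ct)
  expect_equal(as.vector(anomalies(tr)), rep(0, 5), tolerance = 1e-9)

  ## NPP 95 against predicted 100 -> -5%
  pred <- 1.5 * cwdv + 800
  npp95 <- pred
  npp95[21] <- pred[21] * 0.95
  tr2 <- percentTrajectory(mkAnnual(matrix(npp95, 61, 1)), reg,
                           mkAnnual(matrix(cwdv, 61, 1)), ct)
  ## year 21 is post-drought year 1 of the event ending year 20
  expect_equal(anomalies(tr2)[1, 2], -5, tolerance = 1e-6)

  ## non-positive predicted NPP is masked with a warning
  regBad <- reg
  regBad@intercept[1, 1] <- -1e6
  expect_warning(
    tr3 <- percentTrajectory(mkAnnual(matrix(nppOn, 61, 1)), regBad,
                             mkAnnual(matrix(cwdv, 61, 1)), ct),
    "non-positive")
  expect_equal(nrow(anomalies(tr3)), 0L)
})

test_that("unselected cells are left out of percent trajectories", {
  cfg <- syntheticConfig(nLat = 3, nLon = 3, nModels = 1, seed = 35)
  cl <- generateClimate(cfg)
  g <- synthesizeNPP(cl, cfg)
  cwd <- computeCWD(cl$precip, cl$pet)
  aC <- annualTotal(cwd)
  z <- zscoreAnnual(aC, quiet = TRUE)
  ct <- identifyDroughtEvents(z)
  aN <- annualTotal(g$npp[[1]])
  reg <- fitCwdNppRegression(aN, aC)
  reg@selected[1, 1] <- FALSE
  tr <- percentTrajectory(aN, reg, aC, ct)
  expect_false(1L %in% tr@cells)
})

test_that("forest stratification filters by dominant class and purity", {
  cfg <- syntheticConfig(nLat = 3, nLon = 3, nModels = 1, seed = 36)
  cl <- generateClimate(cfg)
  g <- synthesizeNPP(cl, cfg)
  aC <- annualTotal(computeCWD(cl$precip, cl$pet))
  z <- zscoreAnnual(aC, quiet = TRUE)
  ct <- identifyDroughtEvents(z)
  aN <- annualTotal(g$npp[[1]])
  b <- climateNormalBaseline(aN, z)
  tr <- absoluteTrajectory(aN, b, ct)

  fm <- syntheticForestMap(cfg, purityLevel = 0.8)
  ## all cells one class -> identity
  fmAll <- forestTypeMap(array(rep(c(1, 0, 0), each = 9), c(3, 3, 3)),
                         lat = latitudes(fm), lon = longitudes(fm))
  trAll <- stratifyByForest(tr, fmAll, "needle_evergreen")
  expect_equal(anomalies(trAll), anomalies(tr))

  ## impossible purity -> explicit empty result, not an error
  trNone <- stratifyByForest(tr, fm, "mixed", minPurity = 1.01)
  expect_equal(nrow(anomalies(trNone)), 0L)

  ## mixed map equals the manual loop filter
  dom <- as.vector(dominantClass(fm))
  for (cls in 1:3) {
    trC <- stratifyByForest(tr, fm, forestClasses(fm)[cls])
    keep <- tr@cells %in% which(dom == cls)
    expect_equal(anomalies(trC), anomalies(tr)[keep, , drop = FALSE])
  }
})

test_that("absolute and percent trajectories agree in sign where slopes are positive", {
  cfg <- syntheticConfig(nLat = 5, nLon = 5, nModels = 1, seed = 37,
                         noiseSD = 2)
  cl <- generateClimate(cfg)
  g <- synthesizeNPP(cl, cfg)
  cwd <- computeCWD(cl$precip, cl$pet)
  aC <- annualTotal(cwd)
  z <- zscoreAnnual(aC, quiet = TRUE)
  ct <- identifyDroughtEvents(z)
  aN <- annualTotal(g$npp[[1]])
  b <- climateNormalBaseline(aN, z)
  reg <- fitCwdNppRegression(aN, aC)
  trA <- absoluteTrajectory(aN, b, ct)
  trP <- percentTrajectory(aN, reg, aC, ct)
  shared <- intersect(trA@cells, trP@cells)
  ## drought-year anomalies are strongly negative under both baselines
  a0 <- anomalies(trA)[match(shared, trA@cells), 1]
  p0 <- anomalies(trP)[match(shared, trP@cells), 1]
  expect_true(all(sign(a0) == sign(p0)))
})
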