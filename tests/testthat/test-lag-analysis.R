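test_that("lagged correlations recover identity and constructed shifts", {
  set.seed(10)
  x <- rnorm(200)
  r0 <- laggedCorrelations(x, x, maxLag = 10)
  expect_equal(r0$r[1], 1)

  shifted <- c(rep(0, 3), x[1:197])
  r3 <- laggedCorrelations(shifted, x, maxLag = 10)
  expect_equal(r3$r[4], 1, tolerance = 1e-12)
  expect_true(all(r3$r[-4] < 1))

  expect_error(laggedCorrelations(x[1:50], x[1:50], maxLag = 60), "short")
})

test_that("lagged correlations match a naive double-loop oracle to 1e-12", {
  set.seed(11)
  a <- rnorm(100); b <- rnorm(100)
  got <- laggedCorrelations(a, b, maxLag = 60)
  expect_equal(got$r, oracleLaggedCor(a, b, 60), tolerance = 1e-12)

  ## map version agrees with the vector version on deseasonalized input
  npp <- mkMonthly(matrix(rnorm(120 * 4), 120, 4), nLat = 2, nLon = 2)
  cwd <- mkMonthly(matrix(rnorm(120 * 4), 120, 4), nLat = 2, nLon = 2)
  res <- lagCorrelationMap(npp, cwd, maxLag = 20)
  nppA <- cellMatrix(deseasonalize(npp)); cwdA <- cellMatrix(deseasonalize(cwd))
  for (cc in 1:4) {
    o <- optimalLag(oracleLaggedCor(nppA[, cc], cwdA[, cc], 20))
    expect_equal(as.vector(res@rMax)[cc], o$rMax, tolerance = 1e-12)
    expect_equal(as.vector(res@lagOpt)[cc], o$lagOpt)
  }
})

test_that("optimal lag takes the signed maximum, ties to the smallest lag", {
  expect_equal(optimalLag(c(0.2, 0.9, 0.1)), list(rMax = 0.9, lagOpt = 1L))
  expect_equal(optimalLag(rep(0.5, 61))$lagOpt, 0L)
  r <- runif(61, -0.5, 0.5); r[61] <- 0.99
  expect_equal(optimalLag(r)$lagOpt, 60L)
  ## signed, not absolute: a large negative correlation never wins
  expect_equal(optimalLag(c(0.3, -0.95, 0.1))$lagOpt, 0L)
})

test_that("BH adjustment matches the hand computation and preserves edge cases", {
  ## step-up by hand with m = 4: all adjusted to 0.04
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdrAdjust(0.123), 0.123)
  p <- c(0.001, NA, 0.5)
  a <- fdrAdjust(p)
  expect_true(is.na(a[2]))
  expect_true(all(a >= p, na.rm = TRUE))
})

test_that("BH keeps the all-null false discovery rate at the nominal level", {
  set.seed(12)
  reps <- 50
  fdp <- replicate(reps, {
    p <- runif(2000)
    mean(fdrAdjust(p) < 0.05) > 0
  })
  ## P(any discovery) <= alpha under independence
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(mean(fdp), 0.05 + 3 * se)
})

test_that("ensemble lag map averages only significant models", {
  mk <- function(r, lag, sig) {
    new("LagCorrelationResult",
        rMax = matrix(r, 1, 2), lagOpt = matrix(lag, 1, 2),
        pValue = matrix(0.01, 1, 2), pAdj = matrix(0.01, 1, 2),
        significant = matrix(sig, 1, 2), maxLag = 60L, alpha = 0.05,
        model = "m")
  }
  ## three models, all significant, lags all 2 -> mean lag 2
  em <- ensembleLagMap(list(mk(0.5, 2, TRUE), mk(0.6, 2, TRUE),
                            mk(0.7, 2, TRUE)))
  expect_equal(as.vector(em$lagOpt), c(2, 2))
  expect_equal(as.vector(em$rMax), c(0.6, 0.6))

  ## one significant of three -> that model's value, nContrib 1
  em2 <- ensembleLagMap(list(mk(0.5, 4, c(TRUE, FALSE)),
                             mk(0.9, 8, FALSE), mk(0.9, 8, FALSE)))
  expect_equal(em2$rMax[1, 1], 0.5)
  expect_equal(em2$nContrib[1, 1], 1L)
  expect_true(is.na(em2$rMax[1, 2]))

  ## mixed significance equals a manual masked average
  r1 <- mk(c(0.4, 0.8), c(2, 10), c(TRUE, TRUE))
  r2 <- mk(c(0.6, 0.2), c(6, 20), c(TRUE, FALSE))
  em3 <- ensembleLagMap(list(r1, r2))
  expect_equal(as.vector(em3$rMax), c(mean(c(0.4, 0.6)), 0.8))
  expect_equal(as.vector(em3$lagOpt), c(4, 10))

  ## a single model's ensemble equals that model's masked map
  em4 <- ensembleLagMap(list(r2))
  expect_equal(em4$rMax[1, 1], 0.6)
  expect_true(is.na(em4$rMax[1, 2]))
})

test_that("lag bins partition 0-60 months at the documented edges", {
  expect_equal(as.character(binLags(c(0, 1, 2, 3, 5, 6, 7, 12, 13, 24, 25, 60))),
               c("0", "1", "2", "3-6", "3-6", "3-6", "7-12", "7-12",
                 "13-24", "13-24", ">24", ">24"))
  ## every integer lag 0..60 lands in exactly one bin
  expect_false(anyNA(binLags(0:60)))
})

test_that("the dominant driver is the variable with the larger optimized |r|", {
  set.seed(13)
  n <- 240
  tA <- rnorm(n); pA <- rnorm(n)
  ## NPP cell 1 is a lagged copy of T; cell 2 leans on P
  npp1 <- c(rep(0, 2), tA[1:(n - 2)])
  npp2 <- 0.8 * pA + 0.3 * rnorm(n)
  npp <- mkMonthly(cbind(npp1, npp2), nLat = 1, nLon = 2)
  prF <- mkMonthly(cbind(pA, pA), nLat = 1, nLon = 2)
  taF <- mkMonthly(cbind(tA, tA), nLat = 1, nLon = 2, units = "K")
  dd <- dominantDriver(npp, prF, taF, maxLag = 6)
  expect_equal(dd$driver[1, 1], "T")
  ## separate deseasonalization of finite series leaves r just under 1
  expect_gt(dd$r[1, 1], 0.97)
  expect_equal(dd$driver[1, 2], "P")
})

test_that("injected lags are recovered exactly without noise and reliably at SNR 2", {
  ## noise-free: r_max = 1 and exact lag at every cell (subset of criterion 1)
  cfg <- noiseFreeConfig(lag = 12L, seed = 102L)
  cl <- generateClimate(cfg)
  g <- synthesizeNPP(cl, cfg)
  cwd <- computeCWD(cl$precip, cl$pet)
  res <- lagCorrelationMap(g$npp[[1]], cwd, maxLag = 24)
  expect_true(all(res@lagOpt == 12))
  expect_equal(as.vector(res@rMax), rep(1, 4), tolerance = 1e-9)

  ## SNR 2:1 (sensitivity 10, marginal noise SD 5): >= 95% of cells
  cfgN <- syntheticConfig(nLat = 8, nLon = 8, nModels = 1, seed = 103,
                          responseLagMonths = 6L,
                          legacyProfile = c(0, 0, 0, 0),
                          droughtYearDepression = 0)
  clN <- generateClimate(cfgN)
  gN <- synthesizeNPP(clN, cfgN)
  resN <- lagCorrelationMap(gN$npp[[1]], computeCWD(clN$precip, clN$pet),
                            maxLag = 24)
  expect_gte(mean(resN@lagOpt == 6), 0.95)
})
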