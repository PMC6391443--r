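test_that("CWD is precipitation minus PET with mask intersection", {
  p <- mkMonthly(matrix(100, 12, 4), nLat = 2, nLon = 2)
  e <- mkMonthly(matrix(80, 12, 4), nLat = 2, nLon = 2)
  cwd <- computeCWD(p, e)
  expect_equal(unique(as.vector(fieldValues(cwd))), 20)

  expect_equal(as.vector(fieldValues(computeCWD(p, p))),
               rep(0, 12 * 4))

  ## masked PET cell propagates
  ev <- fieldValues(e)
  ev[1, 2, 1] <- NA
  e2 <- mkMonthly(matrix(0, 12, 4), nLat = 2, nLon = 2)
  e2@values <- ev
  e2@mask <- apply(is.finite(ev), c(2, 3), all)
  cwd2 <- computeCWD(p, e2)
  expect_false(validMask(cwd2)[2, 1])
  expect_true(validMask(cwd2)[1, 1])

  ## unit mismatch is an error
  e3 <- mkMonthly(matrix(1, 12, 4), nLat = 2, nLon = 2, units = "mm day-1")
  expect_error(computeCWD(p, e3), "units")
})

test_that("CWD is linear in its inputs", {
  set.seed(1)
  p <- mkMonthly(matrix(rlnorm(24, 4), 24, 1))
  e <- mkMonthly(matrix(rlnorm(24, 4), 24, 1))
  a <- 3.7
  p2 <- mkMonthly(a * matrix(fieldValues(p), 24, 1))
  e2 <- mkMonthly(a * matrix(fieldValues(e), 24, 1))
  expect_equal(fieldValues(computeCWD(p2, e2)),
               a * fieldValues(computeCWD(p, e)))
})

test_that("annual totals sum calendar years and mask incomplete cell-years", {
  m <- mkMonthly(matrix(10, 24, 1))
  at <- annualTotal(m)
  expect_equal(as.vector(fieldValues(at)), c(120, 120))

  set.seed(2)
  x <- rnorm(36)
  at2 <- annualTotal(mkMonthly(matrix(x, 36, 1)))
  expect_equal(as.vector(fieldValues(at2)),
               c(sum(x[1:12]), sum(x[13:24]), sum(x[25:36])))

  xm <- x; xm[14] <- NA
  fld <- mkMonthly(matrix(x, 36, 1))
  fld@values[14, 1, 1] <- NA
  at3 <- annualTotal(fld)
  expect_true(is.na(fieldValues(at3)[2, 1, 1]))
  expect_false(is.na(fieldValues(at3)[1, 1, 1]))
})

test_that("z-scoring standardizes per cell and masks zero variance", {
  af <- mkAnnual(matrix(c(1, 2, 3), 3, 1))
  z <- zscoreAnnual(af)
  expect_equal(as.vector(fieldValues(z)), c(-1, 0, 1))

  ## constant series masked, degenerate count reported, no NaN crash
  cst <- mkAnnual(matrix(5, 10, 1))
  expect_message(zc <- zscoreAnnual(cst), "zero-variance")
  expect_false(any(validMask(zc)))
  expect_equal(attr(zc, "nDegenerate"), 1L)

  ## mean 0, sd 1 by construction; affine invariance
  set.seed(3)
  x <- rnorm(61, 100, 15)
  z1 <- fieldValues(zscoreAnnual(mkAnnual(matrix(x, 61, 1))))
  expect_equal(mean(z1), 0, tolerance = 1e-10)
  expect_equal(sd(as.vector(z1)), 1, tolerance = 1e-10)
  z2 <- fieldValues(zscoreAnnual(mkAnnual(matrix(3.2 * x + 40, 61, 1))))
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("deseasonalization removes monthly means and matches the loop oracle", {
  ## pure 12-month sinusoid vanishes
  s <- sin(2 * pi * (1:120) / 12)
  d <- fieldValues(deseasonalize(mkMonthly(matrix(s, 120, 1))))
  expect_equal(as.vector(d), rep(0, 120), tolerance = 1e-12)

  ## sinusoid + trend: zero monthly means, trend shape retained
  x <- s + seq_along(s) * 0.1
  d2 <- as.vector(fieldValues(deseasonalize(mkMonthly(matrix(x, 120, 1)))))
  for (m in 1:12)
    expect_equal(mean(d2[seq(m, 120, by = 12)]), 0, tolerance = 1e-10)
  expect_gt(cor(d2, seq_along(s)), 0.99)

  set.seed(4)
  r <- rnorm(240)
  d3 <- as.vector(fieldValues(deseasonalize(mkMonthly(matrix(r, 240, 1)))))
  expect_equal(d3, oracleDeseason(r), tolerance = 1e-12)
})

test_that("drought events merge runs, anchor on the last year, and apply the exclusion window", {
  z <- mkZ(matrix(c(-2.5, -2.1, 0, 0.5, 1, 0, 0, 0, 0, 0), 10, 1))
  ct <- identifyDroughtEvents(z)
  ev <- events(ct)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$start_year, 1L)
  expect_equal(ev$end_year, 2L)
  expect_false(ev$excluded)

  ## droughts at years 10 and 12: first excluded, second stands alone
  zz <- rep(0, 20); zz[10] <- -2.3; zz[12] <- -2.6
  ev2 <- events(identifyDroughtEvents(mkZ(matrix(zz, 20, 1))))
  expect_equal(nrow(ev2), 2L)
  expect_true(ev2$excluded[ev2$end_year == 10])
  expect_false(ev2$excluded[ev2$end_year == 12])

  ## event near the record end is retained but truncated
  zt <- rep(0, 10); zt[9] <- -2.5
  ev3 <- events(identifyDroughtEvents(mkZ(matrix(zt, 10, 1))))
  expect_false(ev3$excluded)
  expect_true(ev3$truncated)
  expect_equal(ev3$n_post_available, 1L)
})

test_that("event detection is idempotent and matches the Gaussian tail rate", {
  set.seed(5)
  zmat <- matrix(rnorm(50 * 200), 50, 200)
  z <- mkZ(zmat, nLat = 10, nLon = 20)
  ct1 <- identifyDroughtEvents(z)
  ct2 <- identifyDroughtEvents(z)
  expect_identical(events(ct1), events(ct2))

  nExtremeYears <- sum(events(ct1)$end_year - events(ct1)$start_year + 1)
  n <- length(zmat)
  phat <- nExtremeYears / n
  p0 <- pnorm(-2)
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(phat - p0), 3 * se)
})

test_that("normal-year mask is the closed interval [-1, 1] with the Gaussian fraction", {
  z <- mkZ(matrix(c(0, -1, 1, -1.0001, 1.0001, 2), 6, 1))
  nm <- as.vector(normalYearMask(z))
  expect_equal(nm, c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))

  set.seed(6)
  z2 <- mkZ(matrix(rnorm(20000), 100, 200), nLat = 10, nLon = 20)
  frac <- mean(normalYearMask(z2))
  p0 <- pnorm(1) - pnorm(-1)
  expect_lt(abs(frac - p0), 3 * sqrt(p0 * (1 - p0) / 20000))
})

test_that("nearest-neighbour regridding replicates values and matches brute force", {
  ## uniform field stays uniform
  src <- mkMonthly(matrix(7, 12, 4), lat = c(40, 41), lon = c(10, 11))
  tg <- regridNearest(src, targetLat = seq(39.75, 41.25, by = 0.5),
                      targetLon = seq(9.75, 11.25, by = 0.5))
  expect_equal(unique(as.vector(fieldValues(tg))), 7)

  ## 2x2 source onto aligned 4x4 target: each value appears 4 times
  vals <- array(rep(1:4, each = 12), c(12, 2, 2))
  src2 <- monthlyField(vals, lat = c(40, 41), lon = c(10, 11),
                       units = "mm month-1", varname = "pr")
  tg2 <- regridNearest(src2, targetLat = c(39.8, 40.2, 40.8, 41.2),
                       targetLon = c(9.8, 10.2, 10.8, 11.2))
  expect_equal(as.vector(table(fieldValues(tg2)[1, , ])), rep(4L, 4))

  ## irregular hand case vs exhaustive great-circle search
  set.seed(7)
  srcLat <- seq(35, 44, by = 1); srcLon <- seq(-10, -1, by = 1)
  v <- array(rnorm(12 * 10 * 10), c(12, 10, 10))
  src3 <- monthlyField(v, srcLat, srcLon, units = "mm month-1",
                       varname = "pr")
  tLat <- seq(35.3, 43.3, by = 0.9); tLon <- seq(-9.7, -1.6, by = 0.9)
  tg3 <- regridNearest(src3, tLat, tLon)
  gc <- function(la1, lo1, la2, lo2) {
    r <- pi / 180
    a <- sin((la2 - la1) * r / 2)^2 +
      cos(la1 * r) * cos(la2 * r) * sin((lo2 - lo1) * r / 2)^2
    2 * asin(pmin(1, sqrt(a)))
  }
  for (i in seq_along(tLat)) for (j in seq_along(tLon)) {
    d <- outer(srcLat, srcLon, function(a, b) gc(tLat[i], tLon[j], a, b))
    b <- arrayInd(which.min(d), dim(d))
    expect_equal(fieldValues(tg3)[, i, j], v[, b[1], b[2]])
  }
})

test_that("the spatial domain admits only the US and Europe boxes, bounds inclusive", {
  lat <- c(24.9, 25, 37, 50, 50.1, 70, 70.1)
  lon <- c(-125.1, -125, -60, -59.9, -10, 36, 36.1)
  dm <- domainMask(lat, lon)
  expect_true(dm[lat == 25, lon == -125])    # US corner inclusive
  expect_true(dm[lat == 50, lon == -60])
  expect_false(dm[lat == 24.9, lon == -125])
  expect_false(dm[lat == 25, lon == -125.1])
  expect_true(dm[lat == 37, lon == -10])     # Europe west edge
  expect_true(dm[lat == 70, lon == 36])
  expect_false(dm[lat == 70.1, lon == 36])
  expect_false(dm[lat == 37, lon == 36.1])
  ## mid-Atlantic gap is outside both boxes
  expect_false(any(domainMask(40, -30)))
})
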