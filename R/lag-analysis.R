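#' @include AllClasses.R AllGenerics.R constructors.R drought-metrics.R
NULL

#' Lagged correlations between two monthly anomaly series
#'
#' Computes maxLag + 1 Pearson correlations between a response series
#' (de-seasonalized NPP) and a driver series (de-seasonalized CWD), with
#' the response offset by k = 0..maxLag months: r[k] correlates
#' `npp[(k+1)..n]` with `cwd[1..(n-k)]` (a one-month offset correlates NPP
#' starting in month 2 with CWD starting in month 1). The overlap shrinks
#' with k; there is no padding or wrap-around. The p-value is the nominal
#' two-sided t-test p of each correlation at its own sample size.
#'
#' @param npp,cwd equal-length numeric anomaly series; length must exceed
#'   maxLag + 2.
#' @param maxLag largest offset in months (default 60).
#' @return data.frame with columns lag, r, p, n. Offsets whose overlap has
#'   zero variance in either series get NA r and p.
#' @export
#' @examples
#' x <- rnorm(120)
#' laggedCorrelations(c(rep(0, 3), x[1:117]), x, maxLag = 6)$r[4] # ~1 at lag 3
laggedCorrelations <- function(npp, cwd, maxLag = 60L) {
  maxLag <- as.integer(maxLag)
  n <- length(npp)
  if (length(cwd) != n) stop("series must have equal length")
  if (n <= maxLag + 2L)
    stop("series too short: need length > maxLag + 2")
  r <- p <- rep(NA_real_, maxLag + 1L)
  nn <- integer(maxLag + 1L)
  for (k in 0:maxLag) {
    a <- npp[(k + 1L):n]
    b <- cwd[1:(n - k)]
    ok <- is.finite(a) & is.finite(b)
    m <- sum(ok)
    nn[k + 1L] <- m
    if (m < 3L) next
    a <- a[ok]; b <- b[ok]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    rk <- stats::cor(a, b)
    r[k + 1L] <- rk
    tstat <- rk * sqrt((m - 2) / max(1 - rk^2, .Machine$double.eps))
    p[k + 1L] <- 2 * stats::pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  }
  data.frame(lag = 0:maxLag, r = r, p = p, n = nn)
}

#' Optimal lag from a correlation vector
#'
#' The optimum is the offset with the maximum signed correlation (not
#' absolute value: water deficit and productivity anomalies are expected to
#' be positively correlated). Ties break toward the smallest lag; NA
#' entries are ignored.
#'
#' @param r numeric vector of correlations at lags 0..(length(r) - 1).
#' @return list(rMax, lagOpt).
#' @export
optimalLag <- function(r) {
  if (all(is.na(r))) return(list(rMax = NA_real_, lagOpt = NA_integer_))
  i <- which.max(r)   # first maximum -> smallest lag on ties
  list(rMax = r[i], lagOpt = as.integer(i - 1L))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values controlling the false discovery rate across
#' one family of tests (here: all in-domain grid cells of one model map).
#' Thin wrapper over [stats::p.adjust()] with method "BH"; NA p-values are
#' preserved.
#'
#' @param p numeric vector of raw p-values.
#' @return Adjusted p-values, same length and order; adjusted >= raw.
#' @export
fdrAdjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Per-cell lag-correlation map for one model
#'
#' De-seasonalizes the monthly NPP and CWD fields (idempotent if anomalies
#' are supplied), computes per-cell lagged correlations over 0..maxLag
#' months, takes the lag of maximum signed correlation, and adjusts the
#' nominal p-values of the maxima across all valid cells in one
#' Benjamini-Hochberg family. The reported p is the nominal p of the
#' selected maximum (a lag-optimized maximum is optimistic; see the
#' vignette for the caveat).
#'
#' @param npp,cwd aligned [MonthlyField-class] objects.
#' @param maxLag largest offset in months (default 60).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @param domain optional logical (nLat, nLon) matrix restricting the
#'   family of cells (e.g. [domainMask()]); others are masked.
#' @param model model identifier carried into the result.
#' @return A [LagCorrelationResult-class].
#' @export
lagCorrelationMap <- function(npp, cwd, maxLag = 60L, alpha = 0.05,
                              domain = NULL, model = "model") {
  .checkAligned(npp, cwd)
  maxLag <- as.integer(maxLag)
  nppA <- .cellMat(deseasonalize(npp))
  cwdA <- .cellMat(deseasonalize(cwd))
  n <- nrow(nppA)
  if (n <= maxLag + 2L) stop("record too short for maxLag")
  nCell <- ncol(nppA)
  valid <- as.vector(npp@mask & cwd@mask)
  if (!is.null(domain)) valid <- valid & as.vector(domain)

  rAll <- matrix(NA_real_, maxLag + 1L, nCell)
  for (k in 0:maxLag) {
    a <- nppA[(k + 1L):n, , drop = FALSE]
    b <- cwdA[1:(n - k), , drop = FALSE]
    rAll[k + 1L, ] <- .colCor(a, b)
  }
  rAll[, !valid] <- NA_real_

  rMax <- rep(NA_real_, nCell)
  lagOpt <- rep(NA_integer_, nCell)
  pVal <- rep(NA_real_, nCell)
  any_ok <- colSums(!is.na(rAll)) > 0L
  for (cc in which(any_ok)) {
    o <- optimalLag(rAll[, cc])
    rMax[cc] <- o$rMax
    lagOpt[cc] <- o$lagOpt
    m <- n - o$lagOpt
    tstat <- o$rMax * sqrt((m - 2) / max(1 - o$rMax^2, .Machine$double.eps))
    pVal[cc] <- 2 * stats::pt(abs(tstat), df = m - 2, lower.tail = FALSE)
  }
  pAdj <- fdrAdjust(pVal)
  sig <- !is.na(pAdj) & pAdj < alpha

  dimG <- c(length(npp@lat), length(npp@lon))
  new("LagCorrelationResult",
      rMax = matrix(rMax, dimG[1L], dimG[2L]),
      lagOpt = matrix(as.numeric(lagOpt), dimG[1L], dimG[2L]),
      pValue = matrix(pVal, dimG[1L], dimG[2L]),
      pAdj = matrix(pAdj, dimG[1L], dimG[2L]),
      significant = matrix(sig, dimG[1L], dimG[2L]),
      maxLag = maxLag, alpha = alpha, model = model)
}

## columnwise Pearson correlation of two conformable matrices
.colCor <- function(a, b) {
  am <- sweep(a, 2L, colMeans(a), "-")
  bm <- sweep(b, 2L, colMeans(b), "-")
  num <- colSums(am * bm)
  den <- sqrt(colSums(am^2) * colSums(bm^2))
  out <- num / den
  out[!is.finite(out)] <- NA_real_
  out
}

#' Ensemble mean of per-model lag maps
#'
#' Averages r_max and lag_opt across models, per cell, using only the
#' models whose correlation at that cell is significant (FDR-adjusted
#' p < alpha). Cells where no model is significant are masked. The number
#' of contributing models is recorded.
#'
#' @param results list of [LagCorrelationResult-class], one per model, on a
#'   common grid.
#' @return list(rMax, lagOpt, nContrib): matrices (nLat, nLon).
#' @export
ensembleLagMap <- function(results) {
  stopifnot(length(results) >= 1L)
  d <- dim(results[[1L]]@rMax)
  rSum <- lSum <- matrix(0, d[1L], d[2L])
  nC <- matrix(0L, d[1L], d[2L])
  for (res in results) {
    use <- res@significant & !is.na(res@rMax)
    rSum[use] <- rSum[use] + res@rMax[use]
    lSum[use] <- lSum[use] + res@lagOpt[use]
    nC[use] <- nC[use] + 1L
  }
  rMean <- rSum / nC
  lMean <- lSum / nC
  rMean[nC == 0L] <- NA_real_
  lMean[nC == 0L] <- NA_real_
  list(rMax = rMean, lagOpt = lMean, nContrib = nC)
}

#' Bin lag times into reporting intervals
#'
#' Bins lag times (months) into the intervals 0, 1, 2, 3-6, 7-12, 13-24 and
#' >24 months, which separate immediate, sub-seasonal, seasonal and
#' multi-annual response timescales.
#'
#' @param lags numeric vector, matrix or array of lags in months (0..60;
#'   ensemble means may be fractional).
#' @return Factor (same shape attributes dropped for vectors; matrices keep
#'   dim) with levels "0", "1", "2", "3-6", "7-12", "13-24", ">24".
#' @export
#' @examples
#' binLags(c(0, 5, 25))   # "0", "3-6", ">24"
binLags <- function(lags) {
  labs <- c("0", "1", "2", "3-6", "7-12", "13-24", ">24")
  ## right-closed bins on (-0.5, 0.5], (0.5, 1.5], (1.5, 2.5], (2.5, 6.5]...
  breaks <- c(-0.5, 0.5, 1.5, 2.5, 6.5, 12.5, 24.5, Inf)
  out <- cut(as.numeric(lags), breaks = breaks, labels = labs)
  if (!is.null(dim(lags))) dim(out) <- dim(lags)
  out
}

#' Dominant climate driver of productivity anomalies
#'
#' For each cell, finds the lag-optimized correlation of de-seasonalized
#' NPP with de-seasonalized precipitation and with temperature (same
#' 0..maxLag search for both), and labels the cell with the driver whose
#' maximum correlation has the larger absolute value. Cells where neither
#' driver's correlation is significant (each variable's own FDR family) are
#' masked.
#'
#' @param npp,precip,temp aligned [MonthlyField-class] objects.
#' @inheritParams lagCorrelationMap
#' @return list(driver: character matrix "P"/"T"/NA, r: matrix of the
#'   winning correlation, precipResult, tempResult).
#' @export
dominantDriver <- function(npp, precip, temp, maxLag = 60L, alpha = 0.05,
                           domain = NULL) {
  rp <- lagCorrelationMap(npp, precip, maxLag = maxLag, alpha = alpha,
                          domain = domain, model = "P")
  rt <- lagCorrelationMap(npp, temp, maxLag = maxLag, alpha = alpha,
                          domain = domain, model = "T")
  d <- dim(rp@rMax)
  driver <- matrix(NA_character_, d[1L], d[2L])
  rwin <- matrix(NA_real_, d[1L], d[2L])
  pOK <- rp@significant & !is.na(rp@rMax)
  tOK <- rt@significant & !is.na(rt@rMax)
  both <- pOK & tOK
  pw <- both & abs(rp@rMax) >= abs(rt@rMax)
  tw <- both & !pw
  pw <- pw | (pOK & !tOK)
  tw <- tw | (tOK & !pOK)
  driver[pw] <- "P"; rwin[pw] <- rp@rMax[pw]
  driver[tw] <- "T"; rwin[tw] <- rt@rMax[tw]
  list(driver = driver, r = rwin, precipResult = rp, tempResult = rt)
}
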