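#' @include AllClasses.R AllGenerics.R legacy-effects.R
NULL

#' Spatial mean trajectory of one model
#'
#' Unweighted mean over all contributing cells of a per-cell recovery
#' trajectory, giving one 5-vector (drought year + 4 post-drought years)
#' per model. Cells missing a given year offset (truncated events) are
#' skipped for that offset.
#'
#' @param trajectory a [RecoveryTrajectory-class].
#' @return list(mean: numeric(5), nCells: integer(5) contributing cells per
#'   offset, units).
#' @export
modelMeanTrajectory <- function(trajectory) {
  a <- trajectory@anomalies
  if (nrow(a) == 0L)
    return(list(mean = rep(NA_real_, 5L), nCells = integer(5L),
                units = trajectory@units))
  list(mean = colMeans(a, na.rm = TRUE),
       nCells = colSums(!is.na(a)),
       units = trajectory@units)
}

#' Bootstrap confidence intervals for the ensemble mean trajectory
#'
#' Resamples the per-model mean trajectories with replacement `nBoot` times
#' (default 5000), averages each resample, and takes percentile confidence
#' intervals per trajectory year. The intervals measure the spread of the
#' model means, not sampling uncertainty of any one model. Deterministic
#' under a fixed seed.
#'
#' @param modelMeans numeric matrix (nModels, 5): one mean trajectory per
#'   model.
#' @param nBoot number of bootstrap resamples (default 5000).
#' @param level confidence level (default 0.95).
#' @param seed integer RNG seed.
#' @param probs probabilities for the across-model percentile bands
#'   (default 0.25, 0.5, 0.75).
#' @param units units tag carried through.
#' @return An [EnsembleSummary-class].
#' @export
bootstrapCI <- function(modelMeans, nBoot = 5000L, level = 0.95,
                        seed = 1L, probs = c(0.25, 0.5, 0.75),
                        units = "percent") {
  modelMeans <- as.matrix(modelMeans)
  m <- nrow(modelMeans)
  if (m < 2L)
    warning("fewer than 2 models: confidence interval is degenerate")
  meanTraj <- colMeans(modelMeans)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  bootMeans <- matrix(NA_real_, nBoot, ncol(modelMeans))
  for (b in seq_len(nBoot)) {
    idx <- sample.int(m, m, replace = TRUE)
    bootMeans[b, ] <- colMeans(modelMeans[idx, , drop = FALSE])
  }
  aHalf <- (1 - level) / 2
  ci <- apply(bootMeans, 2L, stats::quantile,
              probs = c(aHalf, 1 - aHalf), na.rm = TRUE, names = FALSE)
  ## percentile CIs can exclude the simple mean only by MC noise; clamp
  ciLow <- pmin(ci[1L, ], meanTraj)
  ciHigh <- pmax(ci[2L, ], meanTraj)
  pb <- ensemblePercentiles(modelMeans, probs = probs)
  out <- new("EnsembleSummary",
             meanTrajectory = meanTraj, ciLow = ciLow, ciHigh = ciHigh,
             percentiles = pb, probs = probs, perModel = modelMeans,
             units = units, nModels = as.integer(m),
             nBoot = as.integer(nBoot))
  attr(out, "bootGrandMean") <- colMeans(bootMeans)
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
}

#' Across-model percentile bands
#'
#' Empirical percentiles of the per-model mean trajectories for each
#' trajectory year, using the linear-interpolation convention of
#' [stats::quantile()] type 7 (so the median of 1..12 is 6.5).
#'
#' @param modelMeans numeric matrix (nModels, 5).
#' @param probs probabilities (default 0.25, 0.5, 0.75).
#' @return Numeric matrix (length(probs), 5), rownames the probabilities.
#' @export
ensemblePercentiles <- function(modelMeans, probs = c(0.25, 0.5, 0.75)) {
  modelMeans <- as.matrix(modelMeans)
  out <- apply(modelMeans, 2L, stats::quantile, probs = probs,
               na.rm = TRUE, names = FALSE, type = 7)
  out <- matrix(out, nrow = length(probs))
  rownames(out) <- paste0("p", formatC(100 * probs, format = "g"))
  out
}

#' Compare an ensemble trajectory against the observational benchmark
#'
#' Per post-drought year, reports the modeled percent depression
#' (depression = negative anomaly magnitude), the benchmark depression, and
#' the weakness ratio observed/modeled. Also reports each side's legacy
#' duration: the last consecutive post-drought year whose depression
#' exceeds `floorPct`. A modeled depression of zero or of opposite sign
#' yields an infinite ratio flagged `undefined` rather than an error.
#'
#' @param summary an [EnsembleSummary-class] in percent units.
#' @param benchmark a [Benchmark-class].
#' @param floorPct depression floor (percent) defining "still depressed"
#'   (default 0.5).
#' @return list(table: data.frame(year, modeled_depression_pct,
#'   benchmark_depression_pct, ratio, undefined), durationModel,
#'   durationBenchmark, year1Ratio).
#' @export
benchmarkComparison <- function(summary, benchmark, floorPct = 0.5) {
  stopifnot(is(summary, "EnsembleSummary"), is(benchmark, "Benchmark"))
  ## post-drought years 1..4; depression = -anomaly (percent below baseline)
  modelDep <- -summary@meanTrajectory[2:5]
  obsDep <- benchmark@values
  undef <- !is.finite(modelDep) | modelDep <= 0
  ratio <- ifelse(undef, Inf, obsDep / modelDep)
  tab <- data.frame(
    year = 1:4,
    modeled_depression_pct = modelDep,
    benchmark_depression_pct = obsDep,
    ratio = ratio,
    undefined = undef
  )
  durWith <- function(dep) {
    d <- 0L
    for (k in seq_along(dep)) {
      if (is.finite(dep[k]) && dep[k] > floorPct) d <- k else break
    }
    d
  }
  list(table = tab,
       durationModel = durWith(modelDep),
       durationBenchmark = durWith(obsDep),
       year1Ratio = ratio[1L])
}
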