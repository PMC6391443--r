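#' @include AllClasses.R AllGenerics.R synthetic-data.R drought-metrics.R lag-analysis.R legacy-effects.R ensemble.R io.R
NULL

#' Analysis configuration with study defaults
#'
#' Collects every tunable constant of the pipeline, defaulted to the study
#' values: extreme-drought threshold Z <= -2, normal-year window [-1, 1],
#' regression selection r > 0.3, FDR alpha 0.05, lag search 0-60 months,
#' 4-year exclusion window, 5000 bootstrap resamples.
#'
#' @param synthetic a [SyntheticConfig-class] describing the pseudo-model
#'   ensemble to generate (synthetic runs), or NULL when fields are
#'   supplied directly to [runPipeline()].
#' @param droughtThreshold extreme-drought Z threshold.
#' @param normalRange closed Z interval of climate-normal years.
#' @param rThreshold regression-selection correlation threshold (strict).
#' @param alpha FDR level.
#' @param maxLag largest lag searched, months.
#' @param exclusionWindow post-drought years scanned for follow-up
#'   extremes.
#' @param nBoot bootstrap resamples.
#' @param minNormalYears minimum qualifying years for the climate-normal
#'   baseline.
#' @param benchmark a [Benchmark-class] (default [treeRingBenchmark()]).
#' @param forestPurity purity of the synthetic forest map.
#' @param computeLagMaps compute per-model lag maps (the slowest stage;
#'   disable for legacy-only runs).
#' @param domainBoxes domain boxes passed to [domainMask()].
#' @param seed pipeline seed (bootstrap; the synthetic config carries its
#'   own generator seed).
#' @param outDir optional output directory for CSV/JSON artifacts.
#' @return A named list, validated.
#' @export
pipelineConfig <- function(synthetic = syntheticConfig(),
                           droughtThreshold = -2,
                           normalRange = c(-1, 1),
                           rThreshold = 0.3, alpha = 0.05,
                           maxLag = 60L, exclusionWindow = 4L,
                           nBoot = 5000L, minNormalYears = 5L,
                           benchmark = treeRingBenchmark(),
                           forestPurity = 0.8,
                           computeLagMaps = TRUE,
                           domainBoxes = list(us = c(25, 50, -125, -60),
                                              europe = c(36, 70, -10, 36)),
                           seed = 1L, outDir = NULL) {
  stopifnot(droughtThreshold < 0, length(normalRange) == 2L,
            normalRange[1] <= normalRange[2], rThreshold >= 0,
            alpha > 0, alpha < 1, maxLag >= 0, exclusionWindow >= 0,
            nBoot >= 1, minNormalYears >= 1)
  list(synthetic = synthetic, droughtThreshold = droughtThreshold,
       normalRange = normalRange, rThreshold = rThreshold, alpha = alpha,
       maxLag = as.integer(maxLag),
       exclusionWindow = as.integer(exclusionWindow),
       nBoot = as.integer(nBoot),
       minNormalYears = as.integer(minNormalYears),
       benchmark = benchmark, forestPurity = forestPurity,
       computeLagMaps = isTRUE(computeLagMaps),
       domainBoxes = domainBoxes,
       seed = as.integer(seed), outDir = outDir)
}

#' Run the full drought-legacy analysis
#'
#' Orchestrates the complete pipeline on a synthetic pseudo-model ensemble:
#' climate generation, CWD and its standardization, drought-event
#' detection, per-model lag maps with ensemble averaging, climate-normal
#' and CWD-regression recovery trajectories per model, forest-type maps,
#' ensemble bootstrap synthesis, and benchmark comparison. Returns all
#' intermediate objects plus a manifest with the filter-stage counts
#' (domain cells, selected cells, retained events) on which the analysis's
#' credibility rests. Reruns with an identical configuration are
#' bit-identical.
#'
#' @param config a list from [pipelineConfig()].
#' @return A list with elements climate, npp (per model), truth, cwd, z,
#'   catalog, lag (per model + ensemble), baselines, trajectories
#'   (absolute/percent per model), forest, summaryAbsolute, summaryPercent,
#'   comparison, manifest.
#' @export
#' @examples
#' \donttest{
#' cfg <- pipelineConfig(syntheticConfig(nLat = 3, nLon = 3, nModels = 3,
#'                                       seed = 7),
#'                       nBoot = 200, computeLagMaps = FALSE)
#' res <- runPipeline(cfg)
#' res$manifest$counts
#' }
runPipeline <- function(config) {
  synth <- config$synthetic
  if (is.null(synth))
    stop("stage synthetic_data: only synthetic configurations are supported; ",
         "supply a SyntheticConfig")

  climate <- generateClimate(synth)
  gen <- synthesizeNPP(climate, synth)

  dom <- domainMask(latitudes(climate$precip), longitudes(climate$precip),
                    boxes = config$domainBoxes)
  if (!any(dom)) stop("stage domain_filter: no cells in domain")

  cwd <- computeCWD(climate$precip, climate$pet)
  annualCWD <- annualTotal(cwd)
  z <- zscoreAnnual(annualCWD, quiet = TRUE)
  catalog <- identifyDroughtEvents(z, threshold = config$droughtThreshold,
                                   exclusionWindow = config$exclusionWindow)

  forest <- syntheticForestMap(synth, purityLevel = config$forestPurity)

  lag <- NULL
  if (config$computeLagMaps) {
    perModel <- lapply(seq_along(gen$npp), function(i)
      lagCorrelationMap(gen$npp[[i]], cwd, maxLag = config$maxLag,
                        alpha = config$alpha, domain = dom,
                        model = sprintf("model%02d", i)))
    lag <- list(perModel = perModel, ensemble = ensembleLagMap(perModel))
  }

  nSelected <- integer(length(gen$npp))
  absTraj <- pctTraj <- vector("list", length(gen$npp))
  absMeans <- pctMeans <- matrix(NA_real_, length(gen$npp), 5L)
  baselines <- vector("list", length(gen$npp))
  for (i in seq_along(gen$npp)) {
    annualNPP <- annualTotal(gen$npp[[i]])
    cnb <- climateNormalBaseline(annualNPP, z,
                                 minNormalYears = config$minNormalYears)
    reg <- fitCwdNppRegression(annualNPP, annualCWD, alpha = config$alpha,
                               rThreshold = config$rThreshold, domain = dom)
    nSelected[i] <- sum(reg@selected, na.rm = TRUE)
    absTraj[[i]] <- absoluteTrajectory(annualNPP, cnb, catalog)
    pctTraj[[i]] <- percentTrajectory(annualNPP, reg, annualCWD, catalog)
    absMeans[i, ] <- modelMeanTrajectory(absTraj[[i]])$mean
    pctMeans[i, ] <- modelMeanTrajectory(pctTraj[[i]])$mean
    baselines[[i]] <- list(climateNormal = cnb, regression = reg)
  }

  summaryAbs <- bootstrapCI(absMeans, nBoot = config$nBoot,
                            seed = config$seed, units = "gC m-2 yr-1")
  summaryPct <- bootstrapCI(pctMeans, nBoot = config$nBoot,
                            seed = config$seed, units = "percent")
  comparison <- benchmarkComparison(summaryPct, config$benchmark)

  ev <- events(catalog)
  counts <- list(
    cells_total = length(latitudes(cwd)) * length(longitudes(cwd)),
    cells_domain = sum(dom),
    cells_valid = sum(validMask(z)),
    cells_selected_median = stats::median(nSelected),
    events_total = nrow(ev),
    events_retained = sum(!ev$excluded),
    events_excluded = sum(ev$excluded),
    events_truncated = sum(ev$truncated & !ev$excluded)
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("droughtLegacy")),
    seed = config$seed, synth_seed = synth@seed,
    thresholds = list(drought = config$droughtThreshold,
                      normal = config$normalRange,
                      r = config$rThreshold, alpha = config$alpha,
                      max_lag = config$maxLag,
                      exclusion_window = config$exclusionWindow,
                      n_boot = config$nBoot),
    counts = counts,
    ensemble_mean_percent = summaryPct@meanTrajectory,
    ensemble_mean_absolute = summaryAbs@meanTrajectory
  )
  manifest$hash <- .manifestHash(manifest)

  res <- list(climate = climate, npp = gen$npp, truth = gen$truth,
              cwd = cwd, annualCWD = annualCWD, z = z, catalog = catalog,
              domain = dom, forest = forest, lag = lag,
              baselines = baselines,
              trajectories = list(absolute = absTraj, percent = pctTraj),
              modelMeans = list(absolute = absMeans, percent = pctMeans),
              summaryAbsolute = summaryAbs, summaryPercent = summaryPct,
              comparison = comparison, manifest = manifest)

  if (!is.null(config$outDir)) .writePipelineOutputs(res, config$outDir)
  res
}

.manifestHash <- function(manifest) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
             tmp)
  unname(tools::md5sum(tmp))
}

.writePipelineOutputs <- function(res, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  exportCatalogCSV(res$catalog, file.path(outDir, "drought_catalog.csv"),
                   startYear = startYear(res$cwd))
  for (i in seq_along(res$trajectories$percent)) {
    tr <- res$trajectories$percent[[i]]
    if (nrow(tr@anomalies))
      exportTrajectoryCSV(tr, file.path(outDir,
        sprintf("trajectory_percent_model%02d.csv", i)))
  }
  summ <- list(
    manifest = res$manifest,
    ensemble_percent = list(mean = res$summaryPercent@meanTrajectory,
                            ci_low = res$summaryPercent@ciLow,
                            ci_high = res$summaryPercent@ciHigh),
    comparison = res$comparison$table
  )
  writeLines(jsonlite::toJSON(summ, auto_unbox = TRUE, digits = NA,
                              dataframe = "rows"),
             file.path(outDir, "summary.json"))
  invisible(outDir)
}
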