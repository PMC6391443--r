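# droughtLegacy

Drought response and recovery analysis for gridded terrestrial
productivity.

## What this is for

Tree-ring records show that forest growth stays depressed for several
years after an extreme drought — a roughly 9% growth reduction in the
first post-drought year. Terrestrial biosphere models, which project the
future land carbon sink, may instead recover almost immediately; if so
they overestimate post-drought carbon uptake. droughtLegacy implements,
as reusable tested functions, the full analysis chain needed to ask that
question of gridded monthly model output, for carbon-cycle scientists and
model evaluators:

1. **Drought detection** — climatic water deficit CWD = P − PET
   (mm month⁻¹), summed annually and Z-scored per grid cell; extreme
   droughts are years with Z ≤ −2, merged into events anchored on their
   last year, with events followed by another extreme within 4 years
   excluded (`computeCWD()`, `zscoreAnnual()`, `identifyDroughtEvents()`).
2. **Lag times** — per cell, 61 Pearson correlations between monthly
   de-seasonalized NPP and CWD anomalies at offsets 0–60 months; the lag
   of the maximum signed correlation maps the response timescale, with
   Benjamini–Hochberg FDR control across cells and ensemble averaging
   over significant models (`lagCorrelationMap()`, `ensembleLagMap()`).
3. **Recovery trajectories** — 5-year NPP anomaly sets (drought year + 4
   post-drought years) under two baselines: the climate-normal mean NPP
   (years with −1 ≤ Z ≤ 1; absolute gC m⁻² yr⁻¹) and the per-cell OLS
   regression of annual NPP on annual CWD (percent of expected NPP;
   cells require significant r > 0.3), with forest-type stratification
   and spherical-area regional integrals in PgC
   (`absoluteTrajectory()`, `percentTrajectory()`, `regionalIntegral()`).
4. **Ensemble synthesis** — per-model spatial means, percentile bootstrap
   confidence intervals (5000 resamples of model means), across-model
   percentile bands, and comparison against a configurable tree-ring
   benchmark (`bootstrapCI()`, `benchmarkComparison()`).
5. **Synthetic truth** — a seeded pseudo-model ensemble generator with
   known injected lags, sensitivities and multiplicative legacy
   depressions, so every stage is validated by parameter recovery
   (`syntheticConfig()`, `generateClimate()`, `synthesizeNPP()`).

See `vignette("drought-legacy-methods")` for the model, its assumptions
and the numerical choices.

## Worked example

Twelve pseudo-models with a weak true legacy (2% in post-drought year 1,
nothing after) against the 9% tree-ring benchmark:

```r
library(droughtLegacy)

cfg <- pipelineConfig(
  synthetic = syntheticConfig(nLat = 8, nLon = 8, nModels = 12, seed = 42,
                              legacyProfile = c(0.02, 0, 0, 0)),
  nBoot = 5000, computeLagMaps = FALSE, seed = 42)
res <- runPipeline(cfg)

res$summaryPercent
#> EnsembleSummary [percent]: 12 models, 5000 bootstrap resamples
#>   yr 0:  -11.21  [ -11.39,  -11.03]
#>   yr 1:   -1.45  [  -1.58,   -1.31]
#>   yr 2:    0.46  [   0.30,    0.63]
#>   yr 3:    0.63  [   0.48,    0.78]
#>   yr 4:    0.51  [   0.39,    0.64]

print(res$comparison$table, digits = 3)
#>   year modeled_depression_pct benchmark_depression_pct ratio undefined
#> 1    1                  1.446                        9  6.22     FALSE
#> 2    2                 -0.462                        5   Inf      TRUE
#> 3    3                 -0.632                        2   Inf      TRUE
#> 4    4                 -0.514                        0   Inf      TRUE
```

Reading it: the ensemble's drought-year response is strong (−11.2% of the
NPP expected from CWD), but the year-1 legacy depression is only ~1.4% —
several-fold weaker than the 9% benchmark — and by year 2 the models have
fully recovered (anomalies at or above zero, so the observed/modeled
ratio is flagged undefined) while observations say growth should still be
depressed. The recovered 1.4% also illustrates the method's known
attenuation of an injected 2% legacy (the OLS baseline absorbs part of
the depression; see the vignette).

A command-line wrapper for config-driven runs lives at
`inst/scripts/run-pipeline.R`.

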