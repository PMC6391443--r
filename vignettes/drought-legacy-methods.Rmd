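---
title: "Quantifying drought response and recovery in gridded productivity: methods"
author: "droughtLegacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying drought response and recovery in gridded productivity: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(droughtLegacy)
```

## The problem

Terrestrial biosphere models (TBMs) project the future land carbon sink,
and one of the least constrained parts of those projections is how
vegetation recovers from extreme drought. Tree-ring records show *drought
legacy effects*: growth remains depressed for several years after climate
returns to normal, with roughly a 9% growth reduction in the first
post-drought year. If models recover too quickly, they overestimate the
carbon taken up after droughts and hence future sink strength.

droughtLegacy implements the analysis chain used to ask that question of
gridded monthly model output: detect extreme droughts from climate alone,
measure how fast productivity responds to water-deficit anomalies, trace
five-year recovery trajectories under two baselines, and compare a
multi-model ensemble against the tree-ring benchmark. Because the real
model archives are terabytes of NetCDF, the package also ships a seeded
synthetic pseudo-model ensemble with known injected lags and legacy
effects, so every stage can be validated by parameter recovery instead of
by eye.

## Drought index and event detection

The drought metric is the climatic water deficit,

$$\mathrm{CWD} = P - \mathrm{PET},$$

precipitation minus potential evapotranspiration (mm month⁻¹), a
plant-centred measure of water stress that avoids the soil-moisture
reporting ambiguities of process models (`computeCWD()`). PET supplied on
a coarser grid is brought onto the analysis grid by nearest-neighbour
replication, never interpolation (`regridNearest()`).

Annual CWD totals are Z-scored per grid cell over the full record
(`zscoreAnnual()`, sample standard deviation with the $n-1$ denominator; at
61 years the choice is immaterial but it is fixed for reproducibility).
An *extreme drought* is a year with $Z \le -2$; consecutive extreme years
merge into one event whose analysis anchor — the "drought year" — is the
run's last year (`identifyDroughtEvents()`). Two pragmatic rules protect
the recovery window:

* an event followed by another extreme year within the next 4 years is
  excluded (its recovery would be contaminated by the next drought);
  exclusion looks forward only — a *previous* nearby event does not void
  a later one;
* events whose 4 post-drought years run past the record end are retained
  but flagged truncated, contributing only the years they cover.

*Climate-normal* years are those with $-1 \le Z \le 1$ (closed interval,
`normalYearMask()`); for standard-normal Z about 68.3% of years qualify
and about 2.3% are extreme, which the calibration tests verify.

## Lag time between climate and productivity anomalies

Monthly NPP and CWD are de-seasonalized by removing each cell's calendar-
month means (`deseasonalize()`). For each cell, 61 Pearson correlations
are computed with NPP offset 0–60 months behind CWD: offset $k$
correlates NPP months $k{+}1..n$ with CWD months $1..n{-}k$
(`laggedCorrelations()`). The overlap simply shrinks with the offset;
there is no padding or wrap-around. The optimum is the offset with the
maximum *signed* correlation — drought (negative CWD anomaly) reduces
NPP, so the expected correlation is positive — with ties broken toward
the smallest lag (`optimalLag()`).

Significance uses the nominal two-sided t-test p-value of the selected
maximum, adjusted across all in-domain cells of one model map by the
Benjamini–Hochberg step-up procedure (`fdrAdjust()`, one family per
model). Two caveats are deliberate:

* the p-value of a lag-optimized maximum is optimistic (a selection
  effect); the nominal value is reported because that is the convention
  the analysis follows, and downstream use is limited to masking;
* ensemble maps average r and lag only over the models significant at a
  cell (`ensembleLagMap()`), recording how many contributed.

Lags are reported in bins of 0, 1, 2, 3–6, 7–12, 13–24 and >24 months
(`binLags()`), separating immediate, sub-seasonal, seasonal and
multi-annual response timescales. Dominant-driver maps
(`dominantDriver()`) run the same lag-optimized search of NPP against
precipitation and temperature anomalies and label each cell by the larger
absolute maximum correlation; the same 0–60 window is used for both
drivers for comparability, and the series are monthly de-seasonalized
anomalies throughout.

## Recovery trajectories under two baselines

**Absolute (climate-normal) baseline.** Per cell, mean annual NPP over
climate-normal years only (`climateNormalBaseline()`; at least 5
qualifying years, otherwise the baseline is considered noise and the cell
is masked). The anomaly for event year offset $k = 0..4$ is
$\mathrm{NPP}(y_0{+}k) - \overline{\mathrm{NPP}}_{\mathrm{normal}}$ in
gC m⁻² yr⁻¹ (`absoluteTrajectory()`). Anomaly maps integrate to regional
totals with exact spherical cell areas,
$A = R^2\,\Delta\lambda\,(\sin\varphi_2 - \sin\varphi_1)$,
$R = 6{,}371$ km (`regionalIntegral()`, PgC yr⁻¹).

**Percent (CWD-regression) baseline.** Per cell, ordinary least squares
of annual NPP on annual CWD over the full record
(`fitCwdNppRegression()`). Cells qualify when the correlation is FDR-
significant *and* $r > 0.3$ — strictly, $r = 0.3$ fails — mirroring the
site-selection criterion of the tree-ring benchmark. The anomaly is the
percent departure from the NPP expected given that year's CWD:

$$a_k = 100\,\frac{\mathrm{NPP}(y_k) - \widehat{\mathrm{NPP}}(y_k)}
{\widehat{\mathrm{NPP}}(y_k)},$$

with the predicted value as the reference denominator ("how far is NPP
operating outside its typical relationship with climate"). Multi-year
droughts use the event's last-year CWD for the drought-year prediction.
Non-positive predictions are masked with a warning. Multiple events at a
cell are averaged together but never across cells, preserving spatial
heterogeneity; forest-type stratification keeps cells whose dominant
class matches and whose purity (dominant cover fraction) clears a
threshold, defaulting to dominant-class-only (`stratifyByForest()`).

### A known attenuation of the percent anomaly

Because OLS residuals average zero, the depressed drought and legacy
years are part of the fit and pull the regression line down; every
prediction is then slightly too low and recovered legacy depressions are
slightly too small. Under the synthetic defaults (three forced events per
cell in 61 years, 15% drought-year depression) the shift is about 0.6–0.9
percentage points. The same artifact is intrinsic to the method on real
data. Parameter-recovery tests therefore use a ±1.5 percentage-point
band, and the weak-legacy ensemble comparison is asserted qualitatively
(much weaker than the benchmark, recovery by year 2) rather than as an
exact ratio.

## Ensemble synthesis and the benchmark

Each model's cell trajectories reduce to one spatial-mean 5-vector
(`modelMeanTrajectory()`). The ensemble mean takes 95% percentile
bootstrap intervals from 5000 resamples of the model means
(`bootstrapCI()`); the intervals describe model-mean spread, not model
uncertainty, and the percentile (not BCa) variant is used as the plainest
reading of "bootstrapping the model means". Across-model percentile bands
use the `stats::quantile()` type-7 linear-interpolation convention (the
median of 1..12 is 6.5). `benchmarkComparison()` reports, per
post-drought year, the modeled percent depression, the benchmark
depression, their observed/modeled ratio, and each side's recovery
duration (last consecutive year with depression above a 0.5% floor); a
zero or negative modeled depression yields an infinite ratio with an
`undefined` flag rather than an error.

The benchmark ships as configuration: the first post-drought year is the
reported 9% growth reduction; years 2–4 default to a decaying profile
(5, 2, 0%) that is an assumption, not a measured value, and should be
overridden when better estimates exist (`treeRingBenchmark()`).

## The synthetic pseudo-model ensemble

`generateClimate()` and `synthesizeNPP()` build a world in which every
downstream answer is known:

* **Precipitation** is a sinusoidal seasonal pattern times a per-cell,
  per-year lognormal multiplier (mean 1, log-SD 0.25) — seasonality plus
  interannual variability in factorized form. **PET** repeats its own
  seasonal cycle. Listed drought years are forced by scaling that year's
  precipitation down with bisection until the annual CWD Z-score is at or
  below −2.05, so detection at the −2 threshold is never borderline; if
  even zero precipitation cannot reach −2.05 the generator fails naming
  the year.
* **NPP** is `meanNPP` + seasonal cycle + `cwdSensitivity` × the
  standardized monthly CWD anomaly shifted by `responseLagMonths`, plus
  AR(1) noise (default coefficient 0.3 — plausible ecological memory
  without swamping the signal; the real noise structure of TBM output is
  unknown, so the coefficient is exposed as configuration). The lag is
  applied as a **circular shift**: the wrapped driver is defined for
  every month and carries exactly zero calendar-month means, so
  de-seasonalization recovers it exactly and, with zero noise, the
  lag-analysis stage returns the injected lag with $r_{\max} = 1$ to
  machine precision — the property the exactness tests assert. A
  zero-padded shift would leave order-0.1% deficits in $r$ from
  finite-sample seasonal means.
* **Legacy effects** multiply total NPP (matching the growth-fraction
  semantics of tree-ring benchmarks, not an additive anomaly): by
  $1 - 0.15$ in every extreme-drought year and by
  $1 - \mathrm{profile}[k]$ in the $k$-th post-drought year, default
  profile 9/5/2/0%. Depression applies to *all* realized extreme years —
  forced and naturally occurring — because the generated ecosystem should
  respond to droughts as such; otherwise natural events would dilute
  parameter recovery downstream. NPP is floored at zero.
* **Forest types** are assigned round-robin (needle-leaf evergreen,
  broadleaf deciduous, mixed) with configurable purity.
* Defaults: 61 years (emulating 1948–2008), 12 pseudo-models differing
  only in noise realization, baseline 50 gC m⁻² month⁻¹ (600 gC m⁻² yr⁻¹,
  a typical temperate forest), sensitivity 10 gC m⁻² month⁻¹ per Z-unit
  with marginal noise SD 5 (signal-to-noise 2:1), forced droughts in
  years 15, 35 and 50 (spaced beyond the exclusion window).

What the generator does **not** emulate: radiation, temperature or CO₂
effects on productivity; nitrogen; mortality and re-establishment;
spatially varying lags or sensitivities; non-stationary climate. Passing
recovery tests therefore demonstrate that the *analysis chain* is
correct and calibrated — not that any real model behaves this way.

## Numerical choices and degenerate inputs

* Zero-variance cells (constant annual CWD) are masked during Z-scoring
  with a reported count, never NaN.
* A cell-year with any missing month is masked in annual totals
  (conservative).
* Lag ties break to the smallest lag; all-NA correlation vectors return
  NA.
* Percentile-bootstrap intervals are clamped to bracket the simple
  ensemble mean (they can exclude it only through Monte-Carlo noise).
* Fewer than two models makes the bootstrap degenerate: a warning, not
  an error.
* The spatial domain is two boxes, contiguous US (25–50°N, 125–60°W) and
  Europe (36–70°N, 10°W–36°E), inclusive on cell centers; an empty
  domain aborts the pipeline with a clear message.
* The regression family for FDR is all in-domain cells of one model, the
  same family definition as the lag maps.

## Problem sizes in the shipped tests

The test suite exercises the pipeline at sizes chosen to make Monte-Carlo
bands tight while keeping the default run near ten seconds: 2×2 grids for
exactness properties, 8×8 for noisy lag recovery and the 12-model
ensemble comparison, 20×25 (500 cells) for legacy-profile recovery,
10,000 synthetic cell-years for detection calibration, and 200
repetitions of 5,000 all-null p-values for FDR calibration. The
acceptance script (`scripts/acceptance.R`) re-runs the same computations
from scratch under a caller-supplied seed.

## Limitations

* The percent-anomaly attenuation described above biases legacy
  magnitudes toward zero by well under a percentage point per unit of
  depressed-year mass; it is a property of the method, not of the
  implementation.
* Confidence intervals quantify model-mean spread only.
* The benchmark beyond post-drought year 1 is an assumed decay.
* Real-data ingestion expects CF-style NetCDF via the optional `ncdf4`
  readers; the analysis itself is format-agnostic and fully exercised on
  in-memory objects.
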