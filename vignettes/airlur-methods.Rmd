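---
title: "Methods: land-use regression with PLS and universal kriging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: land-use regression with PLS and universal kriging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airlur)
```

## The model

`airlur` implements a national-scale land-use-regression (LUR) workflow for
annual-average concentrations of the criteria air pollutants (PM2.5, PM10,
CO, NO2, SO2, O3). Monitoring-network annual values `y` are square-root
transformed — annual concentration averages are right-skewed and the sqrt
scale makes the Gaussian working assumption tenable — and modelled as

\[ \sqrt{y(s)} \;=\; F(s)\,\beta \;+\; \eta(s) \;+\; \varepsilon(s), \]

where `F(s)` holds an intercept plus a small number of partial-least-squares
(PLS) summary scores of the geographic predictor variables at site `s`,
`eta` is a stationary Gaussian process with exponential covariance
`C(h) = sigma2 * exp(-h/phi)` (partial sill `sigma2`, range `phi` in km) and
`epsilon` is iid nugget noise with variance `tau2`. Prediction at a new
location is the universal-kriging (UK) predictor

\[ \hat z(s_0) = F(s_0)\hat\beta + c(s_0)^\top \Sigma^{-1}(y_{\sqrt{}} - F\hat\beta),
   \qquad c_i(s_0) = \sigma^2 e^{-d(s_0, s_i)/\phi}, \]

followed by the back-transform `max(z, 0)^2`. No lognormal-style bias
correction is applied on the way back; the clamped square keeps native-scale
concentrations non-negative.

The PLS stage is classical univariate NIPALS on centred, unit-variance
predictors: the first weight vector is proportional to `X'y`, with deflation
between components; with as many components as the rank of the centred
matrix it reproduces ordinary least squares exactly, which the tests check.
Standardisation is necessary because the predictor set mixes units (km of
road, persons, grid samples, coordinates). Two or three components are used
in practice; `select_k_pls()` picks between them by conventional
cross-validation when the choice is open.

## Covariance estimation

`fit_uk()` maximises the Gaussian likelihood with `beta` profiled out by
generalised least squares, optimising `log(tau2), log(sigma2), log(phi)`
unconstrained (Nelder-Mead) from three variogram-guided starting points,
because the likelihood in `phi` is multi-modal. The guided start reads the
nugget from the first empirical-variogram bin, the sill from the last three,
and the range from the lag where the curve reaches 63% of the partial sill;
two dispersed starts bracket it. Restricted maximum likelihood is available
behind `reml = TRUE`; plain ML is the default.

Two numerical guards matter:

* a numerically singular covariance returns a large penalty (1e10) so the
  optimiser steps past it rather than crashing;
* when the optimum is within 2 NLL units of the nested iid model, the
  nugget-only fit is returned. Near `phi = 0` the likelihood cannot separate
  partial sill from nugget (`Sigma -> (sigma2 + tau2) I`), so on spatially
  independent data the unconstrained optimiser lands arbitrarily on that
  ridge; charging the two extra covariance parameters 2 NLL units (an
  AIC-style allowance) resolves the ridge toward the parsimonious model.

Distances are Euclidean km on projected coordinates or great-circle
(haversine) km on lon/lat, selected by a `metric` flag: monitor tables are
natively geographic, but kriging needs a metric space.

## Monitor quality control

Raw series are hourly for gases and daily for particulate matter. The rules,
applied by `qc_annual()`:

* a day is valid with at least 18 valid hourly measurements (hourly cadence
  only; daily PM records count by presence);
* a year is included with at least 244 valid days, or 61 for monitors
  reporting every third day, or 41 for every-sixth-day reporters. The
  schedule is classified from the modal gap between reported days, mapped to
  the nearest of {1, 3, 6}, ties toward the denser schedule — misclassified
  sparse sites then face the stricter threshold and fail, the conservative
  outcome. Thresholds are used unchanged in leap years;
* no more than 45 consecutive days may pass without any measurement. The run
  is measured on reported (not valid) days, includes year-edge silence, and
  applies to gases and PM alike;
* ozone uses a seasonal metric instead: for each May 1 - September 30 day the
  maximum over all 17 within-day 8-hour rolling means (a window's mean is
  computed when at least 6 of its 8 hours are present, a common regulatory
  convention; configurable), averaged over valid days, requiring valid days
  on at least 75% of the 153-day season. "At least 75%" is read as an
  inclusive lower bound, so the count threshold is the ceiling, 115. The
  season denominator is taken as the fixed 153-day season length rather than
  a monitor's scheduled days, the stringent reading.

Rejections are typed results carrying the failed rule, never errors; a QC
pass over a network reports per-site outcomes.

## Predictor variables

Features are computed in a projected plane (km) under a fixed
equirectangular mapping to lon/lat. Buffers are planar circles with radii
between 50 m and 15 km. Clipping is exact rather than rasterised:
segment-circle intersection in closed form for road length, and
piecewise-analytic circle-rectangle intersection areas for polygon fractions
and for apportioning population raster cells by overlap area (areal
weighting stands in for block-group population counts). Satellite-style
coarse rasters are sampled nearest-cell with no interpolation; cells are
half-open so a site exactly on an edge falls in the lower-left cell, and
out-of-extent sites take the nearest cell with a flag. Raw x/y position is
passed through as two variables. Column order always equals spec order, so
training and prediction matrices align by construction, and misaligned
prediction inputs are an error, never silently reordered.

## Model testing

Variables enter by greedy forward selection: the first by largest absolute
Pearson correlation with the response, each later one by the largest partial
F-statistic `((SSE_r - SSE_f)/1) / (SSE_f / (n - p_f))`, with `p_f` counting
the intercept (texts differ; this is stated explicitly). At a fixed step the
F ranking is monotone in the SSE reduction, so the implementation
orthogonalises candidates incrementally (one rank-1 Gram-Schmidt update per
step) and still reproduces the two-regression definition exactly, which the
brute-force oracle test verifies. Ties break by variable-name order;
numerically collinear candidates are skipped and logged. The partial F is a
ranking score only, not a hypothesis test.

Model testing runs two 10-fold cross-validations: conventional (seeded
random partition, fold sizes within one of each other) and spatially
clustered (k-means on site coordinates with deterministic farthest-point
seeding plus 50 seeded restarts; each cluster is a fold, and unequal fold
sizes are inherent). Clustered CV probes performance far from monitors.
Within every training fold the entire pipeline is refit — standardisation,
forward selection, PLS and the covariance parameters — because anything else
leaks information; a deliberate-leakage test confirms the honest pipeline
scores lower on noise-heavy data. Metrics are computed over pooled held-out
predictions (more stable than per-fold averages at small fold sizes) on the
native concentration scale after back-transform (chosen for
interpretability; the sqrt scale is a configuration away since predictions
carry both):

* MSE-R2 `= 1 - SSE/SST` about the observation mean: fit to the 1:1 line,
  penalising bias and slope, possibly negative;
* sRMSE `= RMSE / mean(obs)`: unitless, comparable across pollutants.

`sweep_n_predictors()` traces both metrics against the number of selected
variables under both schemes, the curve on which the parsimony argument
rests: with many pure-noise candidates the conventional-CV optimum sits at a
small predictor count and decays beyond it.

## Application and aggregation

A fitted model is applied at census-block centroids with nonzero population
(`predict_blocks()`; batched evaluation, and batch size provably cannot
change results since features and kriging are pointwise).
`population_weighted_aggregate()` computes `sum(pop * conc) / sum(pop)` per
block group, tract or county; weighted means are associative, so
block-to-tract equals block-to-block-group-to-tract exactly, a tested
invariant. FIPS codes are strings throughout (leading zeros are semantic)
and nest by prefix, mirroring 2010-vintage census geography.

## The synthetic study region

No national monitor extract or GIS stack can ship with a package, so every
input is generated with known parameters: a square projected domain (default
300 km) with urban foci; road segments and emission point sources anchored
near the foci with a uniform background share; a 2-km population raster
(Gaussian urban kernels, multiplicative lognormal texture); a strictly
coarser 25-km satellite-proxy raster correlated with the urban/traffic
structure; and a sqrt-scale truth field built exactly like the model assumes
— a linear mean in three analytic covariates (urban kernel, traffic
proximity, source proximity) plus an exponential-covariance Gaussian random
field. The GRF is simulated exactly by Cholesky factorisation, lazily: new
points are drawn conditionally on all previously materialised ones, so any
evaluation order realises the same stationary law and repeated evaluation of
a point returns its memoised value. Default truth coefficients
`(2.0, 3.0, 0.6, 0.3)` with partial sill 0.09, range 60 km and nugget 0.01
give annual PM2.5-like means of roughly 4-15 ug/m3 with realistic
urban-rural gradients; the positive mean offset plus clamped back-transform
keeps concentrations non-negative.

Monitor series reproduce the operational texture the QC rules exist for:
everyday / 1-in-3 / 1-in-6 schedules in configurable proportions (a 1-in-3
site has 110-123 scheduled days depending on its start day), MCAR dropout,
at most one contiguous gap per site (without it the 45-day rule would be
untestable under MCAR alone), per-hour dropout driving the 18-h rule, a
seasonal cycle, lognormal day-to-day noise, and a diurnal profile scaled so
the ozone daily-max-8-h metric is centred on the site's truth value.
Monitor siting is urban-clustered by default for the CV contrast: the
paper's use of clustered CV to probe extrapolation presumes monitors
cluster, and regulatory networks do.

What the generator does not emulate: multi-pollutant chemistry, reporting
artefacts other than missingness (exceptional events, instrument drift),
real census geography, and real satellite-product error structure. Passing
tests therefore demonstrate the pipeline's internal correctness and its
statistical behaviour under the model's own assumptions — not model adequacy
on real networks.

## Problem sizes and reproducibility

The test suite and the acceptance script run desk-scale versions of each
study: 150-monitor networks on a 300-km domain, 200 sites for
covariance-parameter recovery (20 replicates), 120 sites with 10 informative
plus 200 noise variables for the overfitting sweep, 10 seeded replicates for
the CV-scheme ordering, and a few hundred to 2000 blocks for the
application stage. All randomness flows from explicit integer seeds;
generators are bit-reproducible for a given seed. The numbered scripts under
`analysis/` run the pipeline end to end and write every table under
`results/`; `scripts/acceptance.R --seed N --out results/acceptance.json`
condenses a full run into one JSON report.

## Known limitations

* The exact GRF (O(n^3) Cholesky) is meant for thousands of points, not the
  millions a national block file holds; a sparse or spectral approximation
  would be the next step for that scale.
* Forward selection and the PLS mean model are refit per CV fold but the
  candidate variable list itself is fixed; structurally new predictors would
  require regenerating the feature spec.
* The 45-day-gap and schedule-classification conventions are deliberate
  resolutions of under-specified rules (stated above); sites near those
  boundaries can flip under a different convention, which is why the QC
  oracle test pins the implemented reading exactly.
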