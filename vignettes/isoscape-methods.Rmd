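---
title: "Methods: forest-based strontium isoscapes, their uncertainty, and provenance assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forest-based strontium isoscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Bioavailable ⁸⁷Sr/⁸⁶Sr — the strontium isotope ratio accessible to plants
and animals through soil and water — tracks the age and rubidium content of
the underlying bedrock and is stable on human timescales. A map of its
spatial distribution (an *isoscape*) lets archaeologists ask whether a
sampled individual is consistent with the place it was found: a measured
ratio inside the locally predicted range is compatible with local origin; a
ratio outside it indicates mobility.

This package implements the full workflow for building such an isoscape
from a georeferenced sample database and an environmental covariate stack,
quantifying its spatial uncertainty, measuring the value of additional
regional sampling, and assessing archaeological samples against the result.
Because the real inputs (a global sample compilation and ~1 km covariate
rasters) are multi-gigabyte external downloads, the package ships a
synthetic-landscape generator with the same statistical structure, so every
stage runs and is tested end to end at desk scale.

## The model

The response is the measured ratio $y_i$ at site $i$ with covariate vector
$x_i$ (bedrock-model ratio quantiles, lithological ages, climate,
atmospheric deposition, topography, soils — see `covariate_registry()`).
The core predictor is a bagged regression-forest
$\hat f(x) = \frac{1}{B}\sum_b T_b(x)$ with $B = 3000$ trees,
per-split candidate count $\lfloor p/3 \rfloor$, fitted after two
screening stages:

1. **Correlation pruning.** While any predictor pair has $|R| > 0.9$, one
   member is dropped — the one with the larger mean absolute correlation
   against the remaining predictors (ties broken by registry order).
   Forests tolerate collinearity, but strongly correlated pairs split
   importance and inflate their apparent influence. $|R|$ rather than $R$:
   a strong negative correlation is equally redundant.
2. **Three-step variable selection** (`select_variables()`).
   *Thresholding:* permutation importance is averaged over 50 forests;
   variables whose mean importance falls below the minimum of a
   regression-tree fit to the importance-SD-versus-rank curve are
   discarded (the SD curve is low and flat across pure-noise variables,
   so its fitted minimum separates the regimes). *Interpretation:* nested
   models are grown along the ranking; the smallest model whose OOB MSE
   is within one SD of the minimum is kept. *Prediction:* variables are
   re-admitted in rank order only when they improve OOB MSE by more than
   the noise fluctuation, estimated by adding step-1-discarded variables
   one at a time to the interpretation model and averaging the absolute
   OOB change (when step 1 discarded nothing, the fallback is the SD of
   the interpretation model's OOB error across repeated fits). The three
   sets are nested by construction; an all-noise input returns an explicit
   "no informative predictors" result rather than an error.

### Spatial uncertainty

The same forest doubles as a quantile forest: its leaves retain response
values, so conditional quantiles are available at no extra fit. The
uncertainty surface is
$\mathrm{SD}(x) = (q_{0.8413}(x) - q_{0.1587}(x))/2$,
half the central 68.27% prediction interval — the Gaussian-σ convention.
One estimator choice matters here: quantile leaves are grown to a minimum
of 20 observations instead of the regression default 5. Leaf response
distributions estimated from a handful of in-bag values are systematically
too narrow and the resulting intervals undercover; with ~20 values per
leaf the empirical coverage of the 68.27% interval on independent
synthetic test data sits within a few points of nominal (the acceptance
suite checks ±5), while the mean prediction is essentially unchanged.

### The stacked ensemble

The alternative estimator (`fit_stack()`) is a super learner: five base
learners — random forest, gradient boosting, RBF support-vector
regression, a single-hidden-layer neural network, and an elastic-net
linear model — are trained on spatially blocked folds, and a linear
meta-learner is fit on their *out-of-fold* predictions only, so it never
sees in-fold leakage (shuffling held-out labels collapses the stack's CV
R² to ~0, which the tests assert). Design choices the literature leaves
open, fixed here and surfaced in `stack_spec()`:

- **Oblique coordinates.** Four rotated planar axes
  ($\theta \in \{0°, 45°, 90°, 135°\}$, features
  $x\cos\theta + y\sin\theta$) enter as covariates to carry broad-scale
  spatial trend. Planar km coordinates come from a Lambert azimuthal
  equal-area projection centred on the data; raw degrees are anisotropic.
- **Spatial blocking.** Five folds from k-means on the projected
  coordinates. Blocked CV is the honest error under clustered sampling;
  random folds would let near-duplicate neighbours leak across folds.
- **Hyperparameters.** Library defaults throughout (recorded in the
  metrics output); a failing base learner is excluded with a diagnostic
  and the stack refits on the remainder.
- **Meta-learner CV.** The stack's own CV metric refits the linear
  combination leaving out each fold's rows, rather than reusing the
  full-data meta-fit.

The EML uncertainty surface comes from a quantile forest on the same
training data including the oblique features, with the same interval
convention as the RF product.

## The synthetic landscape

`generate_world()` emulates exactly the features the analysis relies on,
and nothing else:

- **Geology as a Voronoi tessellation** of uniformly placed seeds —
  piecewise-constant units with sharp boundaries, the reason local
  autocorrelation alone cannot carry an isoscape. Unit ages are drawn
  log-uniformly over 1–3000 Myr (Archean basement to Cenozoic cover).
- **An affine log-age response**:
  $\text{truth} = 0.704 + 0.002\log_{10}(\text{age}) + \sum_j \beta_j c_j$,
  monotone in log-age as radiogenic enrichment is, with two smooth climate
  fields ($\beta$ = 8e-4 and 5e-4 per SD) as secondary drivers.
- **Autocorrelated fields**: Gaussian white noise smoothed by a separable
  Gaussian kernel (20 km length), standardised.
- **A clustered campaign**: 500 sites, 60% inside one 15 km-radius disc
  (the densely sampled province), the rest uniform; recorded ratio =
  truth + site-level noise (σ = 0.001) + measurement noise (σ = 1e-4,
  matching a ~2e-4 2σ external reproducibility). The site-level σ is a
  free simulation parameter — within-site sampling variance of plant
  ratios is not something the generator can take from published values.
- **The full covariate registry**: bedrock-model quantiles are noisy
  transforms of the age-driven bedrock ratio (hence strongly informative
  and mutually correlated, as real ones are), lithological ages are
  per-unit perturbations, two climate fields are the true secondary
  drivers, and the remaining registry entries are independent smooth
  fields on realistic scales — present so pruning and selection face
  realistic redundancy and irrelevance.

The grid is geographic WGS84, square in degrees (~1 km at the reference
latitude). What the generator does **not** emulate: geochemical mass
balance (weathering, mixing, rainfall strontium budgets), anisotropic
terrain, non-Gaussian measurement error, and any resemblance to the real
Mongolian map. Passing tests therefore demonstrate that the estimators
recover a landscape *with the assumed structure* — piecewise lithology,
smooth secondary drivers, additive noise — not that any real isoscape is
accurate.

## The calibration experiment

`incremental_calibration()` asks: with a baseline database that never
sampled a province, how fast do predictions there improve as the new
regional campaign is added? For each fraction $f \in \{0, 0.1, …, 1\}$
and 10 repeats, $\lfloor f n \rfloor$ new sites are drawn without
replacement, a quantile forest is trained on base ∪ drawn, and the
*remaining* new sites provide held-out RMSE and the mean predicted SD
("spatial error" — the deliberate operationalisation of an axis the
source material labels only "SD"). At $f = 1$ evaluation is in-sample on
all new sites, once, flagged as such. Training and evaluation sets are
disjoint for every $f < 1$ by construction, and the suite asserts it.

## Provenance assessment

`assess_sites()` compares measured ratios against the isoscape range
within 10, 20 and 50 km of each site: min/max of the prediction over all
valid cells whose *centres* lie within the great-circle radius
(centre-rule membership is deterministic; polygon intersection is not
needed at 1 km resolution). Within-range is closed-interval — a
boundary-equal sample counts as local. Proportions are reported in
percent, two decimals, rounded half-up. Group means (site × material ×
archaeological/modern) are classified by their deviation from the nearest
bound of the 50 km range: inside; small (< 0.0005, within measurement
plus plant-scale scatter); moderate; large (> 0.001, a clear non-local
signal). Ranges are computed on the prediction surface only; widening by
±SD is available as an option but off by default, since the published
convention the package mirrors uses the prediction range.

Degenerate cases are explicit errors, not silent results: a site outside
the raster, a radius capturing no valid cell centre, a misaligned raster
pair.

## Numerical and I/O choices

- Rasters live in a minimal north-up container (`raster_grid`) and are
  exchanged as plain-text ESRI ASCII grids with a `.prj` sidecar; no
  GDAL-backed raster package is required anywhere in the workflow. The
  format carries one square cell size, which the degree-square grid
  satisfies.
- All km-radius logic (fallback search, buffers, cluster discs) uses
  haversine distances on cell centres; the nearest-valid-cell fallback
  searches up to 50 km (the largest assessment radius) and errors beyond.
- Every stochastic routine takes an explicit integer seed and runs under
  a save/restore of the caller's RNG state; forests are single-threaded
  for bit-stable reruns (the pipeline manifest hashes verify this).
- CV R² is defined as $1 - SSE/SST$ on held-out predictions and may be
  negative.
- Problem sizes in the shipped analysis and acceptance runs — a 100×100
  grid, 500 sites, 10 repeats/seeds per experiment, 1000 test sites for
  coverage — were chosen so the full suite reruns from scratch in
  minutes on a single core while keeping Monte-Carlo noise well inside
  the asserted margins.

## Known limitations

- The synthetic bedrock-model covariates are *constructed* to be
  informative; real bedrock models carry spatially structured error, so
  real-data selection results will differ from the synthetic ground-truth
  recovery demonstrated here.
- Quantile-forest intervals are conditional on the covariates and do not
  include extrapolation risk outside the training range; predictions are
  bounded by the training response range (a forest property), which
  understates uncertainty in genuinely novel geology.
- The three-step selection's step counts (50/25 forests) follow the cited
  algorithm's published defaults, and the per-forest tree count (100) was
  fixed for single-core runtime; all are exposed as arguments.
- Site-table support for summary-only sources produces mean-based
  assessment but no within-range proportions; that limitation is flagged
  per site rather than imputed away.
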