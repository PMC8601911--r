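---
title: "Methods: removal N-mixture density models and RTR representation tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: removal N-mixture density models and RTR representation tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic-data
generator, and the numerical and design choices behind `grasslandRTR`. It
states no empirical result beyond what the package's tests and
`scripts/acceptance.R` themselves compute.

## The observation model

Point-count surveys follow a removal protocol: over a 10-minute count
grouped into $J = 5$ two-minute bins, only newly detected individuals are
recorded. Given a per-interval detection probability $p$, an individual
present at the site is first recorded in bin $j$ with probability
$p(1-p)^{j-1}$ and never recorded with probability $(1-p)^J$. Site
abundance is Poisson with mean $\lambda_i A$, where
$\log \lambda_i = x_i^\top\beta$ is a density per km² and $A$ is the
effective sampled area entering the model as an offset — by default the
area of a 100-m-radius circle ($\pi \cdot 0.1^2 \approx 0.0314$ km²),
matching the buffer radius used for site covariates so that predictions
are area-free densities. Detection varies between surveys through a
logit-linear model in the (standardized) survey date; it is assumed
constant across bins within a survey, the standard removal-model
assumption.

Marginalizing the latent abundance gives the exact multinomial-Poisson
likelihood used throughout: the total count $T_i$ is Poisson with mean
$\lambda_i A\,(1-(1-p_i)^J)$ and the bin split is conditionally
multinomial. The package keeps a brute-force truncated sum over the
latent abundance only as a test oracle; the closed form is the production
likelihood (exact, fast, and free of a truncation constant). The two
agree to below $10^{-8}$ over a grid of 1134 small cases in the test
suite.

**Identifiability of the land-cover covariates.** The synthetic land
cover is an exact four-class partition (grassland, agriculture, forest,
urban), so the four buffer proportions always sum to one and are exactly
linearly dependent after centering. The default model therefore uses
forest as the reference class and fits grassland, agriculture and urban
proportions plus maximum temperature and precipitation. On real land
cover, where the four chosen classes need not partition the map, the
model specification accepts any named covariate set.

## Fitting, uncertainty and validation

* **Optimizer.** BFGS with analytic gradients, relative tolerance
  $10^{-8}$, at most 500 iterations, one perturbed restart on failure.
  The abundance intercept starts at the moment estimate
  $\log(\bar T / (A(1-0.5^J)))$ with all other coefficients at zero: a
  pure zero start can overflow the exponential on high-count data before
  the first line search completes. Inside the optimizer only, linear
  predictors are capped at $\eta = 30$ ($e^{30}$ per km² is far beyond
  any plausible density); non-finite covariate inputs are rejected with
  an error instead.
* **Covariance** is the inverse observed information (numeric Hessian at
  the optimum); intervals are Wald throughout.
* **Overdispersion.** A parametric bootstrap simulates data from the
  fitted model (site-by-interval Poisson cells, distributionally
  identical to Poisson abundance with multinomial removal), refits, and
  recomputes the Pearson chi-square over site × interval cells with a
  small-expectation floor of $10^{-4}$. $\hat c$ is the observed
  statistic over the bootstrap mean, floored at 1; standard errors are
  inflated by $\sqrt{\hat c}$ and point estimates are untouched.
* **Validation.** Repeated 30%-holdout AUC uses the detection-based
  probability $1-\exp(-\hat\lambda A(1-(1-\hat p)^J))$ scored by the rank
  (Mann–Whitney) statistic against the detection indicator, with a mean
  above 0.6 flagged as acceptable; the detection-based definition is a
  documented choice, as is reporting RMSE/MAE for the cross-validation
  metric. Residual spatial autocorrelation is assessed with a binned
  Moran's I correlogram of Pearson residuals (binary in-bin weights,
  global-variance normalization) against a permutation envelope within
  30 km — a binned correlogram rather than a spline-smoothed one, since
  the criterion (envelope straddling zero) does not depend on the
  smoothing. Under this convention a bin whose residuals are all equal
  is undefined and reported as `NA` rather than 1.

## Density surfaces and spatial planning

Predictions on the 1-km² grid use the fitted abundance coefficients
standardized with the *fitting* data's means and sample (n−1) standard
deviations — the convention is stored in `ScalingParams` so prediction
reuses it exactly. Error propagation follows the coefficient-shift
design: all abundance coefficients are jointly shifted by $\pm 1.96$ SE
($\hat c$-adjusted, covariances ignored) and every downstream analysis
can be run per layer. No ordering among the three layers is guaranteed
once covariates change sign; this mirrors the propagation design rather
than a delta-method alternative.

Population in a cell is density × 1 km²; the statewide population is the
sum over cells. The minimum set for a target fraction accumulates cells
by descending density (ties broken by row, then column) — for the
objective "fewest cells reaching a fraction of the total" this greedy
rule is provably optimal, and the tests verify it against exhaustive
search on small instances. A relative epsilon of $10^{-12}$ on the
target threshold absorbs `cumsum` round-off on near-tied (e.g. exactly
uniform) surfaces. Conservation-area baselines are the mean density over
cells whose centres fall within the footprint dilated by a 500-m buffer
(distance to the nearest footprint cell square), the reproducible
analogue of "all pixels intersecting the boundary" on a cell-mask
representation.

## The RTR null model

Replicates preserve the size and shape of the real conservation areas: a
uniform rotation in $(0, 2\pi)$ about the footprint centroid and a
translation uniform over the sampling-region bounding box, accepted only
when the replicate lies entirely within the region. Rasterization is by
cell-centre containment (a grid cell joins the replicate when its centre,
mapped through the inverse pose, lands inside a source cell); poses whose
rasterized cell count drifts more than 5% from the source are rejected as
rasterization failures. Suitability uses the 50% rule (a 1-km² cell is
unsuitable when forest + urban cover reaches half) and replicates with
more than 20% unsuitable cells are discarded and redrawn, with a
per-replicate budget of 1000 pose attempts and a global cap of $10^6$.

Decisions left open by the design and resolved here:

* Replicates may overlap one another and the real conservation area —
  excluding the real area would bias the null upward.
* Replicate means use **no** boundary buffer; the 500-m buffer applies to
  real-area baselines only. Both are toggleable (`buffer_m`,
  `replicate` behaviour via `generate_null_distribution`).
* "Greater than the 90% confidence interval" is operationalized as
  strictly greater than the empirical 90th percentile (one-sided): the
  baseline must fall in the top 10% of the null. A consequence exercised
  in the tests: an exactly uniform surface can never be flagged, because
  every replicate mean ties the baseline.
* Placements must lie entirely within the region (not merely their
  centroids), and the 1000 placements per area are shared across species
  (same placements, different surfaces): cheaper, and between-species
  comparisons are not contaminated by placement noise.
* Seeding: a scenario seed spawns one stream per area, so per-area null
  distributions are independently reproducible.

The test suite checks the calibration consequence of this construction:
on an exchangeable landscape (iid cell values, everything suitable), an
area drawn by the same placement process is flagged in roughly 10% of
trials (the nominal level of the one-sided 90th-percentile rule; the
empirical band allowed is 7–13%).

## The synthetic-data generator

The generator emulates the study conditions end to end and is itself
tested code.

* **Land cover**: a Gaussian-smoothed noise field thresholded at the rank
  quantiles of the target class fractions. Realized fractions are exact
  up to rounding; the autocorrelation range (default 1.5 km; 3 km in the
  demo) controls patch size. The texture is a modelling convenience —
  real land cover has anisotropic patches, linear features and class
  adjacencies the generator does not reproduce.
* **Climate**: linear spatial trends plus smoothed noise for maximum
  temperature (°C) and total precipitation (mm); precipitation is
  emitted directly as a seasonal total, treating upstream monthly
  aggregation as out of scope.
* **Conservation network**: contiguous blobs of 1-km² cells grown with a
  mild bias towards grass-rich cells; among up to 25 admissible
  candidates per footprint, the grass-richest is kept. This greedy step
  emulates expert designation of priority landscapes in the
  highest-grassland regions — without it, randomly seeded "priority"
  areas are statistically indistinguishable from the RTR null and the
  representation scenarios have nothing to detect. Every footprint must
  satisfy the same ≤20% unsuitable-cover rule as the null replicates.
* **Surveys**: uniform site locations rejected to a >400-m minimum
  spacing (with a hexagonal-packing feasibility bound and a bounded
  rejection budget of $10^5$ attempts), dates uniform over a
  configurable season window (default days 140–190).
* **Counts**: Poisson abundance at the (standardized) site covariates and
  interval membership drawn directly at the $J=5$ bin level — the model
  operates only on binned data, so the 1-minute recording step is not
  simulated.
* **Seeding**: one master seed with deterministic child streams per
  generator (`child_seed`), so any stage can be re-run in isolation.

The demo study (`demo_config_path()`) uses a 60 × 60 km landscape
(600 × 600 cells of 100 m), 400 survey sites, three 150-km² Focal
Landscapes with three 6-km² GBCAs each, and 1000 replicates per area —
sizes chosen so a full run completes in well under a minute while keeping
roughly the real survey density (about 0.12 sites per km²) and the real
GBCA-to-landscape area ratio. Its two species are designed as extreme
cases: a strongly grassland-concentrated species (log-density +2.0 per SD
of grassland cover) and an exactly uniform one (intercept-only
abundance), bracketing the behaviours the representation test must and
must not flag.

## Known limitations

* Fractions of a per-cell population, not connectivity or patch
  configuration, drive every evaluation; area-sensitivity of grassland
  birds enters only through covariate effects.
* Covariates act at a single scale (the buffer radius and the 1-km²
  cell); no multi-scale selection is attempted.
* Wald intervals with a scalar $\hat c$ are a pragmatic overdispersion
  correction, not a full hierarchical variance model.
* The coefficient-shift error layers ignore coefficient covariances by
  design.
* File interchange is plain text (CSV cell tables with geometry headers,
  YAML configuration, JSON summaries); in-memory rasters are matrix-backed
  objects in projected planar metres with an upper-left origin and
  half-open cell intervals.
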