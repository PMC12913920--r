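---
title: "Modelling forest microclimate grids with boosted spatial GAMs"
author: "microgrid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling forest microclimate grids with boosted spatial GAMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microgrid)
```

## The problem

Standard climate grids miss the microclimate that forest organisms
actually experience: temperatures under the canopy and near the ground
are decoupled from free-air macroclimate by terrain (lapse rate,
radiation load, cold-air pooling) and by canopy structure (buffering of
daily extremes). This package maps annual microclimate over structured
mountain forest at 5 m resolution by combining three ingredients: a
network of temperature loggers recording every 15 minutes at three
heights (soil −8 cm, near-ground 15 cm, air 200 cm), land-surface
predictors derived from a terrain model, and forest-structure predictors
derived from canopy rasters.

## From raw series to annual variables

Sensors measured together in a controlled environment for at least 24 h
receive a fixed offset — the mean difference between the focal sensor
and the mean of all other sensors at shared instants — which is
subtracted from every reading. Visual screening is replaced by two
deterministic rules: readings outside [−45, 60] °C, and runs of more
than 672 identical readings (7 days at 15 minutes — a failed or buried
sensor), are flagged removed. Both thresholds are configurable.

From calibrated series the package computes per site: the annual mean
per level; the 95th percentile of daily maxima and 5th percentile of
daily minima for the two air levels (robust extremes, insensitive to
single anomalous days); and growing degree days above 5 °C,
$\mathrm{GDD5} = \sum_i \max(0, T_i - 5)/96$, the time integral of the
temperature excess in °C·days. A site measured at all three levels
yields exactly nine annual variables.

Conventions the data sources leave open, fixed here and configurable:

* **Quantiles** use the linear-interpolation ("type 7") definition.
* **Calendar days** are bounded in fixed UTC+1 (no daylight saving);
  series should be built in a fixed-offset zone such as `Etc/GMT-1`.
* **Measurement year** = first timestamp + 365 days.
* **Completeness**: a day enters the daily table with ≥ 90 % of its 96
  readings; annual summaries require ≥ 90 % of days. These two 90 %
  thresholds are pragmatic defaults, not estimated quantities.

## Terrain predictors

All land-surface predictors derive from a terrain model at the target
resolution (5 m by default):

* **Slope/aspect** by the Evans–Young second-order polynomial on the
  3×3 window; aspect in degrees clockwise from north, pointing
  downslope; cells without a full window are nodata.
* **DAH**, diurnal anisotropic heating,
  $\cos(202.5^\circ - \alpha)\,\arctan(\beta)$ with slope angle
  $\beta$ in radians: an asymmetric heat-load proxy peaking on
  south-west slopes (afternoon sun), unlike symmetric solar radiation.
* **TPI** at 100/250/500 m radii: cell elevation minus the circular
  focal mean (cell-centre membership, focal cell included), divided by
  its raster-wide standard deviation so the three scales are
  comparable.
* **TWI** $= \ln(a/\tan\beta)$, with specific catchment area $a$ from
  Freeman multiple-flow routing at convergence 1.0 (flow to all lower
  8-neighbours ∝ slope^1), flow width equal to the grid resolution, and
  $\tan\beta$ floored at 0.001 so flats stay finite. Depressions are
  pre-filled to an epsilon gradient (Planchon–Darboux style); a no-fill
  mode exists for deliberately closed basins.
* **SAGAWI**: a TWI variant in which the catchment area is iteratively
  "modified": each neighbourhood pass lets a cell's area rise toward the
  largest neighbouring modified area damped by $s^{-\tan\beta}$ with
  suction $s = 10$. On steep ground the damping removes the spread
  (SAGAWI ≈ TWI); on flat valley floors the modified area approaches
  the basin maximum, which is exactly the cold-air-pooling behaviour the
  index is meant to capture. The damping exponent follows the published
  SAGA formulation in spirit; the package states it explicitly because
  upstream sources do not. Iteration stops at a relative change below
  10⁻³; the default cap of 1000 passes covers spread across a 200-cell
  map (roughly one pass per cell of distance).
* **Gaussian smoothing** (σ = 10 m and 25 m, suffixes `_g10`/`_g25`)
  models lateral air mixing. Kernels truncate at 4σ and renormalize;
  nodata is handled by mask-weighted normalization; edges use
  half-sample reflection, which makes the operator doubly stochastic and
  therefore exactly mean-preserving on fully valid rasters.

Coarsening a finer terrain model uses separable interpolating cubic
splines (passes through every source value, reproduces planes exactly);
adjacent terrain sources merge seam-free with symmetric linear distance
weights inside a 25 m blend strip.

## Canopy predictors

Vegetation height is the DSM−DTM difference floored at zero (a surface
below terrain is sensor noise) and median-aggregated to the target cell.
Canopy density is PRA2m, the percentage of LiDAR returns above 2 m;
cells with zero returns are nodata. Coniferous and deciduous cover
multiply PRA2m by the coniferous fraction and its complement, so the two
always sum to the canopy density. All structure predictors also get
`_g10`/`_g25` smooths.

## Sampling design

Site networks are stratified: Fisher–Jenks natural-breaks classification
(exact dynamic programme minimising within-class sum of squares; ties
broken toward the lowest first break; intervals left-closed) over five
elevation, three heat-load and three wetness classes gives 45 strata —
90 with an open/closed canopy split at the median canopy cover. Within
each non-empty stratum a seeded draw selects two plots; extreme-elevation
plots are forced in. Plots inside disturbance polygons are excluded
first (boundary points count as inside). The heat-load axis uses DAH as
the radiation proxy throughout the synthetic pipeline.

## The boosted spatial GAM

Each candidate predictor becomes a univariate P-spline base learner:
cubic B-splines on 20 interior knots with a second-order difference
penalty, its smoothing parameter fixed so every learner has exactly 4
effective df during boosting — equal complexity is what makes
componentwise selection fair. A 10×10 tensor-product smooth of the
coordinates (the spatial tensor) absorbs broad-scale trend and residual
autocorrelation and is always carried into the final model.

Componentwise L2 boosting starts from the response mean; each iteration
fits all learners to the current residuals by penalized least squares,
updates only the best one by a step of ν = 0.1, and the stopping
iteration `mstop` is the inner-10-fold-CV minimiser over the grid
{25, 50, …, 1000}. The learners ever selected form the model.

The selected smooths are then refit jointly, with per-term smoothing
parameters chosen by generalized cross-validation. Plain GCV is known to
undersmooth, so the effective-df term in the GCV denominator is inflated
by the customary γ = 1.4; this choice matters mostly at low noise. Each
term reports its effective df and a shape class (monotone ↑/↓, unimodal
∩, inverse-unimodal ∪, or flat below an absolute tolerance of 10⁻⁶;
curves with more sign changes are assigned the dominant direction and
flagged). GCV rather than REML keeps the refit closed-form and
dependency-free; it is a potential numeric difference from
implementations that optimise REML.

Predictions extend univariate smooths linearly beyond the training range
(value plus boundary derivative) and clamp tensor margins; the
serialized JSON model carries knots, transforms, coefficients, training
ranges and the selection seed, so a saved model reproduces predictions
exactly.

### The interaction decision

A possible interaction between heat load and canopy density (radiation
reaching the forest floor) is tested by adding a 5×5 DAH×PRA2m tensor to
the *final* model as an added-variable term: the tensor margins are
centred (so its penalty null space is the pure bilinear product, not
main effects), and the term is orthogonalized against the base model's
fitted effect curves before fitting — the base coefficients are
untouched and the tensor can only pick up structure the base model
cannot represent. Both models are scored by the same spatial folds
(coefficients refit per training fold, the tensor's own smoothing
parameter re-tuned per fold), and the interaction is kept only when it
lowers the mean fold RMSE by more than 3 %. A bare "any decrease" rule
is a coin flip under the null because fold-resampling noise alone moves
the mean RMSE by a percent or two; simulated true interactions of
ecologically plausible size improve the CV RMSE by 10–40 %, so the 3 %
margin separates the two regimes cleanly. The margin is a configurable
argument.

## Spatial cross-validation

Model error is estimated by ten-fold spatial block CV: sites map to a
regular flat-topped hexagon lattice (axial-coordinate rounding, lattice
origin at the data bounding-box corner), and hexagons are assigned to
folds by the longest-processing-time greedy rule (largest hexagon to the
currently smallest fold), so folds are approximately balanced and a
hexagon is never split. Each fold is predicted by a model fitted from
scratch — including boosting selection — on the other nine. The headline
number is the unweighted mean of the ten fold RMSEs; the pooled RMSE
over all held-out residuals is reported alongside.

## The synthetic world

Because the real logger network and LiDAR rasters cannot ship with the
package, a seeded generator builds worlds with known truth:

* **Terrain**: spectral-synthesis fractal surface (power-law spectrum,
  exponent 1.8) plus one incised valley, one ridge and a regional tilt,
  scaled to span 400 m of relief above 600 m a.s.l. — a realistic
  single-mountain block at the default 200×200 cells of 5 m, with
  enough structure that the wetness and position indices carry signal.
* **Canopy**: thresholded smoothed noise divides the map into disturbed
  patches (density near 0–15 %) and closed forest (80–95 %), with
  correlated vegetation height, Poisson return counts and a smooth
  coniferous fraction; 30 % disturbed by default, matching a
  heavily disturbed montane spruce landscape.
* **Loggers**: the generative temperature model is stated exactly:
  $$T(s,t) = T_0 + \text{lapse}\,(z_s - z_0) + a_\mathrm{dah}\,\mathrm{DAH}_s
    + \text{season}(t) + \big[1 - a_\mathrm{buffer}\,\tfrac{\mathrm{PRA2m}_s}{100}\big]\,
    \text{diurnal}(t) - a_\mathrm{twi}\,\mathrm{SAGAWI}_s\,\text{night}(t) + \varepsilon$$
  with a yearly cosine peaking on day 200, a daily cosine peaking at
  14:00, a night indicator (18:00–06:00), level-specific multipliers
  (soil damps the daily cycle to 15 %, near-ground amplifies it by 20 %),
  and ε ~ N(0, 0.3 °C) per reading. Defaults: lapse −6.5 °C km⁻¹,
  $a_\mathrm{dah}$ = 1.5 °C, $a_\mathrm{buffer}$ = 0.8,
  $a_\mathrm{twi}$ = 0.15 °C per SAGAWI unit, seasonal amplitude 9 °C,
  diurnal amplitude 4 °C — magnitudes typical of montane forest
  gradients. An optional `a_int` adds a genuine DAH×PRA2m product for
  interaction experiments.
* **Ground truth** annual summaries come in closed form from the
  repeating daily profile (exact, matching the pipeline's summaries of
  noiseless simulated loggers to 10⁻⁶), so recovery can be scored
  against an analytic target.

One subtlety is worth stating. Per-reading noise averages out of annual
summaries almost entirely (0.3 °C per reading contributes ~0.002 °C to
an annual mean of 35 000 readings). Real site summaries scatter far more
than that around any terrain model because of microsite heterogeneity —
soil, understorey, sensor placement. The generator therefore also
provides `simulateSiteSummaries()`: closed-form truth plus an
independent N(0, 0.3 °C) site-level effect. The model-recovery and
CV-calibration experiments use this site-level response; with it, the
spatial-CV mean RMSE should sit in [0.8, 1.3] times the site noise for a
correctly specified world, which is exactly what the test suite
verifies.

## What the tests show — and what they do not

The test suite verifies: exact oracles for every arithmetic operation
(offsets, quantiles vs a sort-based oracle, degree days, Jenks vs
exhaustive partitions, Freeman mass conservation, DAH geometry);
property-style invariants (SAGAWI ≥ TWI, shape classes, chunk-invariant
grid prediction, bit-reproducible worlds); and full-pipeline recovery on
the default world — predicted annual-mean grids correlate r ≥ 0.95 with
truth in at least 18 of 20 seeds at 0.3 °C site noise, spatial-CV RMSE
calibrates to the injected noise, and the interaction tensor is kept
when simulated and dropped otherwise in ≥ 90 % of runs. Problem sizes
(200×200 cells, 150 sites, 20 seeds) are chosen so a full desk run
completes in minutes.

Passing these tests shows the machinery is correct and the estimator
recovers the generative structure it assumes. It does not show that real
forest microclimate is additive in these predictors, that 0.3 °C is the
right microsite noise, or that snow-cover dynamics (which dominate
interannual variability of near-ground minima in real data) are
representable — the generator has no snow, no soil moisture, and no
phenology. Numbers obtained on synthetic worlds transfer to real
networks only as far as those assumptions do.

## Known limitations

* Raster IO is ESRI ASCII text only; the CRS is carried as an opaque
  tag. GeoTIFF support would require an external geospatial stack.
* The GCV refit optimises per-term smoothing by Nelder–Mead; REML-based
  implementations can give somewhat different effective df for the same
  data.
* The SAGAWI damping exponent is stated, not inherited from a reference
  implementation; absolute SAGAWI values may differ from other software
  even where orderings agree.
* Aspect is undefined on flats and within one cell of the raster edge;
  downstream indices inherit that nodata ring.
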