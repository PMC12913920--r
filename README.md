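# microgrid

High-resolution forest microclimate mapping in R: from raw 15-minute
temperature-logger series and LiDAR-derived terrain/canopy rasters to
5-m annual microclimate grids with spatially cross-validated error
estimates and an extrapolation-uncertainty map.

## Who this is for

Ecologists and climate modellers who run (or want to emulate) a
microclimate logger network in structured forest terrain — soil (−8 cm),
near-ground (15 cm) and air (200 cm) temperature sensors recording every
15 minutes — and want wall-to-wall annual temperature surfaces rather
than point measurements.

## What it computes

**Annual microclimate variables per site.** Sensor co-location offsets,
automated quality screening, daily aggregation, and the nine standard
annual variables: mean temperature per level, the 95th percentile of
daily maxima and 5th percentile of daily minima for the two air levels,
and growing degree days above 5 °C
(`GDD5 = Σ max(0, T_i − 5) / 96` over the measurement year).

**Terrain and canopy predictors at 5 m.** Cubic-spline resampling and
seam-free mosaicking of terrain models; Evans–Young slope and aspect;
diurnal anisotropic heating `DAH = cos(202.5° − aspect) · arctan(slope)`;
standardized topographic position indices (100/250/500 m radii);
topographic wetness index `ln(a / tan β)` from Freeman multiple-flow
routing (convergence 1.0, flow width = grid resolution); the SAGA
wetness index (iteratively modified catchment area, suction 10) as a
cold-air-pooling proxy; vegetation height (median-aggregated DSM−DTM),
canopy density (proportion of LiDAR returns above 2 m, PRA2m),
coniferous/deciduous cover, and Gaussian-smoothed variants (`_g10`,
`_g25`).

**The modelling engine.** A componentwise gradient-boosted spatial GAM:
P-spline base learners (cubic B-splines, 20 interior knots, 2nd-order
difference penalty, 4 df each during boosting) are fitted to residuals;
each iteration updates only the best learner (step 0.1), so boosting
performs variable selection; the stopping iteration is chosen by inner
10-fold CV. Selected smooths plus a 10×10 spatial tensor are then
jointly refit with GCV-chosen smoothing parameters. An optional
DAH×PRA2m interaction tensor is accepted only if it lowers spatial-CV
RMSE by a clear margin. Model skill is measured by ten-fold spatial
block cross-validation on a hexagon lattice (sites in one hexagon never
split across folds).

**Grids.** Fitted models are applied over the predictor stack
(chunked, bit-reproducible), with a per-cell extrapolation-uncertainty
raster: the fraction of model predictors outside the training range.

**A synthetic world.** `makeSyntheticWorld()` builds a seeded fractal
mountain landscape with patchy canopy, a stratified site network
(Fisher–Jenks natural-breaks strata over elevation, heat load and
wetness), and loggers driven by a known additive temperature model — so
every pipeline stage is testable end to end with known ground truth.

## Worked example

```r
library(microgrid)

w <- makeSyntheticWorld(seed = 1)          # 200 x 200 cells @ 5 m, 150 sites
d <- simulateSiteSummaries(w, seed = 11)   # annual mean air temperature + site noise

m <- fitBoostedGAM(d, "response",
                   c("Elevation", "DAH", "SAGAWI", "TWI", "TPI_500",
                     "Slope", "PRA2m", "Veg_Height"),
                   control = boostControl(seed = 11))
m
#> BoostedGAMModel for response: 8 terms, mstop 150, adj R2 0.891
#>   Elevation              edf  2.67 ↓
#>   DAH                    edf  1.00 ↑
#>   SAGAWI                 edf  1.00 ↓
#>   ...
#>   SpatialTensor          edf  3.07

grid  <- predictGrid(m, worldStack(w))     # 5-m annual-mean grid
unc   <- uncertaintyRaster(m, worldStack(w))

truth <- groundTruthGrids(w, variables = "mean")$mean
ok <- is.finite(gridValues(grid)) & is.finite(gridValues(truth))
cor(gridValues(grid)[ok], gridValues(truth)[ok])
#> [1] 0.9961905
```

The fitted model reads as: temperature falls with elevation (↓), rises
on warm south-west slopes (DAH ↑), and falls where
cold air pools (SAGAWI ↓) — and the predicted grid correlates r ≈ 0.996
with the noiseless generative surface.

Spatial cross-validation:

```r
folds <- allocateFolds(hexAssign(d$x, d$y, 150), k = 10, seed = 1)
cv <- spatialCv(d, "response", folds$fold,
                predictors = c("Elevation", "DAH", "SAGAWI", "TWI",
                               "TPI_500", "Slope", "PRA2m", "Veg_Height"),
                control = boostControl(seed = 21))
cv$meanRmse
#> [1] 0.3052032     # close to the 0.3 degC site-level noise
```

## Command line

A thin wrapper is installed under `inst/scripts/microgrid.R`:

```sh
Rscript inst/scripts/microgrid.R synth --config demo.json   # emit a synthetic world
Rscript inst/scripts/microgrid.R run   --config demo.json   # full pipeline run
```

Grids are read and written as ESRI ASCII (`.asc`) text rasters; models
serialize to self-describing JSON.
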