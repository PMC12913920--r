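## Synthetic worlds with known generative truth: fractal terrain, patchy
## canopy, and an additive temperature model driving simulated loggers.

withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Synthetic mountain terrain
#'
#' Spectral-synthesis fractal surface (power-law amplitude spectrum)
#' with one incised valley and one ridge superimposed so that wetness
#' and position indices have real signal, scaled to span exactly
#' `reliefM` metres above `baseElev`.
#'
#' @param seed RNG seed; the raster is bit-for-bit reproducible.
#' @param n grid side length in cells (default 200).
#' @param cellSize cell size in metres (default 5).
#' @param reliefM elevation span (default 400 m).
#' @param baseElev elevation of the lowest cell (m a.s.l., default 600).
#' @param exponent spectral decay exponent (default 1.8; larger =
#'   smoother terrain).
#' @return [RasterGrid-class] digital terrain model.
#' @export
synthTerrain <- function(seed = 1, n = 200, cellSize = 5, reliefM = 400,
                         baseElev = 600, exponent = 1.8) {
  z <- withSeed(seed, {
    f1 <- stats::fft(matrix(stats::rnorm(n * n), n, n))
    fr <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
    fmag <- sqrt(outer(fr^2, fr^2, `+`))
    fmag[1, 1] <- Inf   # kill the DC term
    amp <- fmag^(-exponent)
    Re(stats::fft(f1 * amp, inverse = TRUE)) / (n * n)
  })
  # deterministic valley (diagonal incision) and ridge (off-diagonal crest)
  u <- (row(z) - 1) / max(n - 1, 1); v <- (col(z) - 1) / max(n - 1, 1)
  dValley <- (u - v) / sqrt(2)
  dRidge <- (u + v - 1.3) / sqrt(2)
  z <- scale01(z) - 0.55 * exp(-(dValley / 0.08)^2) +
    0.45 * exp(-(dRidge / 0.1)^2) + 0.8 * v   # regional tilt: drains the valley
  if (reliefM <= 0) return(rasterGrid(matrix(baseElev, n, n),
                                      cellSize = cellSize, crs = "synthetic"))
  zz <- scale01(z) * reliefM + baseElev
  rasterGrid(zz, cellSize = cellSize, crs = "synthetic")
}

scale01 <- function(m) {
  r <- range(m)
  if (diff(r) == 0) return(m * 0)
  (m - r[1]) / (r[2] - r[1])
}

#' Synthetic canopy structure
#'
#' A patchy canopy-density field: thresholded smoothed noise divides the
#' landscape into disturbed patches (density near 0-15%) and closed
#' forest (near 80-95%), with correlated vegetation height, simulated
#' LiDAR return counts and a smoothly varying coniferous fraction.
#'
#' @param seed RNG seed.
#' @param dtm terrain model the canopy is draped on.
#' @param disturbedFraction target areal fraction of disturbed patches.
#' @param returnsPerCell mean simulated LiDAR returns per cell.
#' @return named list of rasters: `PRA2m`, `Veg_Height`, `returns_total`,
#'   `returns_above2m`, `tree_type_fraction`, `disturbed` (0/1), and
#'   `dsm` (dtm + canopy height).
#' @export
synthCanopy <- function(seed = 1, dtm, disturbedFraction = 0.3,
                        returnsPerCell = 1375) {
  n <- nrow(dtm@values); m <- ncol(dtm@values)
  out <- withSeed(seed + 1000L, {
    noise <- rasterLike(matrix(stats::rnorm(n * m), n, m), dtm)
    field <- gaussianSmooth(noise, sigma = 8 * dtm@cellSize)@values
    thr <- stats::quantile(field, disturbedFraction, type = 7)
    disturbed <- field <= thr
    u <- matrix(stats::runif(n * m), n, m)
    pra <- ifelse(disturbed, 15 * u, 80 + 15 * u)
    height <- ifelse(disturbed, 2 * u, (12 + 24 * u) * pra / 95)
    total <- matrix(stats::rpois(n * m, returnsPerCell), n, m)
    above <- round(total * pra / 100)
    conifNoise <- gaussianSmooth(
      rasterLike(matrix(stats::rnorm(n * m), n, m), dtm),
      sigma = 15 * dtm@cellSize)@values
    conif <- stats::pnorm(scale(as.vector(conifNoise))[, 1] + 1)  # mostly conifer
    list(pra = pra, height = height, total = total, above = above,
         conif = matrix(conif, n, m), disturbed = disturbed)
  })
  list(PRA2m = rasterLike(out$pra, dtm),
       Veg_Height = rasterLike(out$height, dtm),
       returns_total = rasterLike(out$total, dtm),
       returns_above2m = rasterLike(out$above, dtm),
       tree_type_fraction = rasterLike(out$conif, dtm),
       disturbed = rasterLike(out$disturbed * 1, dtm),
       dsm = rasterLike(dtm@values + out$height, dtm))
}

#' Default generative coefficients of the synthetic temperature model
#'
#' The additive model is
#' `T(s,t) = T0 + lapse * (elev - refElev) + a_dah * DAH + season(t) +
#'  (1 - a_buffer * PRA2m/100) * diurnal(t) - a_twi * SAGAWI * night(t) + eps`
#' with `season` a yearly cosine peaking on day 200, `diurnal` a daily
#' cosine peaking at 14:00, `night` an indicator of 18:00-06:00, and
#' level-specific multipliers damping the diurnal and night terms in the
#' soil and amplifying them near the ground.
#'
#' @details An optional `a_int` coefficient (default 0) adds a genuine
#' heat-load-by-canopy interaction `a_int * DAH * PRA2m / 100` to the
#' base level, used to test the interaction-tensor decision.
#'
#' @return named list of coefficients.
#' @export
defaultCoefficients <- function() {
  list(T0 = 7, refElev = 600, lapse = -0.0065, a_dah = 1.5, a_buffer = 0.8,
       a_twi = 0.15, a_int = 0, seasonalAmp = 9, diurnalAmp = 4,
       levelMult = list(soil_8cm = list(diurnal = 0.15, night = 0.5, season = 0.85),
                        air_15cm = list(diurnal = 1.2, night = 1.2, season = 1),
                        air_200cm = list(diurnal = 1, night = 1, season = 1)))
}

# temporal basis over one measurement year of 15-minute steps
temporalBasis <- function(yearStart = "2019-10-12", tz = "Etc/GMT-1") {
  t0 <- as.POSIXct(paste(yearStart, "00:00:00"), tz = tz)
  ts <- t0 + 900 * (0:(365 * 96 - 1))
  lt <- as.POSIXlt(ts)
  doy <- lt$yday + 1
  hour <- lt$hour + lt$min / 60
  list(timestamps = ts,
       season = cos(2 * pi * (doy - 200) / 365),
       diurnal = cos(2 * pi * (hour - 14) / 24),
       night = as.numeric(hour < 6 | hour >= 18),
       doy = doy)
}

siteABC <- function(sites, coefficients, level, allowNA = FALSE) {
  co <- coefficients
  need <- c("Elevation", "DAH", "PRA2m", "SAGAWI")
  miss <- setdiff(need, names(sites))
  if (length(miss)) stop("sites table lacks predictor(s): ",
                         paste(miss, collapse = ", "))
  if (!allowNA && anyNA(sites[need])) stop("missing predictor value at a site")
  lm <- co$levelMult[[level]]
  aInt <- if (is.null(co$a_int)) 0 else co$a_int
  list(A = co$T0 + co$lapse * (sites$Elevation - co$refElev) +
         co$a_dah * sites$DAH + aInt * sites$DAH * sites$PRA2m / 100,
       B = (1 - co$a_buffer * sites$PRA2m / 100) * co$diurnalAmp * lm$diurnal,
       C = co$a_twi * sites$SAGAWI * lm$night,
       seasonAmp = co$seasonalAmp * lm$season)
}

#' Simulate logger series from the generative model
#'
#' One 15-minute [TemperatureSeries-class] per site and level over a full
#' measurement year, with independent per-reading Gaussian noise.
#'
#' @param world a [SyntheticWorld-class] (supplies sites and defaults),
#'   or `NULL` if `sites` carries the predictor columns itself.
#' @param sites site table with `id`, `x`, `y` and predictor columns
#'   `Elevation`, `DAH`, `PRA2m`, `SAGAWI`; default `world@sites`.
#' @param levels measurement levels to simulate.
#' @param coefficients generative coefficients ([defaultCoefficients]).
#' @param noiseSd per-reading noise SD in degC.
#' @param seed RNG seed.
#' @param yearStart first calendar day of the measurement year.
#' @return list of [TemperatureSeries-class], named `<site>_<level>`.
#' @export
simulateLoggers <- function(world = NULL, sites = if (!is.null(world)) world@sites,
                            levels = c("soil_8cm", "air_15cm", "air_200cm"),
                            coefficients = if (!is.null(world)) world@coefficients
                            else defaultCoefficients(),
                            noiseSd = if (!is.null(world)) world@noiseSd else 0.3,
                            seed = 1, yearStart = "2019-10-12") {
  tb <- temporalBasis(yearStart)
  nT <- length(tb$timestamps)
  out <- list()
  withSeed(seed, {
    for (lev in levels) {
      abc <- siteABC(sites, coefficients, lev)
      for (i in seq_len(nrow(sites))) {
        vals <- abc$A[i] + abc$seasonAmp * tb$season +
          abc$B[i] * tb$diurnal - abc$C[i] * tb$night
        if (noiseSd > 0) vals <- vals + stats::rnorm(nT, 0, noiseSd)
        key <- sprintf("%s_%s", sites$id[i], lev)
        out[[key]] <- temperatureSeries(sites$id[i], sprintf("S%s", key), lev,
                                        tb$timestamps, vals)
      }
    }
  })
  out
}

# closed-form annual summaries of the noiseless generative model for
# vectors of per-site/cell A (base level), B (diurnal amplitude),
# C (night depression) and the seasonal amplitude
closedFormSummary <- function(A, B, C, seasonAmp, yearStart = "2019-10-12",
                              variables = c("mean", "max95p", "min5p", "GDD5"),
                              base = 5) {
  tb <- temporalBasis(yearStart)
  prof_d <- tb$diurnal[1:96]; prof_n <- tb$night[1:96]
  seasonDay <- tb$season[seq(1, length(tb$season), by = 96)]
  out <- list()
  P <- outer(B, prof_d) - outer(C, prof_n)   # n x 96 daily profile
  if ("mean" %in% variables)
    out$mean <- A + seasonAmp * mean(tb$season) + B * mean(prof_d) -
      C * mean(prof_n)
  if ("max95p" %in% variables)
    out$max95p <- A + apply(P, 1, max) +
      seasonAmp * unname(stats::quantile(seasonDay, 0.95, type = 7))
  if ("min5p" %in% variables)
    out$min5p <- A + apply(P, 1, min) +
      seasonAmp * unname(stats::quantile(seasonDay, 0.05, type = 7))
  if ("GDD5" %in% variables) {
    g <- numeric(length(A))
    for (d in seq_along(seasonDay)) {
      K <- A - base + seasonAmp * seasonDay[d]
      g <- g + rowSums(pmax(K + P, 0))
    }
    out$GDD5 <- g / 96
  }
  out
}

#' Ground-truth annual summary grids
#'
#' Evaluates the noiseless generative model per cell, in closed form for
#' the mean and by exact evaluation of the repeating daily profile for
#' the extremes and degree days.
#'
#' @param world a [SyntheticWorld-class].
#' @param level measurement level (default `"air_200cm"`).
#' @param variables subset of `c("mean", "max95p", "min5p", "GDD5")`.
#' @param yearStart first day of the measurement year.
#' @return named list of RasterGrids.
#' @export
groundTruthGrids <- function(world, level = "air_200cm",
                             variables = c("mean", "max95p", "min5p", "GDD5"),
                             yearStart = "2019-10-12") {
  st <- world@stack
  ref <- st[["Elevation"]]
  cells <- data.frame(Elevation = as.vector(gridValues(st[["Elevation"]])),
                      DAH = as.vector(gridValues(st[["DAH"]])),
                      PRA2m = as.vector(gridValues(st[["PRA2m"]])),
                      SAGAWI = as.vector(gridValues(st[["SAGAWI"]])))
  abc <- siteABC(cells, world@coefficients, level, allowNA = TRUE)
  ok <- stats::complete.cases(cells)
  cf <- closedFormSummary(abc$A[ok], abc$B[ok], abc$C[ok], abc$seasonAmp,
                          yearStart, variables)
  d <- dim(gridValues(ref))
  lapply(cf, function(v) {
    full <- rep(NA_real_, nrow(cells)); full[ok] <- v
    rasterLike(matrix(full, d[1], d[2]), ref)
  })
}

#' Simulate site-level annual summaries for recovery experiments
#'
#' Closed-form truth of the generative model at the sites plus an
#' independent site-level Gaussian effect: the microsite heterogeneity
#' (soil, understorey, sensor placement) that logger averaging over a
#' year cannot remove. This is the response used in model-recovery and
#' cross-validation calibration experiments.
#'
#' @param world a [SyntheticWorld-class].
#' @param variable one of `"mean"`, `"max95p"`, `"min5p"`, `"GDD5"`.
#' @param level measurement level.
#' @param noiseSd site-level effect SD in degC (default `world@noiseSd`).
#' @param seed RNG seed.
#' @return the world's site table with a `response` column added.
#' @export
simulateSiteSummaries <- function(world, variable = "mean",
                                  level = "air_200cm",
                                  noiseSd = world@noiseSd, seed = 1) {
  sites <- world@sites
  abc <- siteABC(sites, world@coefficients, level)
  cf <- closedFormSummary(abc$A, abc$B, abc$C, abc$seasonAmp,
                          variables = variable)
  sites$response <- cf[[variable]] +
    withSeed(seed, stats::rnorm(nrow(sites), 0, noiseSd))
  sites
}

#' Build a complete synthetic world
#'
#' Terrain, canopy, the full predictor stack (all land-surface and
#' forest-structure predictors), and a stratified site network selected
#' with the sampling module (natural-breaks strata on elevation, heat
#' load and wetness; two draws per stratum plus elevation extremes,
#' topped up at random to `nSites`).
#'
#' @param seed RNG seed; the whole world is reproducible from it.
#' @param n grid side (cells).
#' @param cellSize cell size (m).
#' @param reliefM elevation span (m).
#' @param nSites number of monitoring sites.
#' @param noiseSd per-reading logger noise SD (degC).
#' @param coefficients generative coefficients.
#' @param disturbedFraction areal fraction of disturbed canopy.
#' @param tpiRadii,smoothSigmas passed to the predictor derivation.
#' @return a [SyntheticWorld-class].
#' @export
makeSyntheticWorld <- function(seed = 1, n = 200, cellSize = 5, reliefM = 400,
                               nSites = 150, noiseSd = 0.3,
                               coefficients = defaultCoefficients(),
                               disturbedFraction = 0.3,
                               tpiRadii = c(100, 250, 500),
                               smoothSigmas = c(10, 25)) {
  dtm <- synthTerrain(seed, n = n, cellSize = cellSize, reliefM = reliefM)
  can <- synthCanopy(seed, dtm, disturbedFraction = disturbedFraction)
  terr <- terrainPredictors(dtm, tpiRadii = tpiRadii,
                            smoothSigmas = smoothSigmas)
  struct <- smoothStructure(
    list(Veg_Height = can$Veg_Height, PRA2m = can$PRA2m,
         Conif_Cover = typeCover(can$PRA2m, can$tree_type_fraction)$Conif_Cover,
         Decid_Cover = typeCover(can$PRA2m, can$tree_type_fraction)$Decid_Cover),
    sigmas = smoothSigmas)
  stack <- predictorStack(c(terr, struct))
  # candidate inventory grid covering the whole area except a thin edge
  # ring (2 sigma of the widest smoothing kernel): the site network spans
  # the full mapped domain, as a monitoring network would
  margin <- min(ceiling(2 * max(smoothSigmas) / cellSize), floor(n / 4))
  idx <- seq(margin + 1, n - margin, by = 4)
  cc <- cellCenters(dtm)
  cand <- expand.grid(ri = idx, ci = idx)
  plots <- data.frame(id = sprintf("P%04d", seq_len(nrow(cand))),
                      x = cc$x[cand$ci], y = cc$y[cand$ri])
  pv <- extractAtPoints(stack, plots$x, plots$y, method = "bilinear")
  plots <- cbind(plots, pv)
  plots <- plots[stats::complete.cases(plots), , drop = FALSE]
  plots$elevation <- plots$Elevation
  plots$radiation <- plots$DAH      # heat-load proxy for the radiation axis
  plots$twi <- plots$TWI
  strata <- buildStrata(plots)
  picked <- selectSites(strata, nPerStratum = 2, extremes = 6, seed = seed)
  if (length(picked) < nSites) {
    rest <- setdiff(plots$id, picked)
    extra <- withSeed(seed + 7L,
                      sample(rest, min(nSites - length(picked), length(rest))))
    picked <- c(picked, extra)
  } else if (length(picked) > nSites) {
    picked <- withSeed(seed + 7L, sample(picked, nSites))
  }
  sites <- plots[match(picked, plots$id),
                 c("id", "x", "y", names(stackLayers(stack)))]
  rownames(sites) <- NULL
  new("SyntheticWorld", dtm = dtm, dsm = can$dsm,
      canopy = can[c("PRA2m", "Veg_Height", "returns_total",
                     "returns_above2m", "tree_type_fraction", "disturbed")],
      stack = stack, sites = sites, coefficients = coefficients,
      noiseSd = noiseSd, seed = seed)
}

setMethod("show", "SyntheticWorld", function(object) {
  d <- dim(gridValues(object@dtm))
  cat(sprintf("SyntheticWorld (seed %d): %d x %d cells @ %g m, %d sites\n",
              as.integer(object@seed), d[1], d[2], cellSize(object@dtm),
              nrow(object@sites)))
  cat(sprintf("  elevation %.0f-%.0f m, noise SD %.2f degC\n",
              min(gridValues(object@dtm)), max(gridValues(object@dtm)),
              object@noiseSd))
})

#' @rdname makeSyntheticWorld
#' @param world a [SyntheticWorld-class].
#' @export
setGeneric("worldStack", function(world) standardGeneric("worldStack"))
#' @rdname makeSyntheticWorld
#' @export
setMethod("worldStack", "SyntheticWorld", function(world) world@stack)

#' @rdname makeSyntheticWorld
#' @export
setGeneric("worldSites", function(world) standardGeneric("worldSites"))
#' @rdname makeSyntheticWorld
#' @export
setMethod("worldSites", "SyntheticWorld", function(world) world@sites)
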