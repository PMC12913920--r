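#' Resample a raster with interpolating cubic splines
#'
#' Fits a separable interpolating cubic-spline surface through the source
#' cell centres and samples it at the target cell centres. The surface
#' passes through every source value and reproduces planar ramps exactly,
#' which is the behaviour needed when coarsening fine terrain models
#' (e.g. 1 m to 5 m) without introducing steps.
#'
#' @param r source [RasterGrid-class].
#' @param targetCell target cell size (m), `>=` the source cell size.
#' @return resampled [RasterGrid-class]; extent preserved (target counts
#'   are `floor(extent / targetCell)`).
#' @export
resampleBspline <- function(r, targetCell) {
  stopifnot(is(r, "RasterGrid"))
  if (targetCell < r@cellSize) stop("targetCell must be >= source cell size")
  m <- r@values
  if (all(!is.finite(m))) {
    d <- c(max(1L, floor(nrow(m) * r@cellSize / targetCell)),
           max(1L, floor(ncol(m) * r@cellSize / targetCell)))
    return(rasterGrid(matrix(NA_real_, d[1], d[2]), cellSize = targetCell,
                      xmin = r@xmin, ymax = r@ymax, crs = r@crs))
  }
  src <- cellCenters(r)
  nrT <- max(1L, floor(nrow(m) * r@cellSize / targetCell))
  ncT <- max(1L, floor(ncol(m) * r@cellSize / targetCell))
  xT <- r@xmin + (seq_len(ncT) - 0.5) * targetCell
  yT <- r@ymax - (seq_len(nrT) - 0.5) * targetCell
  # gaps: fill with row/col means for the spline pass, mask afterwards
  mask <- is.finite(m)
  mf <- m
  if (!all(mask)) mf[!mask] <- mean(m[mask])
  # pass 1: resample columns (along x) per source row
  tmp <- t(apply(mf, 1, function(row) {
    if (length(src$x) == 1) return(rep(row, ncT))
    stats::splinefun(src$x, row, method = "fmm")(xT)
  }))
  if (nrow(mf) == 1) tmp <- matrix(tmp, nrow = 1)
  # pass 2: resample rows (along y, increasing coordinate) per column
  tmp2 <- apply(tmp, 2, function(col) {
    if (length(src$y) == 1) return(rep(col, nrT))
    stats::splinefun(rev(src$y), rev(col), method = "fmm")(yT)
  })
  out <- matrix(tmp2, nrow = nrT, ncol = ncT)
  if (!all(mask)) {
    nearestMask <- extractAtPoints(rasterLike(mask * 1, r),
                                   rep(xT, each = nrT), rep(yT, ncT),
                                   method = "nearest")
    out[matrix(nearestMask < 0.5, nrT, ncT)] <- NA_real_
  }
  rasterGrid(out, cellSize = targetCell, xmin = r@xmin, ymax = r@ymax, crs = r@crs)
}

#' Merge overlapping rasters with distance-weighted blending
#'
#' Rasters are merged sequentially from first (highest priority, finest
#' original resolution) to last. Where only one source is valid its value
#' is used; inside a strip of width `blendWidth` along the edge of the
#' higher-priority coverage, the two sources are combined with linear
#' distance weights so no seam appears.
#'
#' @param rasters list of co-registered [RasterGrid-class] objects,
#'   highest priority first.
#' @param blendWidth width of the blend strip in metres.
#' @return merged [RasterGrid-class].
#' @export
mosaicBlend <- function(rasters, blendWidth = 25) {
  stopifnot(length(rasters) >= 1)
  acc <- rasters[[1]]
  for (r in rasters[-1]) {
    if (!isAligned(acc, r)) stop("mosaicBlend requires co-registered rasters")
    a <- acc@values; b <- r@values
    okA <- is.finite(a); okB <- is.finite(b)
    nSteps <- max(1L, ceiling(blendWidth / acc@cellSize))
    dA <- coverageDepth(okA, nSteps)   # cells into A's coverage, capped
    dB <- coverageDepth(okB, nSteps)
    out <- a
    onlyB <- !okA & okB
    out[onlyB] <- b[onlyB]
    both <- okA & okB
    # symmetric linear distance weights inside the strip; pure primary
    # once deeper than the blend width into its own coverage
    w <- ifelse(dA >= nSteps, 1, dA / pmax(dA + dB, 1))
    out[both] <- w[both] * a[both] + (1 - w[both]) * b[both]
    acc <- rasterLike(out, acc)
  }
  acc
}

# Chebyshev distance (in cells) from the nearest cell outside `ok`,
# capped at `cap`; 0 outside the coverage.
coverageDepth <- function(ok, cap) {
  d <- matrix(Inf, nrow(ok), ncol(ok))
  d[!ok] <- 0
  if (all(ok)) return(matrix(cap, nrow(ok), ncol(ok)))
  cur <- !ok
  for (s in seq_len(cap)) {
    cur <- dilate8(cur)
    d[cur & !is.finite(d)] <- s
  }
  d[!is.finite(d)] <- cap
  d
}

# 8-neighbour binary dilation
dilate8 <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  sh <- function(dr, dc) {
    res <- matrix(FALSE, n, m)
    rs <- seq_len(n) + dr; cs <- seq_len(m) + dc
    ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
    res[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
    res
  }
  for (dr in -1:1) for (dc in -1:1) if (dr || dc) out <- out | sh(dr, dc)
  out
}

#' Slope and aspect by second-order polynomial (Evans-Young) fit
#'
#' Fits the local quadratic surface on each 3x3 window and reports slope
#' (degrees) and aspect (degrees clockwise from north, direction of
#' steepest descent). Aspect is `NA` on flat cells; cells without a full
#' 3x3 valid window are `NA` in both outputs.
#'
#' @param dtm a [RasterGrid-class] terrain model.
#' @return list with RasterGrids `slope` and `aspect`.
#' @export
slopeAspect <- function(dtm) {
  z <- dtm@values; g <- dtm@cellSize
  n <- nrow(z); m <- ncol(z)
  sh <- function(dr, dc) {
    out <- matrix(NA_real_, n, m)
    r1 <- max(1, 1 + dr); r2 <- min(n, n + dr)
    c1 <- max(1, 1 + dc); c2 <- min(m, m + dc)
    out[(r1:r2) - dr, (c1:c2) - dc] <- z[r1:r2, c1:c2]
    out
  }
  # rows run north->south: row-1 is the cell to the NORTH
  zNW <- sh(-1, -1); zN <- sh(-1, 0); zNE <- sh(-1, 1)
  zW  <- sh(0, -1);                    zE  <- sh(0, 1)
  zSW <- sh(1, -1);  zS <- sh(1, 0);  zSE <- sh(1, 1)
  p <- (zNE + zE + zSE - zNW - zW - zSW) / (6 * g)   # dz/dx, east+
  q <- (zNW + zN + zNE - zSW - zS - zSE) / (6 * g)   # dz/dy, north+
  slope <- atan(sqrt(p^2 + q^2)) * 180 / pi
  aspect <- (atan2(-p, -q) * 180 / pi) %% 360
  flat <- is.finite(slope) & slope < 1e-9
  aspect[flat] <- NA_real_
  list(slope = rasterLike(slope, dtm), aspect = rasterLike(aspect, dtm))
}

#' Topographic position index
#'
#' Elevation of each cell minus the mean elevation inside a circular
#' window (cell centres within `radius`, focal cell included). Positive
#' on ridges and knolls, negative in depressions and valleys.
#'
#' @param dtm a [RasterGrid-class].
#' @param radius window radius in metres, `>=` the cell size.
#' @return [RasterGrid-class] of TPI values.
#' @export
tpi <- function(dtm, radius) {
  if (radius < dtm@cellSize) stop("radius must be >= cell size")
  rc <- radius / dtm@cellSize
  h <- floor(rc)
  off <- seq(-h, h)
  kern <- outer(off, off, function(a, b) (a^2 + b^2) <= rc^2 + 1e-12) * 1
  mu <- focalFilter(dtm@values, kern, pad = "zero")
  rasterLike(dtm@values - mu, dtm)
}

#' Standardize a TPI raster to unit standard deviation
#'
#' @param x a [RasterGrid-class] (typically TPI at some radius).
#' @return [RasterGrid-class] with SD of valid cells equal to 1.
#' @export
standardizeTpi <- function(x) {
  v <- x@values[is.finite(x@values)]
  if (length(v) < 2) stop("need more than one valid cell")
  s <- stats::sd(v)
  if (s < 1e-12) stop("flat raster: standard deviation is zero")
  rasterLike(x@values / s, x)
}

#' Fill depressions to an epsilon gradient
#'
#' Planchon-Darboux style iterative filling: raises every interior cell
#' to at least the lowest neighbouring filled level plus `eps`, so water
#' routed on the result always has a downhill path to the raster edge.
#'
#' @param dtm a [RasterGrid-class].
#' @param eps minimal elevation drop imposed across filled flats (m).
#' @return filled [RasterGrid-class].
#' @export
fillDepressions <- function(dtm, eps = 1e-5) {
  z <- dtm@values
  n <- nrow(z); m <- ncol(z)
  w <- matrix(Inf, n, m)
  w[1, ] <- z[1, ]; w[n, ] <- z[n, ]; w[, 1] <- z[, 1]; w[, m] <- z[, m]
  w[!is.finite(z)] <- -Inf  # nodata acts as drain
  for (pass in seq_len(100000L)) {
    old <- w
    low <- matrix(Inf, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      if (!dr && !dc) next
      shifted <- matrix(Inf, n, m)
      r1 <- max(1, 1 + dr); r2 <- min(n, n + dr)
      c1 <- max(1, 1 + dc); c2 <- min(m, m + dc)
      shifted[(r1:r2) - dr, (c1:c2) - dc] <- w[r1:r2, c1:c2]
      low <- pmin(low, shifted + eps)
    }
    w <- pmin(w, pmax(z, low), na.rm = FALSE)
    w[!is.finite(z)] <- -Inf
    ch <- which(w != old)
    if (!length(ch)) break
    d <- abs(w - old)[ch]
    if (all(is.finite(d)) && max(d) < eps * 1e-3) break
  }
  w[!is.finite(z)] <- NA_real_
  rasterLike(w, dtm)
}

#' Freeman multiple-flow-direction accumulation
#'
#' Distributes the contributing area of every cell over all lower
#' 8-neighbours with weights proportional to `slope^convergence`
#' (Freeman's multiple flow direction scheme; `convergence = 1` spreads
#' flow widely, larger values concentrate it). Cells are processed in
#' decreasing elevation order; each cell's own area is included.
#'
#' @param dtm a [RasterGrid-class]; depressions should be filled first
#'   (see [fillDepressions]) unless sinks are wanted.
#' @param convergence flow-convergence exponent (default 1.0).
#' @param fill fill depressions before routing? Default TRUE.
#' @return list: `area` [RasterGrid-class] of contributing areas (m^2),
#'   `weights` (internal list), and `terminal` logical matrix marking
#'   cells with no lower in-grid neighbour (outlets and sinks).
#' @export
freemanAccumulation <- function(dtm, convergence = 1.0, fill = TRUE) {
  r <- if (fill) fillDepressions(dtm) else dtm
  z <- r@values; cs <- r@cellSize
  n <- nrow(z); m <- ncol(z)
  cellArea <- cs * cs
  acc <- matrix(cellArea, n, m)
  acc[!is.finite(z)] <- NA_real_
  ord <- order(z, decreasing = TRUE, na.last = NA)
  nbr <- expand.grid(dr = -1:1, dc = -1:1)
  nbr <- nbr[nbr$dr != 0 | nbr$dc != 0, ]
  dist <- sqrt(nbr$dr^2 + nbr$dc^2) * cs
  terminal <- matrix(FALSE, n, m)
  for (idx in ord) {
    rr <- (idx - 1) %% n + 1; cc <- (idx - 1) %/% n + 1
    zi <- z[rr, cc]
    rs <- rr + nbr$dr; csn <- cc + nbr$dc
    ok <- rs >= 1 & rs <= n & csn >= 1 & csn <= m
    w <- numeric(nrow(nbr))
    if (any(ok)) {
      zj <- rep(NA_real_, nrow(nbr))
      zj[ok] <- z[cbind(rs[ok], csn[ok])]
      s <- (zi - zj) / dist
      s[!ok | !is.finite(s) | s <= 0] <- 0
      w <- s^convergence
    }
    tot <- sum(w)
    if (tot <= 0) { terminal[rr, cc] <- TRUE; next }
    w <- w / tot
    give <- acc[rr, cc] * w
    sel <- which(w > 0)
    for (k in sel) acc[rs[k], csn[k]] <- acc[rs[k], csn[k]] + give[k]
  }
  list(area = rasterLike(acc, r), terminal = terminal, filled = r)
}

#' Topographic wetness index
#'
#' `ln(a / tan beta)` with specific contributing area `a` = contributing
#' area / flow width (flow width = cell size) from Freeman routing at
#' convergence 1, and `tan beta` from the Evans-Young slope, floored at
#' `slopeFloor` to keep flats finite.
#'
#' @param dtm a [RasterGrid-class].
#' @param accum optional precomputed result of [freemanAccumulation].
#' @param slopeFloor minimum `tan beta` (default 0.001).
#' @return [RasterGrid-class] of TWI values.
#' @export
twi <- function(dtm, accum = NULL, slopeFloor = 0.001) {
  if (is.null(accum)) accum <- freemanAccumulation(dtm, convergence = 1.0)
  sa <- slopeAspect(dtm)
  tanb <- pmax(tan(sa$slope@values * pi / 180), slopeFloor)
  a <- accum$area@values / dtm@cellSize
  out <- log(a / tanb)
  out[!is.finite(dtm@values)] <- NA_real_
  rasterLike(out, dtm)
}

#' SAGA wetness index
#'
#' A wetness index whose catchment area is iteratively "modified": every
#' pass lets each cell's area rise toward the largest neighbouring
#' modified area damped by `suction^(-tan beta)`, so flat valley floors
#' accumulate wetness from their surroundings (a proxy for cold-air
#' pooling) while steep cells keep their original catchment. The index
#' is `ln(a_mod / tan beta)` and is everywhere `>=` the plain TWI.
#'
#' @param dtm a [RasterGrid-class].
#' @param suction damping strength (default 10; larger = less spread).
#' @param accum optional precomputed [freemanAccumulation] result.
#' @param slopeFloor minimum `tan beta` (default 0.001).
#' @param tol relative convergence tolerance of the iteration.
#' @param maxIter maximum neighbourhood passes.
#' @return [RasterGrid-class]; attribute `converged` reports whether the
#'   iteration met `tol` within `maxIter` passes.
#' @export
sagaWetnessIndex <- function(dtm, suction = 10, accum = NULL,
                             slopeFloor = 0.001, tol = 1e-3, maxIter = 1000) {
  if (is.null(accum)) accum <- freemanAccumulation(dtm, convergence = 1.0)
  sa <- slopeAspect(dtm)
  tanb <- pmax(tan(sa$slope@values * pi / 180), slopeFloor)
  tanb[!is.finite(tanb)] <- slopeFloor
  a <- accum$area@values
  damp <- suction^(-tanb)
  aMod <- a
  n <- nrow(a); m <- ncol(a)
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    nbMax <- matrix(-Inf, n, m)
    for (dr in -1:1) for (dc in -1:1) {
      if (!dr && !dc) next
      shifted <- matrix(-Inf, n, m)
      r1 <- max(1, 1 + dr); r2 <- min(n, n + dr)
      c1 <- max(1, 1 + dc); c2 <- min(m, m + dc)
      shifted[(r1:r2) - dr, (c1:c2) - dc] <- aMod[r1:r2, c1:c2]
      nbMax <- pmax(nbMax, shifted, na.rm = TRUE)
    }
    cand <- pmax(a, nbMax * damp)
    cand[!is.finite(a)] <- NA_real_
    delta <- max(abs(cand - aMod) / pmax(aMod, 1e-12), na.rm = TRUE)
    aMod <- cand
    if (is.finite(delta) && delta < tol) { converged <- TRUE; break }
  }
  if (!converged) warning("SAGA wetness iteration did not converge in ",
                          maxIter, " passes")
  out <- log((aMod / dtm@cellSize) / tanb)
  out[!is.finite(dtm@values)] <- NA_real_
  res <- rasterLike(out, dtm)
  attr(res, "converged") <- converged
  res
}

#' Diurnal anisotropic heating index
#'
#' `DAH = cos(alpha_max - aspect) * arctan(slope)` with the maximum heat
#' surplus fixed at aspect `alpha_max = 202.5` degrees (south-west),
#' slope entering as an angle in radians. Positive on warm south-west
#' slopes, negative on cool north-east slopes, zero on flats.
#'
#' @param slope slope raster in degrees ([RasterGrid-class]).
#' @param aspect aspect raster, degrees clockwise from north; `NA` on
#'   flats (treated as DAH 0).
#' @param alphaMax aspect of maximum heat surplus (degrees, default 202.5).
#' @return [RasterGrid-class] of DAH values in `(-pi/2, pi/2)`.
#' @export
dah <- function(slope, aspect, alphaMax = 202.5) {
  if (!isAligned(slope, aspect)) stop("slope and aspect must be aligned")
  s <- slope@values; a <- aspect@values
  out <- cos((alphaMax - a) * pi / 180) * atan(s * pi / 180)
  out[is.finite(s) & (!is.finite(a) | s < 1e-9)] <- 0
  out[!is.finite(s)] <- NA_real_
  rasterLike(out, slope)
}

#' Gaussian smoothing of a raster
#'
#' Convolution with an isotropic Gaussian kernel of standard deviation
#' `sigma` metres, truncated at 4 sigma and renormalized. Nodata cells
#' are excluded by mask-weighted normalization; edges use whole-point
#' reflection so the raster mean is preserved on fully valid inputs.
#'
#' @param r a [RasterGrid-class].
#' @param sigma kernel standard deviation in metres.
#' @return smoothed [RasterGrid-class].
#' @export
gaussianSmooth <- function(r, sigma) {
  stopifnot(sigma > 0)
  sc <- sigma / r@cellSize
  h <- max(1L, ceiling(4 * sc))
  off <- seq(-h, h)
  k1 <- exp(-off^2 / (2 * sc^2))
  kern <- outer(k1, k1)
  kern <- kern / sum(kern)
  rasterLike(focalFilter(r@values, kern, pad = "reflect"), r)
}

#' Derive the full land-surface predictor set from a terrain model
#'
#' Computes the standard topographic predictor suite at the DTM's
#' resolution: elevation, slope, DAH (raw and Gaussian-smoothed at 10 m
#' and 25 m), standardized TPI at 100/250/500 m radii, TWI and the SAGA
#' wetness index (both from one Freeman accumulation pass).
#'
#' @param dtm a [RasterGrid-class] (typically 5 m).
#' @param tpiRadii TPI window radii in metres.
#' @param smoothSigmas Gaussian SDs (m) for the smoothed DAH variants.
#' @return named list of RasterGrids.
#' @export
terrainPredictors <- function(dtm, tpiRadii = c(100, 250, 500),
                              smoothSigmas = c(10, 25)) {
  sa <- slopeAspect(dtm)
  acc <- freemanAccumulation(dtm, convergence = 1.0)
  out <- list(Elevation = dtm, Slope = sa$slope)
  d0 <- dah(sa$slope, sa$aspect)
  out$DAH <- d0
  for (s in smoothSigmas) out[[sprintf("DAH_g%d", s)]] <- gaussianSmooth(d0, s)
  for (rad in tpiRadii)
    out[[sprintf("TPI_%d", rad)]] <- standardizeTpi(tpi(dtm, rad))
  out$TWI <- twi(dtm, accum = acc)
  out$SAGAWI <- sagaWetnessIndex(dtm, accum = acc)
  out
}
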