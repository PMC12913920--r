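test_that("spline resampling reproduces constants and planes and halves axis counts", {
  cst <- resampleBspline(rasterGrid(matrix(3, 25, 25), cellSize = 1), 5)
  expect_equal(dim(gridValues(cst)), c(5, 5))
  expect_true(all(abs(gridValues(cst) - 3) < 1e-12))

  src <- rasterGrid(outer(1:25, 1:25, function(i, j) 2 * j + 3 * i), cellSize = 1)
  rs <- resampleBspline(src, 5)
  cc <- cellCenters(rs)
  expected <- outer(seq_along(cc$y), seq_along(cc$x), function(i, j)
    2 * (cc$x[j] + 0.5) + 3 * ((25 - cc$y[i]) + 0.5))
  expect_lt(max(abs(gridValues(rs) - expected)), 1e-9)

  allNA <- resampleBspline(rasterGrid(matrix(NA_real_, 10, 10), cellSize = 1), 5)
  expect_true(all(is.na(gridValues(allNA))))
})

test_that("mosaic blending uses linear distance weights in the overlap strip", {
  mk <- function(cols, val) {
    m <- matrix(NA_real_, 5, 20); m[, cols] <- val
    rasterGrid(m, cellSize = 5)
  }
  a <- mk(1:12, 100); b <- mk(8:20, 200)
  mb <- mosaicBlend(list(a, b), blendWidth = 25)
  v <- gridValues(mb)[3, ]
  expect_equal(v[10], 150)              # strip midpoint
  expect_equal(v[5], 100)               # beyond the strip: pure primary
  expect_equal(v[15], 200)              # secondary-only zone
  expect_true(all(diff(v[8:13]) > 0))   # monotone ramp across the seam
  expect_identical(gridValues(mosaicBlend(list(a))), gridValues(a))
})

test_that("Evans-Young slope/aspect handle flats, planes and cones", {
  flat <- slopeAspect(rasterGrid(matrix(5, 9, 9), cellSize = 1))
  expect_true(all(gridValues(flat$slope)[2:8, 2:8] == 0))
  expect_true(all(is.na(gridValues(flat$aspect)[2:8, 2:8])))

  # plane rising east at 45 degrees: downslope due west (270)
  pl <- slopeAspect(rasterGrid(outer(rep(1, 9), 1:9), cellSize = 1))
  expect_equal(gridValues(pl$slope)[5, 5], 45)
  expect_equal(gridValues(pl$aspect)[5, 5], 270)
  expect_true(all(is.na(gridValues(pl$slope)[1, ])))  # no 3x3 support

  # cone apex: aspect sweeps the full circle around it
  n <- 21; ctr <- 11
  cone <- rasterGrid(outer(1:n, 1:n, function(i, j)
    -sqrt((i - ctr)^2 + (j - ctr)^2)), cellSize = 1)
  asp <- gridValues(slopeAspect(cone)$aspect)
  expect_equal(asp[ctr - 5, ctr], 0, tolerance = 1e-6)    # north of apex drains north
  expect_equal(asp[ctr, ctr + 5], 90, tolerance = 1e-6)   # east drains east
  expect_equal(asp[ctr + 5, ctr], 180, tolerance = 1e-6)
  expect_equal(asp[ctr, ctr - 5], 270, tolerance = 1e-6)
})

test_that("TPI is zero on constant rasters, signed on bumps, and tends to z - mean(z)", {
  cst <- tpi(rasterGrid(matrix(4, 15, 15), cellSize = 5), 25)
  expect_lt(max(abs(gridValues(cst))), 1e-10)

  m <- matrix(0, 21, 21); m[11, 11] <- 10
  bump <- tpi(rasterGrid(m, cellSize = 5), 15)
  expect_gt(gridValues(bump)[11, 11], 0)
  expect_lt(gridValues(bump)[11, 12], 0)
  # brute-force window mean at the bump cell
  win <- expand.grid(i = 1:21, j = 1:21)
  win <- win[(win$i - 11)^2 + (win$j - 11)^2 <= 9 + 1e-12, ]
  expect_equal(gridValues(bump)[11, 11],
               10 - mean(m[cbind(win$i, win$j)]), tolerance = 1e-9)

  set.seed(4)
  z <- matrix(rnorm(2500), 50, 50)
  wide <- tpi(rasterGrid(z, cellSize = 5), radius = 1000)
  expect_lt(max(abs(gridValues(wide) - (z - mean(z)))), 1e-9)
})

test_that("TPI standardization yields unit SD and is scale invariant", {
  set.seed(5)
  r <- rasterGrid(matrix(rnorm(100, sd = 3), 10, 10), cellSize = 5)
  s <- standardizeTpi(r)
  expect_equal(sd(gridValues(s)), 1, tolerance = 1e-12)
  s2 <- standardizeTpi(rasterLike(gridValues(r) * 17, r))
  expect_equal(gridValues(s2), gridValues(s), tolerance = 1e-12)
  expect_error(standardizeTpi(rasterGrid(matrix(1, 5, 5))), "zero")
})

test_that("Freeman routing conserves mass and hand-traces on ramps and bowls", {
  # 1-row ramp: contributing area grows linearly downslope
  ramp <- rasterGrid(matrix(10:1, 1, 10), cellSize = 1)
  fa <- freemanAccumulation(ramp, fill = FALSE)
  expect_equal(as.numeric(gridValues(fa$area)), 1:10)

  # bowl with interior pit: the pit drains the entire raster
  n <- 21; ctr <- 11
  bowl <- rasterGrid(outer(1:n, 1:n, function(i, j)
    sqrt((i - ctr)^2 + (j - ctr)^2)), cellSize = 2)
  fb <- freemanAccumulation(bowl, fill = FALSE)
  expect_equal(gridValues(fb$area)[ctr, ctr], n * n * 4)

  # mass conservation on a rough synthetic DTM (50 x 50)
  set.seed(7)
  z <- gridValues(gaussianSmooth(rasterGrid(matrix(rnorm(2500), 50, 50) * 40,
                                            cellSize = 5), 15))
  fa2 <- freemanAccumulation(rasterGrid(z, cellSize = 5))
  tot <- sum(gridValues(fa2$area)[fa2$terminal])
  expect_lt(abs(tot - 2500 * 25) / (2500 * 25), 1e-6)
})

test_that("TWI ranks valleys above slopes and shifts by ln(2) with cell size", {
  w <- smallWorld()
  acc <- freemanAccumulation(w@dtm)
  tw <- twi(w@dtm, accum = acc)
  v <- gridValues(tw)
  # valley cells (high accumulation) are wetter than steep divide cells
  a <- gridValues(acc$area)
  hi <- order(a, decreasing = TRUE)[1:20]
  lo <- order(a)[1:20]
  expect_gt(mean(v[hi], na.rm = TRUE), mean(v[lo], na.rm = TRUE))

  # identical routing topology, doubled cell size: specific area doubles,
  # so TWI shifts by exactly ln(2) wherever slope is defined
  n <- 12
  z1 <- outer(rep(1, n), (n:1) * 0.2)
  r1 <- rasterGrid(z1, cellSize = 1)
  r2 <- rasterGrid(z1 * 2, cellSize = 2)
  t1 <- twi(r1, accum = freemanAccumulation(r1, fill = FALSE))
  t2 <- twi(r2, accum = freemanAccumulation(r2, fill = FALSE))
  mid <- 2:(n - 1)
  expect_equal(gridValues(t2)[mid, mid] - gridValues(t1)[mid, mid],
               matrix(log(2), length(mid), length(mid)), tolerance = 1e-9)

  # flat raster: slope floor keeps TWI finite (edge cells lack 3x3
  # slope support and stay nodata by design)
  fl <- rasterGrid(matrix(5, 6, 6), cellSize = 5)
  tf <- twi(fl, accum = freemanAccumulation(fl))
  expect_true(all(is.finite(gridValues(tf)[2:5, 2:5])))
})

test_that("SAGA wetness index dominates TWI and spreads most on flat valley floors", {
  w <- smallWorld()
  acc <- freemanAccumulation(w@dtm)
  tw <- twi(w@dtm, accum = acc)
  sw <- suppressWarnings(sagaWetnessIndex(w@dtm, accum = acc))
  d <- gridValues(sw) - gridValues(tw)
  expect_true(all(d >= -1e-9, na.rm = TRUE))

  # steep uniform plane: damping kills the spread, SAGAWI ~ TWI
  n <- 15
  plane <- rasterGrid(outer(rep(1, n), n:1) * 5 * tan(30 * pi / 180),
                      cellSize = 5)
  ap <- freemanAccumulation(plane, fill = FALSE)
  dp <- gridValues(sagaWetnessIndex(plane, accum = ap)) -
    gridValues(twi(plane, accum = ap))
  # interior cells, two cells in from the border (edge cells carry the
  # slope floor and are not representative of the plane)
  expect_lt(max(dp[3:(n - 2), 3:(n - 2)], na.rm = TRUE), 0.05)

  # the largest SAGAWI - TWI gap sits in the flattest terrain of the world
  slp <- gridValues(slopeAspect(w@dtm)$slope)
  iMax <- which.max(d)
  expect_lt(slp[iMax], stats::quantile(slp, 1 / 3, na.rm = TRUE))

  # designed valley: steep sides, flat tilted floor -> gap peaks on the floor
  n <- 30
  z <- outer(seq_len(n), seq_len(n), function(i, j)
    pmax(abs(j - 15) - 1, 0) * 4 + i * 0.01)
  vr <- rasterGrid(z, cellSize = 5)
  accv <- freemanAccumulation(vr)
  dv <- gridValues(suppressWarnings(sagaWetnessIndex(vr, accum = accv))) -
    gridValues(twi(vr, accum = accv))
  colMax <- (which.max(dv) - 1) %/% n + 1
  expect_true(colMax %in% 14:16)
})

test_that("DAH geometry: value, antisymmetry, range and argmax at 202.5 degrees", {
  s45 <- rasterGrid(matrix(45, 2, 2))
  expect_equal(gridValues(dah(s45, rasterGrid(matrix(202.5, 2, 2))))[1, 1],
               atan(pi / 4), tolerance = 1e-9)
  expect_equal(gridValues(dah(s45, rasterGrid(matrix(22.5, 2, 2))))[1, 1],
               -atan(pi / 4), tolerance = 1e-9)
  expect_true(all(gridValues(dah(rasterGrid(matrix(0, 3, 3)),
                                 rasterGrid(matrix(100, 3, 3)))) == 0))

  aspects <- seq(0, 359.9, by = 0.1)
  v <- cos((202.5 - aspects) * pi / 180) * atan(30 * pi / 180)
  asp <- rasterGrid(matrix(aspects, 1))
  slp <- rasterGrid(matrix(30, 1, length(aspects)))
  dv <- as.numeric(gridValues(dah(slp, asp)))
  expect_equal(dv, v, tolerance = 1e-12)
  expect_equal(aspects[which.max(dv)], 202.5)
  expect_true(all(dv > -pi / 2 & dv < pi / 2))
  # sign flips under reflection about the 202.5/22.5 axis
  refl <- (2 * 202.5 - aspects + 180) %% 360
  dr <- as.numeric(gridValues(dah(slp, rasterGrid(matrix(refl, 1)))))
  expect_equal(dr, -dv, tolerance = 1e-9)
})

test_that("Gaussian smoothing preserves constants, kernels and the raster mean", {
  cst <- gaussianSmooth(rasterGrid(matrix(7, 20, 20), cellSize = 5), 25)
  expect_lt(max(abs(gridValues(cst) - 7)), 1e-12)

  m <- matrix(0, 31, 31); m[16, 16] <- 1
  im <- gaussianSmooth(rasterGrid(m, cellSize = 5), 10)
  v <- gridValues(im)
  expect_equal(sum(v), 1, tolerance = 1e-9)
  expect_equal(v[16, 18], v[16, 14], tolerance = 1e-12)  # isotropy
  expect_equal(v[16, 18] / v[16, 16], exp(-0.5), tolerance = 1e-6) # 2 cells, sigma = 2 cells

  set.seed(8)
  r <- rasterGrid(matrix(rnorm(400), 20, 20), cellSize = 5)
  sm <- gaussianSmooth(r, 25)
  expect_equal(mean(gridValues(sm)), mean(gridValues(r)), tolerance = 1e-9)
})
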