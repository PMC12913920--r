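test_that("synthetic terrain is reproducible, spans the requested relief and can be flat", {
  a <- synthTerrain(3, n = 60, reliefM = 300)
  b <- synthTerrain(3, n = 60, reliefM = 300)
  expect_identical(gridValues(a), gridValues(b))
  expect_equal(diff(range(gridValues(a))), 300, tolerance = 300 * 0.05)
  expect_false(identical(gridValues(synthTerrain(4, n = 60, reliefM = 300)),
                         gridValues(a)))
  flat <- synthTerrain(3, n = 20, reliefM = 0)
  expect_equal(diff(range(gridValues(flat))), 0)
})

test_that("synthetic canopy respects ranges, patch fraction and DSM >= DTM", {
  dtm <- synthTerrain(5, n = 80)
  can <- synthCanopy(5, dtm, disturbedFraction = 0.3)
  pra <- gridValues(can$PRA2m)
  expect_true(all(pra >= 0 & pra <= 100))
  expect_equal(mean(gridValues(can$disturbed)), 0.3, tolerance = 0.05)
  expect_true(all(gridValues(can$dsm) >= gridValues(dtm)))
  expect_true(all(gridValues(can$returns_above2m) <=
                    gridValues(can$returns_total)))
  f <- gridValues(can$tree_type_fraction)
  expect_true(all(f >= 0 & f <= 1))
})

test_that("simulated loggers are seeded and reduce to the stated additive structure", {
  w <- smallWorld()
  s <- worldSites(w)[1:6, ]
  l1 <- simulateLoggers(world = w, sites = s, levels = "air_200cm", seed = 9)
  l2 <- simulateLoggers(world = w, sites = s, levels = "air_200cm", seed = 9)
  expect_identical(l1[[1]]@values, l2[[1]]@values)

  # lapse only: annual mean exactly linear in elevation
  co <- defaultCoefficients()
  co$a_dah <- 0; co$a_buffer <- 0; co$a_twi <- 0
  lg <- simulateLoggers(world = w, sites = s, levels = "air_200cm",
                        coefficients = co, noiseSd = 0, seed = 9)
  means <- vapply(lg, annualMean, numeric(1))
  fit <- lm(means ~ s$Elevation)
  r2 <- 1 - sum(residuals(fit)^2) / sum((means - mean(means))^2)
  expect_gt(r2, 1 - 1e-12)
  expect_equal(unname(coef(fit)[2]), co$lapse, tolerance = 1e-9)

  # full canopy buffering kills the diurnal cycle: smallest daily range
  sB <- s[1:3, ]
  sB$Elevation <- 800; sB$DAH <- 0; sB$SAGAWI <- 5
  sB$PRA2m <- c(100, 50, 0)
  coB <- defaultCoefficients(); coB$a_buffer <- 1
  lgB <- simulateLoggers(world = NULL, sites = sB, levels = "air_200cm",
                         coefficients = coB, noiseSd = 0, seed = 2)
  spread <- vapply(lgB, function(x) {
    da <- dailyAggregate(x)
    percentileExtreme(da, "max95p") - percentileExtreme(da, "min5p")
  }, numeric(1))
  expect_true(all(diff(spread) > 0))   # more canopy -> narrower extremes

  sMiss <- sB; sMiss$SAGAWI <- NULL
  expect_error(simulateLoggers(world = NULL, sites = sMiss,
                               coefficients = coB), "SAGAWI")
})

test_that("ground-truth grids match pipeline summaries of noiseless loggers", {
  w <- smallWorld()
  gt <- groundTruthGrids(w, level = "air_15cm",
                         variables = c("mean", "max95p", "min5p"))
  s <- worldSites(w)[c(2, 9), ]
  # evaluate truth at the site cells (sites sit on cell centres)
  tMean <- extractAtPoints(gt$mean, s$x, s$y, method = "nearest")
  tMax <- extractAtPoints(gt$max95p, s$x, s$y, method = "nearest")
  tMin <- extractAtPoints(gt$min5p, s$x, s$y, method = "nearest")
  lg <- simulateLoggers(world = w, sites = s, levels = "air_15cm",
                        noiseSd = 0, seed = 7)
  for (i in 1:2) {
    su <- summarizeSite(lg[i])
    expect_equal(su$value[su$variable == "T.air_15_cm.mean"], tMean[i],
                 tolerance = 1e-6)
    expect_equal(su$value[su$variable == "T.air_15_cm.max.95p"], tMax[i],
                 tolerance = 1e-6)
    expect_equal(su$value[su$variable == "T.air_15_cm.min.5p"], tMin[i],
                 tolerance = 1e-6)
  }

  # lapse-only world: the mean grid is linear in elevation
  co <- defaultCoefficients(); co$a_dah <- 0; co$a_buffer <- 0; co$a_twi <- 0
  w2 <- new("SyntheticWorld", dtm = w@dtm, dsm = w@dsm, canopy = w@canopy,
            stack = w@stack, sites = w@sites, coefficients = co,
            noiseSd = 0, seed = w@seed)
  gt2 <- groundTruthGrids(w2, variables = "mean")
  ok <- is.finite(gridValues(gt2$mean))
  yv <- as.vector(gridValues(gt2$mean))[ok]
  fit <- lm(yv ~ as.vector(gridValues(w@stack[["Elevation"]]))[ok])
  r2 <- 1 - sum(residuals(fit)^2) / sum((yv - mean(yv))^2)
  expect_gt(r2, 1 - 1e-12)

  gdd <- groundTruthGrids(w, variables = "GDD5")$GDD5
  expect_true(all(gridValues(gdd) >= 0, na.rm = TRUE))
})

test_that("site-summary simulation adds exactly the site-level effect", {
  w <- smallWorld()
  d0 <- simulateSiteSummaries(w, noiseSd = 0, seed = 1)
  d1 <- simulateSiteSummaries(w, noiseSd = 0.3, seed = 1)
  expect_equal(mean(d1$response - d0$response), 0, tolerance = 0.15)
  expect_gt(sd(d1$response - d0$response), 0.18)
  expect_lt(sd(d1$response - d0$response), 0.42)
  expect_identical(simulateSiteSummaries(w, seed = 5)$response,
                   simulateSiteSummaries(w, seed = 5)$response)
})

test_that("worlds are reproducible bit for bit from their seed", {
  w1 <- suppressWarnings(makeSyntheticWorld(seed = 8, n = 50, nSites = 35,
                                            tpiRadii = c(50, 100)))
  w2 <- suppressWarnings(makeSyntheticWorld(seed = 8, n = 50, nSites = 35,
                                            tpiRadii = c(50, 100)))
  expect_identical(gridValues(w1@dtm), gridValues(w2@dtm))
  expect_identical(worldSites(w1), worldSites(w2))
  expect_identical(gridValues(w1@canopy$PRA2m), gridValues(w2@canopy$PRA2m))
})
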