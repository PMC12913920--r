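test_that("co-location offsets match the mean-of-others definition", {
  mk <- function(id, off) makeSeries(rep(10 + off, 97), sensor = id)
  offs <- computeOffsets(list(mk("a", 0.2), mk("b", -0.1), mk("c", -0.1)))
  expect_equal(offs$offset_C, c(0.30, -0.15, -0.15), tolerance = 1e-12)

  same <- computeOffsets(list(mk("a", 0), mk("b", 0), mk("c", 0)))
  expect_equal(same$offset_C, c(0, 0, 0))

  expect_error(computeOffsets(list(mk("a", 0), mk("b", 0))), "at least 3")
  short <- lapply(c("a", "b", "c"), function(id)
    makeSeries(rep(10, 8), sensor = id))
  expect_error(computeOffsets(short), "24 hours")
})

test_that("calibration shifts ok readings only and round-trips exactly", {
  s <- makeSeries(rep(10, 96))
  cal <- data.frame(sensor_id = "sn1", offset_C = 0.3)
  c1 <- applyCalibration(s, cal)
  expect_true(all(c1@values == 9.7))
  ident <- applyCalibration(s, data.frame(sensor_id = "sn1", offset_C = 0))
  expect_identical(ident@values, s@values)
  back <- applyCalibration(c1, data.frame(sensor_id = "sn1", offset_C = -0.3))
  expect_identical(back@values, s@values)
  expect_error(applyCalibration(s, data.frame(sensor_id = "zz", offset_C = 1)),
               "not found")
})

test_that("QC screen flags range violations and week-long flatlines", {
  raw <- makeSeries(c(rep(10, 40), 12, rep(10, 55)))
  raw@values[20] <- 85
  scr <- qcScreen(raw)
  expect_false(scr@qcOk[20])
  expect_equal(sum(!scr@qcOk), 1)

  # 8-day constant segment inside a varying year
  n <- 12 * 96
  vals <- 10 + sin(2 * pi * seq_len(n) / 96)
  vals[1000:(1000 + 8 * 96)] <- 4
  flat <- qcScreen(makeSeries(vals))
  expect_true(all(!flat@qcOk[1000:(1000 + 8 * 96)]))
  expect_true(all(flat@qcOk[1:999]))

  clean <- qcScreen(makeSeries(10 + sin(2 * pi * seq_len(n) / 96)))
  expect_equal(sum(!clean@qcOk), 0)
})

test_that("daily aggregation reports min/max/mean at sampled instants with completeness rule", {
  cst <- dailyAggregate(makeSeries(rep(12, 96)))
  expect_equal(nrow(cst), 1)
  expect_equal(cst$daily_min, 12); expect_equal(cst$daily_max, 12)
  expect_equal(cst$daily_mean, 12); expect_equal(cst$n_readings, 96L)

  sinu <- dailyAggregate(makeSeries(10 + 5 * sin(2 * pi * (0:95) / 96)))
  expect_equal(sinu$daily_min, 5)
  expect_equal(sinu$daily_max, 15)

  sparse <- makeSeries(rep(10, 96))
  sparse@values[51:96] <- NA          # 50 readings left, threshold 90%
  expect_equal(nrow(dailyAggregate(sparse)), 0)
  expect_equal(nrow(dailyAggregate(makeSeries(numeric(0)))), 0)
})

test_that("annual mean averages the measurement year and enforces coverage", {
  expect_equal(annualMean(yearSeries(7)), 7)
  half <- makeSeries(c(rep(0, 183 * 96), rep(10, 182 * 96)))
  expect_equal(annualMean(half), mean(half@values))
  gappy <- yearSeries(7)
  gappy@values[1:(96 * 100)] <- NA    # 100 missing days > 10%
  expect_error(annualMean(gappy), "coverage", ignore.case = TRUE)
})

test_that("percentile extremes follow the type-7 rule and match a sort-based oracle", {
  mk <- function(mx, mn = mx) data.frame(day = seq_along(mx), daily_min = mn,
                                         daily_max = mx, daily_mean = mx,
                                         n_readings = 96L)
  expect_equal(percentileExtreme(mk(rep(20, 365)), "max95p"), 20)
  expect_equal(percentileExtreme(mk(1:365), "max95p"), 346.8)
  expect_equal(percentileExtreme(mk(rep(0, 365), 1:365), "min5p"), 19.2)
  expect_error(percentileExtreme(mk(1:10), "max95p"), "qualifying days")

  set.seed(11)
  for (n in c(31, 100, 400)) {
    x <- rnorm(n)
    expect_equal(percentileExtreme(mk(x), "max95p"), sortQuantile(x, 0.95),
                 tolerance = 1e-12)
    expect_equal(percentileExtreme(mk(rep(0, n), x), "min5p"),
                 sortQuantile(x, 0.05), tolerance = 1e-12)
  }
})

test_that("growing degree days integrate the excess above 5 degC", {
  day15 <- makeSeries(rep(15, 96))
  expect_equal(gdd5(day15, minCoverage = 0), 10)
  expect_equal(gdd5(makeSeries(rep(5, 96)), minCoverage = 0), 0)
  mixed <- makeSeries(c(rep(25, 48), rep(-5, 48)))
  expect_equal(gdd5(mixed, minCoverage = 0), 10)
  # monotone under pointwise temperature increase
  set.seed(12)
  base <- yearSeries(0); base@values <- rnorm(365 * 96, 8, 6)
  warmer <- base; warmer@values <- base@values + 0.5
  expect_gte(gdd5(warmer), gdd5(base))
})

test_that("site summaries produce 9 / 4 / 1 variables by level set and order extremes sanely", {
  w <- smallWorld()
  s1 <- worldSites(w)[1, ]
  lg <- simulateLoggers(world = w, sites = s1, noiseSd = 0, seed = 3)
  nine <- summarizeSite(lg)
  expect_equal(nrow(nine), 9)
  expect_setequal(nine$variable, c(
    "T.soil_8_cm.mean", "T.air_15_cm.mean", "T.air_15_cm.max.95p",
    "T.air_15_cm.min.5p", "T.air_15_cm.GDD5", "T.air_200_cm.mean",
    "T.air_200_cm.max.95p", "T.air_200_cm.min.5p", "T.air_200_cm.GDD5"))
  four <- summarizeSite(lg[grep("air_200cm", names(lg))])
  expect_equal(nrow(four), 4)
  one <- summarizeSite(lg[grep("soil_8cm", names(lg))])
  expect_equal(nrow(one), 1)

  for (lev in c("air_15_cm", "air_200_cm")) {
    g <- function(v) nine$value[nine$variable == sprintf("T.%s.%s", lev, v)]
    expect_lte(g("min.5p"), g("mean"))
    expect_lte(g("mean"), g("max.95p"))
  }
})

test_that("logger CSV round-trips into series", {
  p <- tempfile(fileext = ".csv")
  t0 <- as.POSIXct("2019-10-12 00:00:00", tz = "Etc/GMT-1")
  df <- data.frame(site_id = "A", sensor_id = "s1", level = "air_200cm",
                   timestamp = format(t0 + 900 * (0:9), "%Y-%m-%dT%H:%M:%S"),
                   temperature_C = 1:10)
  write.csv(df, p, row.names = FALSE)
  ser <- readLoggerCsv(p)
  expect_length(ser, 1)
  expect_equal(ser[[1]]@values, as.numeric(1:10))
  expect_equal(as.numeric(diff(ser[[1]]@timestamps)[1], units = "secs"), 900)
  unlink(p)
})
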