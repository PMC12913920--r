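# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

# Default-size synthetic world (200 x 200 @ 5 m, 150 sites) used by the
# recovery, CV and interaction experiments.
defaultWorld <- function(seed = 1, a_int = 0) {
  key <- sprintf("world_%d_%g", seed, a_int)
  if (is.null(.fixtures[[key]])) {
    co <- defaultCoefficients()
    co$a_int <- a_int
    .fixtures[[key]] <- suppressWarnings(
      makeSyntheticWorld(seed = seed, coefficients = co))
  }
  .fixtures[[key]]
}

# Smaller world for unit-level checks.
smallWorld <- function(seed = 2) {
  key <- sprintf("small_%d", seed)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- suppressWarnings(
      makeSyntheticWorld(seed = seed, n = 60, nSites = 50,
                         tpiRadii = c(50, 100), reliefM = 400))
  }
  .fixtures[[key]]
}

recoveryPredictors <- function() {
  c("Elevation", "DAH", "SAGAWI", "TWI", "TPI_500", "Slope",
    "PRA2m", "Veg_Height")
}

defaultFolds <- function(world) {
  s <- worldSites(world)
  allocateFolds(hexAssign(s$x, s$y, 150), k = 10, seed = 1)
}

# A one-day or multi-day 15-minute series starting Oct 12 2019, UTC+1.
makeSeries <- function(values, level = "air_200cm", site = "S1",
                       sensor = "sn1", start = "2019-10-12 00:00:00") {
  t0 <- as.POSIXct(start, tz = "Etc/GMT-1")
  temperatureSeries(site, sensor, level, t0 + 900 * (seq_along(values) - 1),
                    values)
}

# Full-year constant series (365 * 96 readings).
yearSeries <- function(value, level = "air_200cm") {
  makeSeries(rep(value, 365 * 96), level = level)
}

# type-7 quantile by explicit sorting (independent oracle).
sortQuantile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
}

# Exhaustive Fisher-Jenks oracle: enumerate all contiguous partitions.
bruteJenks <- function(values, k) {
  xs <- sort(values)
  n <- length(xs)
  ssd <- function(v) sum((v - mean(v))^2)
  best <- Inf
  splits <- utils::combn(n - 1, k - 1)
  if (k == 1) return(ssd(xs))
  for (j in seq_len(ncol(splits))) {
    cuts <- c(0, splits[, j], n)
    tot <- sum(vapply(seq_len(k), function(i)
      ssd(xs[(cuts[i] + 1):cuts[i + 1]]), numeric(1)))
    best <- min(best, tot)
  }
  best
}
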