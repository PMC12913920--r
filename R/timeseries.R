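#' Construct a temperature series
#'
#' @param siteId,sensorId identifiers.
#' @param level `"soil_8cm"`, `"air_15cm"` or `"air_200cm"`.
#' @param timestamps POSIXct at a strict 15-minute step. Use a fixed
#'   offset zone (default convention here is UTC+1, no daylight saving)
#'   so calendar days are stable.
#' @param values temperatures in degrees Celsius.
#' @param qcOk logical usability flags (default all `TRUE`).
#' @return a [TemperatureSeries-class].
#' @export
temperatureSeries <- function(siteId, sensorId, level, timestamps, values,
                              qcOk = rep(TRUE, length(values))) {
  new("TemperatureSeries", siteId = as.character(siteId),
      sensorId = as.character(sensorId), level = level,
      timestamps = timestamps, values = as.numeric(values), qcOk = qcOk)
}

setMethod("show", "TemperatureSeries", function(object) {
  cat(sprintf("TemperatureSeries %s/%s [%s]: %d readings, %d flagged\n",
              object@siteId, object@sensorId, object@level,
              length(object@values), sum(!object@qcOk)))
  if (length(object@timestamps))
    cat(sprintf("  %s .. %s\n", format(min(object@timestamps)),
                format(max(object@timestamps))))
})

#' @export
setMethod("length", "TemperatureSeries", function(x) length(x@values))

okValues <- function(series) {
  ifelse(series@qcOk, series@values, NA_real_)
}

#' Sensor offsets from a co-location experiment
#'
#' Sensors measured together in a controlled environment for at least a
#' day each get a fixed offset: the mean, over the shared instants, of
#' the focal sensor's reading minus the mean of all *other* sensors at
#' that instant. Subtracting these offsets removes systematic sensor
#' bias; by construction the offsets of the group sum to ~0.
#'
#' @param group list of [TemperatureSeries-class] measured together.
#' @param minHours minimum shared time span in hours (default 24).
#' @return data.frame with `sensor_id` and `offset_C`.
#' @export
computeOffsets <- function(group, minHours = 24) {
  if (length(group) < 3)
    stop("need at least 3 co-located sensors (mean of others is degenerate)")
  common <- Reduce(intersect, lapply(group, function(s)
    as.numeric(s@timestamps)[s@qcOk & is.finite(s@values)]))
  if (length(common) < 2 ||
      (max(common) - min(common)) < minHours * 3600)
    stop("shared measurement span is shorter than ", minHours, " hours")
  X <- vapply(group, function(s) {
    s@values[match(common, as.numeric(s@timestamps))]
  }, numeric(length(common)))
  rowTot <- rowSums(X); k <- ncol(X)
  offs <- vapply(seq_len(k), function(i) {
    others <- (rowTot - X[, i]) / (k - 1)
    mean(X[, i] - others)
  }, numeric(1))
  if (any(abs(offs) >= 1.0))
    warning("offset(s) exceed 1 degC; check the calibration group")
  data.frame(sensor_id = vapply(group, function(s) s@sensorId, character(1)),
             offset_C = offs, stringsAsFactors = FALSE)
}

#' Apply a sensor calibration offset
#'
#' Subtracts the sensor's fixed offset from every usable reading; flags
#' are untouched. Applying the negated offset afterwards restores the
#' series exactly.
#'
#' @param series a [TemperatureSeries-class].
#' @param calibration one-row data.frame (`sensor_id`, `offset_C`) or the
#'   full calibration table (the matching row is used).
#' @return calibrated [TemperatureSeries-class].
#' @export
applyCalibration <- function(series, calibration) {
  row <- calibration[calibration$sensor_id == series@sensorId, , drop = FALSE]
  if (nrow(row) != 1)
    stop("calibration for sensor '", series@sensorId, "' not found (or duplicated)")
  out <- series
  adj <- series@values
  adj[series@qcOk] <- adj[series@qcOk] - row$offset_C
  out@values <- adj
  out
}

#' Automated quality screen
#'
#' Deterministic surrogate for visual inspection: readings outside the
#' physically plausible range and runs of identical readings longer than
#' `flatlineN` consecutive steps (default 672 = 7 days at 15 minutes,
#' the signature of a failed or buried sensor) are flagged removed.
#'
#' @param series a [TemperatureSeries-class].
#' @param range plausible range in degC (default `c(-45, 60)`).
#' @param flatlineN runs strictly longer than this are removed.
#' @return the series with updated flags.
#' @export
qcScreen <- function(series, range = c(-45, 60), flatlineN = 672) {
  v <- series@values
  bad <- is.finite(v) & (v < range[1] | v > range[2])
  if (length(v) > flatlineN) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    for (j in which(r$lengths > flatlineN & !is.na(r$values))) {
      bad[(ends[j] - r$lengths[j] + 1):ends[j]] <- TRUE
    }
  }
  out <- series
  out@qcOk <- series@qcOk & !bad
  out
}

#' Daily aggregation of a calibrated series
#'
#' One row per calendar day (fixed-offset local time; the timestamps'
#' own zone is used, so build series in e.g. `Etc/GMT-1` for UTC+1 days)
#' that reaches the completeness threshold.
#'
#' @param series a [TemperatureSeries-class].
#' @param completeness minimum fraction of the 96 daily readings present
#'   (default 0.9).
#' @return data.frame: `day` (Date), `daily_min`, `daily_max`,
#'   `daily_mean`, `n_readings`.
#' @export
dailyAggregate <- function(series, completeness = 0.9) {
  v <- okValues(series)
  keep <- is.finite(v)
  if (!any(keep))
    return(data.frame(day = as.Date(character(0)), daily_min = numeric(0),
                      daily_max = numeric(0), daily_mean = numeric(0),
                      n_readings = integer(0)))
  day <- as.Date(series@timestamps, tz = attr(series@timestamps, "tzone")[1])
  d <- day[keep]; x <- v[keep]
  mins <- tapply(x, d, min); maxs <- tapply(x, d, max)
  means <- tapply(x, d, mean); ns <- tapply(x, d, length)
  out <- data.frame(day = as.Date(names(mins)),
                    daily_min = as.numeric(mins), daily_max = as.numeric(maxs),
                    daily_mean = as.numeric(means), n_readings = as.integer(ns))
  out[out$n_readings >= ceiling(completeness * 96), , drop = FALSE]
}

measurementWindow <- function(series) {
  start <- min(series@timestamps)
  c(start, start + 365 * 86400)
}

#' Annual mean temperature
#'
#' Arithmetic mean of all usable readings in the measurement year (first
#' timestamp + 365 days). Refuses when day coverage falls below the
#' threshold, reporting the observed coverage.
#'
#' @param series a [TemperatureSeries-class].
#' @param minCoverage minimum fraction of the 365 days with any usable
#'   reading (default 0.9).
#' @return mean temperature in degC.
#' @export
annualMean <- function(series, minCoverage = 0.9) {
  w <- measurementWindow(series)
  sel <- series@timestamps >= w[1] & series@timestamps < w[2]
  v <- okValues(series)[sel]
  days <- unique(as.Date(series@timestamps[sel][is.finite(v)],
                         tz = attr(series@timestamps, "tzone")[1]))
  cov <- length(days) / 365
  if (cov < minCoverage)
    stop(sprintf("coverage %.1f%% of the measurement year is below the %.0f%% threshold",
                 100 * cov, 100 * minCoverage))
  mean(v[is.finite(v)])
}

#' Percentile-based annual temperature extremes
#'
#' The 95th percentile of daily maxima (`"max95p"`) or the 5th percentile
#' of daily minima (`"min5p"`), using the linear-interpolation (type 7)
#' quantile definition. Robust to single-day outliers.
#'
#' @param daily output of [dailyAggregate].
#' @param which `"max95p"` or `"min5p"`.
#' @param minDays minimum number of qualifying days (default 30).
#' @return temperature in degC.
#' @export
percentileExtreme <- function(daily, which = c("max95p", "min5p"), minDays = 30) {
  which <- match.arg(which)
  if (nrow(daily) < minDays)
    stop("only ", nrow(daily), " qualifying days; need at least ", minDays)
  if (which == "max95p")
    unname(stats::quantile(daily$daily_max, 0.95, type = 7))
  else
    unname(stats::quantile(daily$daily_min, 0.05, type = 7))
}

#' Growing degree days above 5 degC
#'
#' `sum(max(0, T - 5)) / 96` over the measurement year: the integral of
#' the temperature excess above 5 degC expressed in degC-days for a
#' 15-minute series (96 readings per day).
#'
#' @param series a [TemperatureSeries-class].
#' @param base base temperature (degC, default 5).
#' @param minCoverage coverage threshold shared with [annualMean].
#' @return growing degree days (degC d).
#' @export
gdd5 <- function(series, base = 5, minCoverage = 0.9) {
  w <- measurementWindow(series)
  sel <- series@timestamps >= w[1] & series@timestamps < w[2]
  v <- okValues(series)[sel]
  days <- unique(as.Date(series@timestamps[sel][is.finite(v)],
                         tz = attr(series@timestamps, "tzone")[1]))
  if (length(days) / 365 < minCoverage)
    stop(sprintf("coverage %.1f%% below the %.0f%% threshold",
                 100 * length(days) / 365, 100 * minCoverage))
  sum(pmax(0, v[is.finite(v)] - base)) / 96
}

#' The nine annual microclimate variables of a site
#'
#' For soil (-8 cm): the annual mean. For each air level (15 cm and
#' 200 cm): mean, 95th percentile of daily maxima, 5th percentile of
#' daily minima, and growing degree days above 5 degC. A site with all
#' three levels yields exactly nine variables.
#'
#' @param seriesList list of [TemperatureSeries-class] for one site
#'   (one per level).
#' @param minCoverage year-coverage threshold.
#' @param completeness daily completeness threshold.
#' @return data.frame: `site_id`, `variable`, `value`, `n_days_used`.
#' @export
summarizeSite <- function(seriesList, minCoverage = 0.9, completeness = 0.9) {
  stopifnot(length(seriesList) >= 1)
  siteId <- seriesList[[1]]@siteId
  rows <- list()
  add <- function(variable, value, nDays)
    rows[[length(rows) + 1]] <<- data.frame(
      site_id = siteId, variable = variable, value = value,
      n_days_used = nDays, stringsAsFactors = FALSE)
  levelTag <- c(soil_8cm = "soil_8_cm", air_15cm = "air_15_cm",
                air_200cm = "air_200_cm")
  for (s in seriesList) {
    tag <- levelTag[[s@level]]
    daily <- dailyAggregate(s, completeness = completeness)
    nDays <- nrow(daily)
    add(sprintf("T.%s.mean", tag), annualMean(s, minCoverage), nDays)
    if (s@level != "soil_8cm") {
      add(sprintf("T.%s.max.95p", tag),
          percentileExtreme(daily, "max95p"), nDays)
      add(sprintf("T.%s.min.5p", tag),
          percentileExtreme(daily, "min5p"), nDays)
      add(sprintf("T.%s.GDD5", tag), gdd5(s, minCoverage = minCoverage), nDays)
    }
  }
  do.call(rbind, rows)
}

#' Read logger series from a long-format CSV
#'
#' Expected columns: `site_id`, `sensor_id`, `level`, `timestamp`
#' (ISO-8601), `temperature_C`. One series is built per
#' (site, sensor, level) combination.
#'
#' @param path CSV path.
#' @param tz fixed-offset time zone for the calendar (default
#'   `"Etc/GMT-1"`, i.e. UTC+1 without daylight saving).
#' @return list of [TemperatureSeries-class].
#' @export
readLoggerCsv <- function(path, tz = "Etc/GMT-1") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("site_id", "sensor_id", "level", "timestamp", "temperature_C")
  if (!all(need %in% names(df)))
    stop("logger CSV must have columns: ", paste(need, collapse = ", "))
  key <- interaction(df$site_id, df$sensor_id, df$level, drop = TRUE)
  lapply(split(df, key), function(d) {
    ts <- as.POSIXct(d$timestamp, tz = tz,
                     tryFormats = c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S"))
    o <- order(ts)
    temperatureSeries(d$site_id[1], d$sensor_id[1], d$level[1],
                      ts[o], d$temperature_C[o])
  })
}

#' Write site summaries to a tidy CSV
#' @param summaries data.frame from [summarizeSite] (possibly row-bound
#'   over sites).
#' @param path output path.
#' @export
writeSummaryCsv <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE)
  invisible(path)
}
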