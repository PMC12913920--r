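#' Fisher-Jenks natural-breaks classification
#'
#' Exact dynamic-programming optimum: partitions sorted values into `k`
#' contiguous classes minimising the total within-class sum of squared
#' deviations from the class means. Ties between optimal partitions are
#' broken toward the lowest first break. Intervals are left-closed,
#' right-open except the last.
#'
#' @param values numeric vector (at least `k` distinct values).
#' @param k number of classes.
#' @return list: `breaks` (length `k + 1`, outer limits included),
#'   `classes` (class index per input value) and `ssd` (the optimal
#'   objective).
#' @export
fisherJenks <- function(values, k) {
  stopifnot(k >= 1)
  x <- sort(unique(values))
  if (length(x) < k) stop("k exceeds the number of distinct values")
  xs <- sort(values)
  n <- length(xs)
  cs <- cumsum(xs); cs2 <- cumsum(xs^2)
  sse <- function(i, j) { # xs[i..j]
    s <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - s^2 / (j - i + 1)
  }
  # D[c, j]: optimal SSD for first j obs in c classes; B[c, j]: start of last class
  D <- matrix(Inf, k, n); B <- matrix(NA_integer_, k, n)
  for (j in seq_len(n)) { D[1, j] <- sse(1, j); B[1, j] <- 1L }
  if (k > 1) for (cl in 2:k) {
    for (j in cl:n) {
      best <- Inf; bestI <- NA_integer_
      for (i in cl:j) {
        val <- D[cl - 1, i - 1] + sse(i, j)
        # strict < keeps the earliest split, i.e. lowest break, on ties
        if (val < best - 1e-12) { best <- val; bestI <- i }
      }
      D[cl, j] <- best; B[cl, j] <- bestI
    }
  }
  # trace back class boundaries (indices into xs)
  starts <- integer(k); j <- n
  for (cl in k:1) { starts[cl] <- B[cl, j]; j <- starts[cl] - 1L }
  breaks <- c(xs[1], vapply(starts[-1], function(i) xs[i], numeric(1)), xs[n])
  classes <- classifyBreaks(values, breaks)
  list(breaks = breaks, classes = classes, ssd = D[k, n])
}

#' @rdname fisherJenks
#' @param breaks break vector as returned in `$breaks`.
#' @export
classifyBreaks <- function(values, breaks) {
  k <- length(breaks) - 1
  cl <- findInterval(values, breaks, rightmost.closed = TRUE,
                     left.open = FALSE)
  pmin(pmax(cl, 1L), k)
}

#' Stratify plots by elevation, radiation and wetness classes
#'
#' Classifies each plot into 5 elevation x 3 radiation x 3 wetness
#' natural-break classes (45 strata), optionally split further into
#' open/closed canopy at the median canopy cover (90 strata). Plots with
#' a missing covariate are left unassigned and reported.
#'
#' @param plots data.frame with columns `elevation`, `radiation`, `twi`
#'   and (if `canopySplit`) `canopy_cover`.
#' @param nElev,nRad,nTwi class counts (defaults 5, 3, 3).
#' @param canopySplit split each stratum at the median canopy cover?
#' @return list: `plots` (input plus class columns and a `stratum`
#'   label), `nTheoretical` (the theoretical stratum count),
#'   `unassigned` (row indices with missing covariates), and the break
#'   vectors used.
#' @export
buildStrata <- function(plots, nElev = 5, nRad = 3, nTwi = 3,
                        canopySplit = FALSE) {
  need <- c("elevation", "radiation", "twi")
  if (canopySplit) need <- c(need, "canopy_cover")
  if (!all(need %in% names(plots)))
    stop("plots must have columns: ", paste(need, collapse = ", "))
  ok <- Reduce(`&`, lapply(need, function(v) is.finite(plots[[v]])))
  fj <- function(v, k) fisherJenks(plots[[v]][ok], k)$breaks
  bE <- fj("elevation", nElev); bR <- fj("radiation", nRad); bT <- fj("twi", nTwi)
  out <- plots
  out$elevation_class <- out$radiation_class <- out$twi_class <- NA_integer_
  out$elevation_class[ok] <- classifyBreaks(plots$elevation[ok], bE)
  out$radiation_class[ok] <- classifyBreaks(plots$radiation[ok], bR)
  out$twi_class[ok] <- classifyBreaks(plots$twi[ok], bT)
  nTheo <- nElev * nRad * nTwi
  lab <- sprintf("E%d.R%d.W%d", out$elevation_class, out$radiation_class,
                 out$twi_class)
  canopyMedian <- NA_real_
  if (canopySplit) {
    canopyMedian <- stats::median(plots$canopy_cover[ok])
    out$canopy_class <- ifelse(plots$canopy_cover >= canopyMedian,
                               "closed", "open")
    lab <- paste0(lab, ".", out$canopy_class)
    nTheo <- nTheo * 2
  }
  lab[!ok] <- NA_character_
  out$stratum <- lab
  list(plots = out, nTheoretical = nTheo, unassigned = which(!ok),
       breaks = list(elevation = bE, radiation = bR, twi = bT),
       canopyMedian = canopyMedian)
}

#' Stratified random site selection
#'
#' Draws up to `nPerStratum` plots without replacement from every
#' non-empty stratum (taking all when a stratum is smaller), then forces
#' in `extremes` plots from the elevation tails (alternating highest and
#' lowest remaining). Deterministic for a fixed seed.
#'
#' @param strata result of [buildStrata] (or a data.frame with `stratum`
#'   and `elevation` columns and a plot `id` column).
#' @param nPerStratum draws per stratum (default 2).
#' @param extremes number of forced extreme-elevation plots (default 6).
#' @param seed RNG seed.
#' @param idCol name of the plot id column (default `"id"`).
#' @return character/integer vector of selected plot ids.
#' @export
selectSites <- function(strata, nPerStratum = 2, extremes = 0, seed = 1,
                        idCol = "id") {
  df <- if (is.list(strata) && !is.null(strata$plots)) strata$plots else strata
  stopifnot(idCol %in% names(df), "stratum" %in% names(df))
  df <- df[!is.na(df$stratum), , drop = FALSE]
  picked <- character(0)
  withr_seed <- function(code) { # local RNG, restore afterwards
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed); code
  }
  picked <- withr_seed({
    sel <- character(0)
    for (st in sort(unique(df$stratum))) {
      ids <- as.character(df[[idCol]][df$stratum == st])
      take <- min(nPerStratum, length(ids))
      sel <- c(sel, if (length(ids) == 1) ids else sample(ids, take))
    }
    sel
  })
  if (extremes > 0 && "elevation" %in% names(df)) {
    rest <- df[!as.character(df[[idCol]]) %in% picked, , drop = FALSE]
    rest <- rest[order(rest$elevation), , drop = FALSE]
    ex <- character(0)
    lo <- 1; hi <- nrow(rest)
    for (i in seq_len(min(extremes, nrow(rest)))) {
      if (i %% 2 == 1) { ex <- c(ex, as.character(rest[[idCol]][hi])); hi <- hi - 1 }
      else { ex <- c(ex, as.character(rest[[idCol]][lo])); lo <- lo + 1 }
    }
    picked <- c(picked, ex)
  }
  picked
}

#' Remove plots falling inside disturbance polygons
#'
#' Plots whose coordinates lie inside (or exactly on the boundary of)
#' any polygon are excluded — used to drop plots whose canopy changed
#' between the structure survey and the measurement year.
#'
#' @param plots data.frame with `x` and `y` columns.
#' @param polygons list of polygons, each a two-column matrix or
#'   data.frame of vertices (closed or open rings accepted).
#' @return the plots data.frame with inside-polygon rows removed.
#' @export
excludeDisturbed <- function(plots, polygons) {
  if (length(polygons) == 0) return(plots)
  keep <- rep(TRUE, nrow(plots))
  for (poly in polygons) {
    P <- as.matrix(poly)
    if (ncol(P) < 2 || nrow(P) < 3 || any(!is.finite(P)))
      stop("invalid polygon geometry")
    inside <- pointInPolygon(plots$x, plots$y, P[, 1], P[, 2])
    keep <- keep & !inside
  }
  plots[keep, , drop = FALSE]
}

# Ray-casting point-in-polygon, boundary-inclusive.
pointInPolygon <- function(px, py, vx, vy) {
  n <- length(vx)
  if (vx[1] == vx[n] && vy[1] == vy[n]) { vx <- vx[-n]; vy <- vy[-n]; n <- n - 1 }
  inside <- rep(FALSE, length(px))
  onEdge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    x1 <- vx[j]; y1 <- vy[j]; x2 <- vx[i]; y2 <- vy[i]
    # boundary test: point on segment
    cross <- (px - x1) * (y2 - y1) - (py - y1) * (x2 - x1)
    within <- px >= pmin(x1, x2) - 1e-12 & px <= pmax(x1, x2) + 1e-12 &
      py >= pmin(y1, y2) - 1e-12 & py <= pmax(y1, y2) + 1e-12
    onEdge <- onEdge | (abs(cross) < 1e-9 & within)
    crosses <- ((y1 > py) != (y2 > py)) &
      (px < (x2 - x1) * (py - y1) / (y2 - y1) + x1)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside | onEdge
}

#' Site density of a monitoring network
#' @param nSites number of sites.
#' @param areaKm2 study area in square kilometres.
#' @param digits decimals to round to (default 1).
#' @return sites per square kilometre.
#' @export
siteDensity <- function(nSites, areaKm2, digits = 1) {
  round(nSites / areaKm2, digits)
}
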