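#' Assign sites to a regular flat-topped hexagon lattice
#'
#' Each site is mapped to the flat-topped hexagon that contains it, via
#' axial-coordinate (cube) rounding. Deterministic; the lattice origin
#' defaults to the data bounding-box corner.
#'
#' @param x,y site coordinates (m).
#' @param flatToFlat hexagon flat-to-flat distance (m), e.g. 9000.
#' @param origin lattice origin `c(x0, y0)`; default bounding-box corner.
#' @return character vector of hexagon ids (`"q,r"` axial labels).
#' @export
hexAssign <- function(x, y, flatToFlat, origin = c(min(x), min(y))) {
  stopifnot(flatToFlat > 0)
  size <- flatToFlat / sqrt(3)   # circumradius of a flat-topped hexagon
  px <- x - origin[1]; py <- y - origin[2]
  qf <- (2 / 3) * px / size
  rf <- (-px / 3 + sqrt(3) / 3 * py) / size
  # cube rounding
  xf <- qf; zf <- rf; yf <- -xf - zf
  rx <- round(xf); ry <- round(yf); rz <- round(zf)
  dx <- abs(rx - xf); dy <- abs(ry - yf); dz <- abs(rz - zf)
  fixX <- dx > dy & dx > dz
  fixY <- !fixX & dy > dz
  rx[fixX] <- -ry[fixX] - rz[fixX]
  ry[fixY] <- -rx[fixY] - rz[fixY]
  rz[!fixX & !fixY] <- -rx[!fixX & !fixY] - ry[!fixX & !fixY]
  sprintf("%d,%d", as.integer(rx), as.integer(rz))
}

#' Allocate hexagons to approximately balanced folds
#'
#' Longest-processing-time greedy: hexagons sorted by decreasing site
#' count are assigned one by one to the currently smallest fold, so every
#' site in a hexagon shares a fold (the spatial blocking constraint) and
#' fold sizes are approximately balanced.
#'
#' @param hexIds hexagon id per site (see [hexAssign]).
#' @param k number of folds (default 10).
#' @param seed seed used to shuffle equal-count hexagons before the
#'   stable sort, making tie order reproducible.
#' @return data.frame per site: `hexagon`, `fold`.
#' @export
allocateFolds <- function(hexIds, k = 10, seed = 1) {
  counts <- table(hexIds)
  if (length(counts) < k)
    stop("only ", length(counts), " non-empty hexagons for ", k, " folds")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  ord <- sample(length(counts))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  counts <- counts[ord]
  counts <- counts[order(-as.integer(counts))]  # stable: ties keep shuffle order
  foldSize <- numeric(k)
  foldOf <- stats::setNames(integer(length(counts)), names(counts))
  nAssigned <- integer(k)
  for (h in names(counts)) {
    # prefer folds with fewest sites; among those, fewest hexagons, so
    # every fold ends up with multiple hexagons when feasible
    cand <- which(foldSize == min(foldSize))
    f <- cand[which.min(nAssigned[cand])]
    foldOf[h] <- f
    foldSize[f] <- foldSize[f] + counts[[h]]
    nAssigned[f] <- nAssigned[f] + 1L
  }
  data.frame(hexagon = hexIds, fold = as.integer(foldOf[hexIds]),
             stringsAsFactors = FALSE)
}

#' Spatial block cross-validation
#'
#' For each fold: fit on the complement (re-running the full selection
#' pipeline), predict the held-out sites, and compute the RMSE. Reports
#' the unweighted mean of the fold RMSEs (the headline number) alongside
#' the pooled RMSE over all held-out residuals.
#'
#' @param data site table with response, predictors and coordinates.
#' @param response response column name.
#' @param folds integer fold id per row.
#' @param fitFun function(data) returning an object accepted by
#'   `predictFun`; defaults to [fitBoostedGAM] with `predictors`.
#' @param predictFun function(model, newdata) returning predictions.
#' @param predictors,coords,control passed to the default `fitFun`.
#' @return list: `perFold` data.frame (fold, n, rmse), `meanRmse`
#'   (unweighted mean over folds), `pooledRmse`.
#' @export
spatialCv <- function(data, response, folds, predictors = NULL,
                      coords = c("x", "y"), control = boostControl(),
                      fitFun = NULL, predictFun = predictSites) {
  ids <- sort(unique(folds))
  if (length(ids) < 2) stop("need at least 2 folds")
  if (is.null(fitFun))
    fitFun <- function(d) fitBoostedGAM(d, response, predictors, coords, control)
  rows <- list(); resid <- numeric(0)
  for (f in ids) {
    hold <- folds == f
    if (!any(hold)) { warning("fold ", f, " has no sites; skipped"); next }
    model <- fitFun(data[!hold, , drop = FALSE])
    pred <- predictFun(model, data[hold, , drop = FALSE])
    err <- data[[response]][hold] - pred
    rows[[length(rows) + 1]] <- data.frame(fold = f, n = sum(hold),
                                           rmse = sqrt(mean(err^2)))
    resid <- c(resid, err)
  }
  perFold <- do.call(rbind, rows)
  list(perFold = perFold, meanRmse = mean(perFold$rmse),
       pooledRmse = sqrt(mean(resid^2)))
}

#' Export fold allocation as CSV
#' @param siteIds site identifiers.
#' @param foldTable result of [allocateFolds].
#' @param path output path.
#' @export
writeFoldsCsv <- function(siteIds, foldTable, path) {
  utils::write.csv(data.frame(site_id = siteIds, hexagon_id = foldTable$hexagon,
                              fold = foldTable$fold), path, row.names = FALSE)
  invisible(path)
}
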