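#' Vegetation height from surface and terrain models
#'
#' Per fine cell the height is `dsm - dtm`, floored at zero (a surface
#' below the terrain is sensor noise); the fine heights are then
#' aggregated to the target cell size by the median.
#'
#' @param dsm,dtm co-registered fine-resolution [RasterGrid-class]
#'   surface and terrain models.
#' @param targetCell output cell size in metres (default 5).
#' @param warnBelow heights below this (m) trigger an alignment warning.
#' @return [RasterGrid-class] of vegetation heights at `targetCell`.
#' @export
vegHeight <- function(dsm, dtm, targetCell = 5, warnBelow = -0.5) {
  if (!isAligned(dsm, dtm)) stop("dsm and dtm must be co-registered")
  h <- dsm@values - dtm@values
  if (any(h < warnBelow, na.rm = TRUE))
    warning(sum(h < warnBelow, na.rm = TRUE),
            " cells with DSM more than ", -warnBelow,
            " m below DTM; check co-registration")
  h <- pmax(h, 0)
  aggregateBlock(rasterLike(h, dtm), targetCell, fun = stats::median)
}

#' Block aggregation of a raster
#'
#' Aggregates to a coarser grid whose cell size is an integer multiple of
#' the source cell size, applying `fun` to the valid fine values in each
#' block (`NA` if none are valid).
#'
#' @param r source [RasterGrid-class].
#' @param targetCell coarser cell size, integer multiple of `cellSize(r)`.
#' @param fun summary function (default mean).
#' @return aggregated [RasterGrid-class].
#' @export
aggregateBlock <- function(r, targetCell, fun = mean) {
  f <- targetCell / r@cellSize
  if (abs(f - round(f)) > 1e-9) stop("targetCell must be a multiple of the cell size")
  f <- as.integer(round(f))
  if (f == 1L) return(r)
  m <- r@values
  nr <- nrow(m) %/% f; nc <- ncol(m) %/% f
  m <- m[seq_len(nr * f), seq_len(nc * f), drop = FALSE]
  out <- matrix(NA_real_, nr, nc)
  # gather the f^2 offsets into an (nr*nc) x f^2 matrix, then summarise rows
  cols <- matrix(NA_real_, nr * nc, f * f)
  k <- 0L
  for (di in seq_len(f)) for (dj in seq_len(f)) {
    k <- k + 1L
    cols[, k] <- as.vector(m[seq(di, nr * f, by = f), seq(dj, nc * f, by = f)])
  }
  vals <- apply(cols, 1, function(v) {
    v <- v[is.finite(v)]
    if (!length(v)) NA_real_ else fun(v)
  })
  out[] <- vals
  rasterGrid(out, cellSize = targetCell, xmin = r@xmin, ymax = r@ymax, crs = r@crs)
}

#' Canopy density as the proportion of returns above 2 m
#'
#' @param returnsAbove2m,returnsTotal co-registered count rasters.
#' @return [RasterGrid-class] in percent; cells with zero total returns
#'   are nodata.
#' @export
pra2m <- function(returnsAbove2m, returnsTotal) {
  if (!isAligned(returnsAbove2m, returnsTotal))
    stop("count rasters must be co-registered")
  ab <- returnsAbove2m@values; tot <- returnsTotal@values
  if (any(ab > tot, na.rm = TRUE))
    stop("returns above 2 m exceed total returns: corrupt input")
  if (any(ab < 0, na.rm = TRUE) || any(tot < 0, na.rm = TRUE))
    stop("negative return counts")
  out <- 100 * ab / tot
  out[tot == 0] <- NA_real_
  rasterLike(out, returnsTotal)
}

#' Split canopy density into coniferous and deciduous cover
#'
#' `Conif_Cover = PRA2m * fraction`, `Decid_Cover = PRA2m * (1 - fraction)`;
#' the two always sum to the canopy density.
#'
#' @param pra2m canopy-density raster in percent.
#' @param treeTypeFraction raster of the coniferous fraction in `[0, 1]`.
#' @return list of RasterGrids `Conif_Cover` and `Decid_Cover`.
#' @export
typeCover <- function(pra2m, treeTypeFraction) {
  if (!isAligned(pra2m, treeTypeFraction)) stop("rasters must be co-registered")
  f <- treeTypeFraction@values
  if (any(f < 0 | f > 1, na.rm = TRUE)) stop("tree-type fraction outside [0, 1]")
  list(Conif_Cover = rasterLike(pra2m@values * f, pra2m),
       Decid_Cover = rasterLike(pra2m@values * (1 - f), pra2m))
}

#' Gaussian-smoothed variants of structure (and DAH) rasters
#'
#' For each raster in `stack` and each sigma, adds a smoothed layer named
#' `<name>_g<sigma>` (so sigma 10 m yields `_g10`, 25 m `_g25`).
#'
#' @param stack named list of RasterGrids.
#' @param sigmas Gaussian standard deviations in metres.
#' @return the input list extended with the smoothed variants.
#' @export
smoothStructure <- function(stack, sigmas = c(10, 25)) {
  out <- stack
  for (nm in names(stack)) for (s in sigmas)
    out[[sprintf("%s_g%d", nm, s)]] <- gaussianSmooth(stack[[nm]], s)
  out
}

#' Derive the forest-structure predictor set
#'
#' Vegetation height (median-aggregated DSM minus DTM), canopy density
#' (PRA2m), coniferous/deciduous cover, and their Gaussian-smoothed
#' variants at 10 m and 25 m.
#'
#' @param dsm,dtmFine co-registered fine-resolution rasters.
#' @param returnsAbove2m,returnsTotal return-count rasters at the target
#'   resolution.
#' @param treeTypeFraction coniferous-fraction raster at the target
#'   resolution.
#' @param targetCell output cell size (m).
#' @param sigmas smoothing SDs (m).
#' @return named list of RasterGrids.
#' @export
canopyPredictors <- function(dsm, dtmFine, returnsAbove2m, returnsTotal,
                             treeTypeFraction, targetCell = 5, sigmas = c(10, 25)) {
  dens <- pra2m(returnsAbove2m, returnsTotal)
  cov <- typeCover(dens, treeTypeFraction)
  base <- list(
    Veg_Height = vegHeight(dsm, dtmFine, targetCell = targetCell),
    PRA2m = dens, Conif_Cover = cov$Conif_Cover, Decid_Cover = cov$Decid_Cover)
  smoothStructure(base, sigmas = sigmas)
}
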