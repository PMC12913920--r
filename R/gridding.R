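#' Apply a fitted model over a predictor stack
#'
#' Evaluates the model in every cell of the stack, supplying cell-centre
#' coordinates to the spatial tensor. Cells where any required input is
#' nodata are nodata. Evaluation is chunked by rows to bound memory; the
#' output is independent of the chunk size.
#'
#' @param model a [BoostedGAMModel-class].
#' @param stack a [PredictorStack-class] containing every model
#'   predictor.
#' @param chunkRows rows evaluated per chunk (default 64).
#' @return [RasterGrid-class] of predictions.
#' @export
predictGrid <- function(model, stack, chunkRows = 64) {
  needed <- setdiff(unique(unlist(lapply(model@terms, `[[`, "vars"))),
                    c("x", "y"))
  miss <- setdiff(needed, names(stack))
  if (length(miss)) stop("missing predictor layer(s): ",
                         paste(miss, collapse = ", "))
  ref <- stack@layers[[1]]
  cc <- cellCenters(ref)
  nr <- length(cc$y); nc <- length(cc$x)
  out <- matrix(NA_real_, nr, nc)
  layerVals <- lapply(stack@layers[needed], gridValues)
  for (start in seq(1, nr, by = chunkRows)) {
    rows <- start:min(start + chunkRows - 1, nr)
    df <- data.frame(x = rep(cc$x, each = length(rows)),
                     y = rep(cc$y[rows], times = nc))
    for (nm in needed) df[[nm]] <- as.vector(layerVals[[nm]][rows, , drop = FALSE])
    ok <- stats::complete.cases(df)
    pred <- rep(NA_real_, nrow(df))
    if (any(ok)) pred[ok] <- predictSites(model, df[ok, , drop = FALSE])
    out[rows, ] <- matrix(pred, length(rows), nc)
  }
  rasterLike(out, ref)
}

#' Extrapolation-uncertainty raster
#'
#' For each cell, the proportion of the model's predictor variables whose
#' value falls strictly outside the range covered by the training sites
#' (the spatial tensor's coordinates are not counted). 0 means every
#' predictor is within the training range; 1 means the model extrapolates
#' on all of them.
#'
#' @param model a [BoostedGAMModel-class] carrying training ranges.
#' @param stack a [PredictorStack-class].
#' @return [RasterGrid-class] with values in `{0, 1/p, ..., 1}`.
#' @export
uncertaintyRaster <- function(model, stack) {
  ranges <- list()
  for (t in model@terms) {
    if (t$kind == "spatial_tensor") next
    for (v in t$vars) ranges[[v]] <- t$trainRange[[v]]
  }
  p <- length(ranges)
  if (p == 0) stop("model has no non-spatial predictors")
  miss <- setdiff(names(ranges), names(stack))
  if (length(miss)) stop("missing predictor layer(s): ",
                         paste(miss, collapse = ", "))
  ref <- stack@layers[[1]]
  cnt <- matrix(0, nrow(ref@values), ncol(ref@values))
  anyNA <- matrix(FALSE, nrow(ref@values), ncol(ref@values))
  for (v in names(ranges)) {
    vals <- gridValues(stack[[v]])
    cnt <- cnt + (is.finite(vals) &
                    (vals < ranges[[v]][1] | vals > ranges[[v]][2]))
    anyNA <- anyNA | !is.finite(vals)
  }
  out <- cnt / p
  out[anyNA] <- NA_real_
  rasterLike(out, ref)
}

#' Zonal mean aggregation to a coarser grid
#'
#' Mean of the valid fine cells inside every coarse cell (`NA` when no
#' fine cell is valid). Used to compare high-resolution grids with
#' coarser products on their own grid.
#'
#' @param fine a [RasterGrid-class].
#' @param coarseCell coarse cell size, an integer multiple of the fine
#'   cell size.
#' @return aggregated [RasterGrid-class].
#' @export
zonalMean <- function(fine, coarseCell) {
  aggregateBlock(fine, coarseCell, fun = mean)
}

#' Cell-wise grid difference with error summaries
#'
#' `a - b` plus mean error, mean absolute error and RMSE over the cells
#' valid in both grids.
#'
#' @param a,b aligned [RasterGrid-class] objects.
#' @return list: `difference` raster, `me`, `mae`, `rmse`.
#' @export
gridDifference <- function(a, b) {
  if (!isAligned(a, b)) stop("grids are not aligned")
  d <- a@values - b@values
  v <- d[is.finite(d)]
  list(difference = rasterLike(d, a), me = mean(v), mae = mean(abs(v)),
       rmse = sqrt(mean(v^2)))
}
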