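#' @import methods
NULL

#' Regular raster grid with nodata mask
#'
#' A minimal in-memory raster: a numeric matrix with square cells, a
#' georeferenced origin, and a free-text CRS tag. `NA` cells are nodata.
#' Row 1 of `values` is the northernmost row; column 1 the westernmost
#' column, so `values[1, 1]` is the north-west cell. The origin is the
#' outer (north-west) corner of that cell.
#'
#' @slot values numeric matrix; `NA` marks nodata.
#' @slot cellSize cell edge length in metres (cells are square).
#' @slot xmin x coordinate of the west edge (outer corner).
#' @slot ymax y coordinate of the north edge (outer corner).
#' @slot crs free-text coordinate reference system tag, carried through
#'   all operations but never interpreted.
#' @exportClass RasterGrid
setClass("RasterGrid",
  representation(values = "matrix", cellSize = "numeric",
                 xmin = "numeric", ymax = "numeric", crs = "character"),
  prototype(values = matrix(numeric(0), 0, 0), cellSize = 1,
            xmin = 0, ymax = 0, crs = "local"))

setValidity("RasterGrid", function(object) {
  msg <- character(0)
  if (!is.numeric(object@values)) msg <- c(msg, "values must be a numeric matrix")
  if (length(object@cellSize) != 1 || !is.finite(object@cellSize) ||
      object@cellSize <= 0) msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@xmin) != 1 || length(object@ymax) != 1)
    msg <- c(msg, "origin must be scalar (xmin, ymax)")
  if (length(msg)) msg else TRUE
})

#' A named stack of co-registered rasters
#'
#' All layers share shape, cell size, origin and CRS tag; layer names
#' follow the predictor vocabulary used by the models (e.g. `Elevation`,
#' `DAH_g25`, `PRA2m`).
#'
#' @slot layers named list of [RasterGrid-class] objects.
#' @exportClass PredictorStack
setClass("PredictorStack", representation(layers = "list"))

setValidity("PredictorStack", function(object) {
  ls <- object@layers
  if (length(ls) == 0) return("stack must contain at least one layer")
  if (is.null(names(ls)) || any(!nzchar(names(ls))) || anyDuplicated(names(ls)))
    return("layers must have unique non-empty names")
  if (!all(vapply(ls, is, logical(1), "RasterGrid")))
    return("all layers must be RasterGrid objects")
  ref <- ls[[1]]
  for (r in ls[-1]) {
    if (!identical(dim(r@values), dim(ref@values)) ||
        !isTRUE(all.equal(r@cellSize, ref@cellSize)) ||
        !isTRUE(all.equal(r@xmin, ref@xmin)) ||
        !isTRUE(all.equal(r@ymax, ref@ymax)))
      return("all layers must be co-registered (same shape, cell size, origin)")
  }
  TRUE
})

#' One sensor's 15-minute temperature series at a site
#'
#' Timestamps advance at a strict 15-minute step (gaps are explicit `NA`
#' values, never missing rows). Readings flagged not-`ok` are excluded
#' from every summary.
#'
#' @slot siteId,sensorId identifiers.
#' @slot level measurement level, one of `"soil_8cm"`, `"air_15cm"`,
#'   `"air_200cm"`.
#' @slot timestamps `POSIXct`, strictly increasing, constant 900 s step.
#' @slot values temperatures in degrees Celsius (may be `NA`).
#' @slot qcOk logical, `TRUE` where the reading is usable.
#' @exportClass TemperatureSeries
setClass("TemperatureSeries",
  representation(siteId = "character", sensorId = "character",
                 level = "character", timestamps = "POSIXct",
                 values = "numeric", qcOk = "logical"))

setValidity("TemperatureSeries", function(object) {
  msg <- character(0)
  if (!object@level %in% c("soil_8cm", "air_15cm", "air_200cm"))
    msg <- c(msg, "level must be soil_8cm, air_15cm or air_200cm")
  n <- length(object@timestamps)
  if (length(object@values) != n || length(object@qcOk) != n)
    msg <- c(msg, "timestamps, values and qcOk must have equal length")
  if (n > 1) {
    dt <- diff(as.numeric(object@timestamps))
    if (any(abs(dt - 900) > 1e-6))
      msg <- c(msg, "timestamps must advance at a constant 15-minute step")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted boosted spatial GAM
#'
#' The result of componentwise L2 boosting over P-spline base learners
#' followed by a joint penalized refit with GCV-chosen smoothing
#' parameters. Slots hold everything needed to predict (including linear
#' extension beyond the training range) and to report Table-style
#' summaries.
#'
#' @slot response name of the modelled variable.
#' @slot intercept fitted intercept.
#' @slot terms list of fitted term descriptors (kind, predictors, knots,
#'   coefficients, lambda, edf, shape, training range).
#' @slot mstop number of boosting iterations used for selection.
#' @slot adjR2 adjusted R-squared on the training data.
#' @slot interactionIncluded was the DAH-by-canopy interaction tensor kept?
#' @slot seed RNG seed used for the selection stage.
#' @slot sigma2 residual variance estimate of the refit.
#' @exportClass BoostedGAMModel
setClass("BoostedGAMModel",
  representation(response = "character", intercept = "numeric",
                 terms = "list", mstop = "numeric", adjR2 = "numeric",
                 interactionIncluded = "logical", seed = "numeric",
                 sigma2 = "numeric"))

#' A synthetic world with known generative truth
#'
#' Bundles the rasters of a simulated mountain landscape, the site table,
#' and the coefficients of the additive temperature model used to drive
#' the loggers, so that recovery of the generative structure can be
#' tested end to end.
#'
#' @slot dtm,dsm terrain and surface models ([RasterGrid-class]).
#' @slot canopy named list of canopy rasters (`PRA2m`, `Veg_Height`,
#'   `returns_total`, `returns_above2m`, `tree_type_fraction`).
#' @slot stack the full predictor stack derived from the rasters
#'   ([PredictorStack-class]).
#' @slot sites data.frame of site ids, coordinates and extracted
#'   predictor values.
#' @slot coefficients named list of generative coefficients.
#' @slot noiseSd per-reading noise standard deviation (degC).
#' @slot seed integer seed the world was built from.
#' @exportClass SyntheticWorld
setClass("SyntheticWorld",
  representation(dtm = "RasterGrid", dsm = "RasterGrid", canopy = "list",
                 stack = "PredictorStack", sites = "data.frame",
                 coefficients = "list", noiseSd = "numeric", seed = "numeric"))
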