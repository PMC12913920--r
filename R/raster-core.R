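#' Construct a RasterGrid
#'
#' @param values numeric matrix, row 1 = northernmost row, `NA` = nodata.
#' @param cellSize cell edge length (m).
#' @param xmin,ymax coordinates of the outer north-west corner.
#' @param crs free-text CRS tag.
#' @return a [RasterGrid-class].
#' @examples
#' r <- rasterGrid(matrix(1:12, 3, 4), cellSize = 5)
#' dim(gridValues(r))
#' @export
rasterGrid <- function(values, cellSize = 1, xmin = 0, ymax = nrow(values) * cellSize,
                       crs = "local") {
  if (is.vector(values)) values <- matrix(values, 1)
  storage.mode(values) <- "double"
  new("RasterGrid", values = values, cellSize = cellSize,
      xmin = xmin, ymax = ymax, crs = crs)
}

#' @rdname rasterGrid
#' @param x a RasterGrid.
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname rasterGrid
#' @export
setMethod("gridValues", "RasterGrid", function(x) x@values)

#' @rdname rasterGrid
#' @export
setGeneric("cellSize", function(x) standardGeneric("cellSize"))
#' @rdname rasterGrid
#' @export
setMethod("cellSize", "RasterGrid", function(x) x@cellSize)

#' @rdname rasterGrid
#' @export
setGeneric("crsTag", function(x) standardGeneric("crsTag"))
#' @rdname rasterGrid
#' @export
setMethod("crsTag", "RasterGrid", function(x) x@crs)

#' Cell-centre coordinates of a raster
#'
#' @param x a [RasterGrid-class].
#' @return list with vectors `x` (west to east) and `y` (north to south),
#'   matching columns and rows of `gridValues(x)`.
#' @export
cellCenters <- function(x) {
  stopifnot(is(x, "RasterGrid"))
  d <- dim(x@values)
  list(x = x@xmin + (seq_len(d[2]) - 0.5) * x@cellSize,
       y = x@ymax - (seq_len(d[1]) - 0.5) * x@cellSize)
}

#' @describeIn rasterGrid replace values keeping geometry
#' @param template RasterGrid supplying geometry.
#' @export
rasterLike <- function(values, template) {
  rasterGrid(values, cellSize = template@cellSize, xmin = template@xmin,
             ymax = template@ymax, crs = template@crs)
}

setMethod("show", "RasterGrid", function(object) {
  d <- dim(object@values)
  v <- object@values[is.finite(object@values)]
  cat(sprintf("RasterGrid: %d rows x %d cols @ %g m  [%s]\n",
              d[1], d[2], object@cellSize, object@crs))
  cat(sprintf("  origin (xmin, ymax): (%g, %g)\n", object@xmin, object@ymax))
  if (length(v)) cat(sprintf("  values: min %.4g, max %.4g, nodata %d cells\n",
                             min(v), max(v), sum(!is.finite(object@values))))
  else cat("  all nodata\n")
})

#' Check that two rasters share geometry
#' @param a,b RasterGrid objects.
#' @return TRUE or FALSE.
#' @export
isAligned <- function(a, b) {
  identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@cellSize, b@cellSize)) &&
    isTRUE(all.equal(a@xmin, b@xmin)) &&
    isTRUE(all.equal(a@ymax, b@ymax))
}

#' Read / write ESRI ASCII grids
#'
#' Plain-text raster exchange format (`ncols/nrows/xllcorner/yllcorner/
#' cellsize/NODATA_value` header followed by rows north to south). The
#' CRS tag is not representable in the format; `readAsciiGrid` accepts it
#' as an argument.
#'
#' @param path file path.
#' @param crs CRS tag to attach on read.
#' @return `readAsciiGrid`: a [RasterGrid-class]. `writeAsciiGrid`:
#'   invisibly, the path.
#' @export
readAsciiGrid <- function(path, crs = "local") {
  con <- file(path, "r"); on.exit(close(con))
  hdr <- list()
  repeat {
    pos <- seek(con)
    line <- readLines(con, n = 1)
    parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) == 2 && grepl("^[A-Za-z_]", parts[1])) {
      hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    } else { seek(con, pos); break }
  }
  need <- c("ncols", "nrows", "cellsize")
  if (!all(need %in% names(hdr))) stop("malformed ESRI ASCII header in ", path)
  vals <- scan(con, what = numeric(), quiet = TRUE)
  nr <- hdr$nrows; nc <- hdr$ncols
  if (length(vals) != nr * nc) stop("grid body size mismatch in ", path)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  nd <- hdr[["nodata_value"]]
  if (!is.null(nd)) m[m == nd] <- NA_real_
  xll <- if (!is.null(hdr$xllcorner)) hdr$xllcorner else hdr$xllcenter - hdr$cellsize / 2
  yll <- if (!is.null(hdr$yllcorner)) hdr$yllcorner else hdr$yllcenter - hdr$cellsize / 2
  rasterGrid(m, cellSize = hdr$cellsize, xmin = xll,
             ymax = yll + nr * hdr$cellsize, crs = crs)
}

#' @rdname readAsciiGrid
#' @param x a [RasterGrid-class] to write.
#' @param nodata numeric value standing for `NA` in the file.
#' @export
writeAsciiGrid <- function(x, path, nodata = -9999) {
  stopifnot(is(x, "RasterGrid"))
  m <- x@values
  d <- dim(m)
  hdr <- c(sprintf("ncols %d", d[2]), sprintf("nrows %d", d[1]),
           sprintf("xllcorner %.10g", x@xmin),
           sprintf("yllcorner %.10g", x@ymax - d[1] * x@cellSize),
           sprintf("cellsize %.10g", x@cellSize),
           sprintf("NODATA_value %g", nodata))
  m[!is.finite(m)] <- nodata
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Build a PredictorStack
#' @param ... named RasterGrid layers, or a single named list.
#' @return a [PredictorStack-class].
#' @export
predictorStack <- function(...) {
  ls <- list(...)
  if (length(ls) == 1 && is.list(ls[[1]]) && !is(ls[[1]], "RasterGrid")) ls <- ls[[1]]
  new("PredictorStack", layers = ls)
}

#' @rdname predictorStack
#' @param x a PredictorStack.
#' @export
setGeneric("stackLayers", function(x) standardGeneric("stackLayers"))
#' @rdname predictorStack
#' @export
setMethod("stackLayers", "PredictorStack", function(x) x@layers)

#' @export
setMethod("names", "PredictorStack", function(x) names(x@layers))

#' @export
setMethod("[[", "PredictorStack", function(x, i) x@layers[[i]])

setMethod("show", "PredictorStack", function(object) {
  ref <- object@layers[[1]]
  cat(sprintf("PredictorStack: %d layers, %d x %d @ %g m\n",
              length(object@layers), nrow(ref@values), ncol(ref@values),
              ref@cellSize))
  cat(" ", paste(names(object@layers), collapse = ", "), "\n")
})

#' Extract raster values at point coordinates
#'
#' @param r a [RasterGrid-class] or [PredictorStack-class].
#' @param x,y point coordinates.
#' @param method `"bilinear"` (default) or `"nearest"`.
#' @return numeric vector (RasterGrid) or data.frame with one column per
#'   layer (PredictorStack). Points outside the raster return `NA`.
#' @export
extractAtPoints <- function(r, x, y, method = c("bilinear", "nearest")) {
  method <- match.arg(method)
  if (is(r, "PredictorStack")) {
    out <- lapply(r@layers, extractAtPoints, x = x, y = y, method = method)
    return(as.data.frame(out, check.names = FALSE))
  }
  stopifnot(is(r, "RasterGrid"))
  m <- r@values; cs <- r@cellSize; d <- dim(m)
  # fractional cell-centre indices (col ~ x, row ~ y, row 1 north)
  fc <- (x - r@xmin) / cs + 0.5
  fr <- (r@ymax - y) / cs + 0.5
  if (method == "nearest") {
    ci <- round(fc); ri <- round(fr)
    ok <- ri >= 1 & ri <= d[1] & ci >= 1 & ci <= d[2]
    out <- rep(NA_real_, length(x))
    out[ok] <- m[cbind(ri[ok], ci[ok])]
    return(out)
  }
  c0 <- pmin(pmax(floor(fc), 1), d[2] - 1); r0 <- pmin(pmax(floor(fr), 1), d[1] - 1)
  if (d[1] == 1) r0 <- rep(1, length(fr))
  if (d[2] == 1) c0 <- rep(1, length(fc))
  wx <- pmin(pmax(fc - c0, 0), 1); wy <- pmin(pmax(fr - r0, 0), 1)
  c1 <- pmin(c0 + 1, d[2]); r1 <- pmin(r0 + 1, d[1])
  v00 <- m[cbind(r0, c0)]; v01 <- m[cbind(r0, c1)]
  v10 <- m[cbind(r1, c0)]; v11 <- m[cbind(r1, c1)]
  out <- (1 - wy) * ((1 - wx) * v00 + wx * v01) + wy * ((1 - wx) * v10 + wx * v11)
  inside <- fc >= 0.5 & fc <= d[2] + 0.5 & fr >= 0.5 & fr <= d[1] + 0.5
  out[!inside] <- NA_real_
  out
}

## ---- internal: FFT-based focal filtering ---------------------------------

# 2-D convolution of `a` with centred kernel `k` via FFT, zero-padded.
conv2fft <- function(a, k) {
  da <- dim(a); dk <- dim(k)
  n1 <- stats::nextn(da[1] + dk[1] - 1, c(2, 3, 5))
  n2 <- stats::nextn(da[2] + dk[2] - 1, c(2, 3, 5))
  A <- matrix(0, n1, n2); A[seq_len(da[1]), seq_len(da[2])] <- a
  K <- matrix(0, n1, n2); K[seq_len(dk[1]), seq_len(dk[2])] <- k
  out <- Re(stats::fft(stats::fft(A) * stats::fft(K), inverse = TRUE)) / (n1 * n2)
  # kernel centre offset: (dk+1)/2 (dk odd)
  o1 <- (dk[1] + 1) / 2; o2 <- (dk[2] + 1) / 2
  out[o1 + seq_len(da[1]) - 1, o2 + seq_len(da[2]) - 1]
}

# Mask-weighted focal filter: weighted mean of valid cells under `kernel`.
# pad = "zero": outside-raster area contributes nothing (used for TPI);
# pad = "reflect": whole-point reflection, mean-preserving for symmetric
# kernels on fully valid rasters (used for Gaussian smoothing).
focalFilter <- function(m, kernel, pad = c("zero", "reflect")) {
  pad <- match.arg(pad)
  mask <- is.finite(m)
  v0 <- ifelse(mask, m, 0)
  if (pad == "reflect") {
    # half-sample symmetric reflection: doubly stochastic for symmetric
    # kernels, hence exactly mean-preserving on fully valid rasters
    h1 <- (dim(kernel)[1] - 1) / 2; h2 <- (dim(kernel)[2] - 1) / 2
    p1 <- min(h1, nrow(m)); p2 <- min(h2, ncol(m))
    idx1 <- c(rev(seq_len(p1)), seq_len(nrow(m)), nrow(m) + 1 - seq_len(p1))
    idx2 <- c(rev(seq_len(p2)), seq_len(ncol(m)), ncol(m) + 1 - seq_len(p2))
    v0p <- v0[idx1, idx2, drop = FALSE]
    mkp <- (mask * 1)[idx1, idx2, drop = FALSE]
    num <- conv2fft(v0p, kernel)[p1 + seq_len(nrow(m)), p2 + seq_len(ncol(m))]
    den <- conv2fft(mkp, kernel)[p1 + seq_len(nrow(m)), p2 + seq_len(ncol(m))]
  } else {
    num <- conv2fft(v0, kernel)
    den <- conv2fft(mask * 1, kernel)
  }
  out <- num / den
  out[den < 1e-10] <- NA_real_
  out[!mask] <- NA_real_
  out
}
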