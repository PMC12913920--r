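#' Model-summary table across responses
#'
#' One row per modelled variable; predictor columns are sorted by the
#' number of models that selected them (decreasing; alphabetical ties),
#' each cell showing the term's effective df and shape symbol, with
#' trailing adjusted R-squared and mean spatial-CV RMSE columns.
#'
#' @param models named list of [BoostedGAMModel-class] (names = response
#'   variables).
#' @param cvResults optional named list of [spatialCv] results aligned
#'   with `models`.
#' @return data.frame; attribute `"markdown"` carries a rendered text
#'   table.
#' @export
buildTable3 <- function(models, cvResults = NULL) {
  stopifnot(length(models) >= 1)
  termNames <- lapply(models, function(m)
    setdiff(names(m@terms), "SpatialTensor"))
  counts <- sort(table(unlist(termNames)), decreasing = TRUE)
  preds <- names(counts)[order(-as.integer(counts), names(counts))]
  rows <- lapply(names(models), function(resp) {
    m <- models[[resp]]
    cells <- vapply(preds, function(p) {
      t <- m@terms[[p]]
      if (is.null(t)) "" else sprintf("%.2f%s", t$edf,
                                      if (is.na(t$shape)) ""
                                      else shapeSymbol(t$shape))
    }, character(1))
    sp <- m@terms[["SpatialTensor"]]
    out <- c(list(variable = resp), as.list(cells),
             list(SpatialTensor = if (is.null(sp)) ""
                  else sprintf("%.2f", sp$edf),
                  adjR2 = round(m@adjR2, 2),
                  RMSE = if (!is.null(cvResults) && !is.null(cvResults[[resp]]))
                    round(cvResults[[resp]]$meanRmse, 2) else NA_real_))
    as.data.frame(out, check.names = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  md <- paste(c(paste("|", paste(names(tab), collapse = " | "), "|"),
                paste("|", paste(rep("---", ncol(tab)), collapse = " | "), "|"),
                apply(tab, 1, function(r)
                  paste("|", paste(r, collapse = " | "), "|"))),
              collapse = "\n")
  attr(tab, "markdown") <- md
  tab
}

#' Point-validation error statistics
#'
#' Mean error, mean absolute error and RMSE of predicted minus observed
#' (the "grid minus station" sign convention: positive ME means the grid
#' runs warm).
#'
#' @param predicted,observed paired numeric vectors.
#' @return named list: `me`, `mae`, `rmse`.
#' @export
validationTable <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must be the same length")
  d <- predicted - observed
  list(me = mean(d), mae = mean(abs(d)), rmse = sqrt(mean(d^2)))
}

#' Write a model-summary table to CSV
#' @param tab result of [buildTable3].
#' @param path output path.
#' @export
writeTable3 <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
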