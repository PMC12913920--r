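#' Control parameters for the boosted spatial GAM
#'
#' @param nu boosting step length.
#' @param mstopGrid candidate iteration counts scored by the inner CV.
#' @param df fixed effective df of every base learner during boosting
#'   (equal across learners so selection is fair).
#' @param innerFolds folds of the random inner CV that picks `mstop`.
#' @param nKnots interior knots of univariate P-spline learners.
#' @param degree B-spline degree.
#' @param penaltyOrder difference-penalty order.
#' @param tensorK marginal basis dimension of the spatial tensor.
#' @param interK marginal basis dimension of the interaction tensor.
#' @param seed RNG seed for the inner CV.
#' @return list of control values.
#' @export
boostControl <- function(nu = 0.1, mstopGrid = seq(25, 1000, by = 25), df = 4,
                         innerFolds = 10, nKnots = 20, degree = 3,
                         penaltyOrder = 2, tensorK = 10, interK = 5, seed = 1) {
  list(nu = nu, mstopGrid = mstopGrid, df = df, innerFolds = innerFolds,
       nKnots = nKnots, degree = degree, penaltyOrder = penaltyOrder,
       tensorK = tensorK, interK = interK, seed = seed)
}

#' Candidate base learners for one response
#'
#' One univariate P-spline learner per predictor plus the bivariate
#' spatial tensor on the coordinates. Constant predictors are dropped
#' with a warning. The spatial tensor is always carried into the final
#' model regardless of whether boosting picks it.
#'
#' @param data training data.frame.
#' @param predictors predictor column names.
#' @param coords names of the coordinate columns (default `c("x", "y")`).
#' @param control see [boostControl].
#' @return list of learner definitions.
#' @export
buildCandidates <- function(data, predictors, coords = c("x", "y"),
                            control = boostControl()) {
  if (any(!predictors %in% names(data)))
    stop("missing predictor columns: ",
         paste(setdiff(predictors, names(data)), collapse = ", "))
  if (anyNA(data[predictors])) stop("predictors contain missing values")
  defs <- list()
  for (p in predictors) {
    if (stats::sd(data[[p]]) < 1e-12) {
      warning("dropping constant predictor '", p, "'")
      next
    }
    defs[[p]] <- list(name = p, kind = "univariate_pspline", vars = p,
                      bases = list(psplineBasis(data[[p]], control$nKnots,
                                                control$degree,
                                                control$penaltyOrder)))
  }
  nIntTensor <- max(1L, control$tensorK - control$degree - 1L)
  defs[["SpatialTensor"]] <- list(
    name = "SpatialTensor", kind = "spatial_tensor", vars = coords,
    bases = lapply(coords, function(v)
      psplineBasis(data[[v]], nIntTensor, control$degree, control$penaltyOrder)))
  defs
}

interactionLearner <- function(data, dahName, praName, control) {
  nInt <- max(1L, control$interK - control$degree - 1L)
  list(name = sprintf("%s:%s", dahName, praName), kind = "interaction_tensor",
       vars = c(dahName, praName),
       bases = lapply(c(dahName, praName), function(v)
         psplineBasis(data[[v]], nInt, control$degree, control$penaltyOrder)))
}

# Raw design matrix and penalty of a learner definition. The interaction
# tensor is a pure-interaction smooth: each margin is centered before the
# tensor product so the term spans no intercept or main effects (its
# penalty null space is the pure bilinear product only).
learnerDesign <- function(def, data) {
  marginZ <- NULL
  if (def$kind == "univariate_pspline") {
    B <- evalPsplineBasis(def$bases[[1]], data[[def$vars]])
    P <- def$bases[[1]]$P
  } else {
    b1 <- def$bases[[1]]; b2 <- def$bases[[2]]
    x1 <- pmin(pmax(data[[def$vars[1]]], b1$range[1]), b1$range[2])
    x2 <- pmin(pmax(data[[def$vars[2]]], b2$range[1]), b2$range[2])
    B1 <- splines::splineDesign(b1$knots, x1, ord = b1$degree + 1, outer.ok = TRUE)
    B2 <- splines::splineDesign(b2$knots, x2, ord = b2$degree + 1, outer.ok = TRUE)
    if (def$kind == "interaction_tensor") {
      Z1 <- centeringTransform(B1); Z2 <- centeringTransform(B2)
      marginZ <- list(Z1, Z2)
      B <- tensorDesign(B1 %*% Z1, B2 %*% Z2)
      P <- tensorPenalty(crossprod(Z1, b1$P %*% Z1),
                         crossprod(Z2, b2$P %*% Z2))
    } else {
      B <- tensorDesign(B1, B2)
      P <- tensorPenalty(b1$P, b2$P)
    }
  }
  list(B = B, P = P, marginZ = marginZ)
}

# Materialize a learner on the training data: centered design, centered
# penalty, and the boosting-stage smoothing parameter for the target df.
# The interaction tensor is already centered through its margins, so its
# overall transform is the identity.
materializeLearner <- function(def, data, df) {
  d <- learnerDesign(def, data)
  Z <- if (def$kind == "interaction_tensor") diag(ncol(d$B))
  else centeringTransform(d$B)
  Bc <- d$B %*% Z
  Pc <- crossprod(Z, d$P %*% Z)
  BtB <- crossprod(Bc)
  lambda <- lambdaForDf(BtB, Pc, df)
  c(def, list(Z = Z, marginZ = d$marginZ, Bc = Bc, Pc = Pc, lambda = lambda,
              trainRange = stats::setNames(
                lapply(def$vars, function(v) range(data[[v]])), def$vars)))
}

# One componentwise L2-boosting run. Returns the selection sequence and,
# if validation rows are given, the validation SSE at each snapshot.
boostRun <- function(y, mats, nu, mstopMax, snapshotAt = integer(0),
                     trainIdx = NULL, valIdx = NULL) {
  n <- length(y)
  if (is.null(trainIdx)) trainIdx <- seq_len(n)
  ytr <- y[trainIdx]
  L <- length(mats)
  Btr <- lapply(mats, function(m) m$Bc[trainIdx, , drop = FALSE])
  Pl <- vector("list", L); Sl <- vector("list", L)
  for (l in seq_len(L)) {
    M <- crossprod(Btr[[l]]) + mats[[l]]$lambda * mats[[l]]$Pc
    M <- M + diag(1e-10 * mean(diag(M)), nrow(M))
    Pl[[l]] <- solve(M, t(Btr[[l]]))
    Sl[[l]] <- Btr[[l]] %*% Pl[[l]]
  }
  bigS <- do.call(rbind, Sl)
  ntr <- length(ytr)
  intercept <- mean(ytr)
  r <- ytr - intercept
  coefs <- lapply(mats, function(m) numeric(ncol(m$Bc)))
  sel <- integer(mstopMax)
  Bval <- if (!is.null(valIdx))
    lapply(mats, function(m) m$Bc[valIdx, , drop = FALSE])
  valSse <- stats::setNames(numeric(length(snapshotAt)),
                            as.character(snapshotAt))
  trainRss <- numeric(mstopMax)
  snap <- 0L
  for (m in seq_len(mstopMax)) {
    Fv <- matrix(bigS %*% r, ntr, L)
    rss <- colSums((r - Fv)^2)
    best <- which.min(rss)
    coefs[[best]] <- coefs[[best]] + nu * as.numeric(Pl[[best]] %*% r)
    r <- r - nu * Fv[, best]
    sel[m] <- best
    trainRss[m] <- sum(r^2)
    if (m %in% snapshotAt && !is.null(valIdx)) {
      snap <- snap + 1L
      pred <- rep(intercept, length(valIdx))
      for (l in unique(sel[seq_len(m)]))
        pred <- pred + as.numeric(Bval[[l]] %*% coefs[[l]])
      valSse[snap] <- sum((y[valIdx] - pred)^2)
    }
  }
  list(sel = sel, coefs = coefs, intercept = intercept, valSse = valSse,
       trainRss = trainRss)
}

#' Componentwise L2 boosting with inner-CV stopping
#'
#' Initializes at the response mean, then per iteration fits every base
#' learner to the current residuals by penalized least squares (all at
#' the same fixed effective df), updates the best-fitting learner by a
#' step of length `nu`, and chooses the stopping iteration `mstop` that
#' minimizes the inner cross-validated squared error over the grid. The
#' learners ever selected up to `mstop` form the selected set.
#'
#' @param y response vector.
#' @param mats materialized learners (internal; see [fitBoostedGAM] for
#'   the user-facing entry point).
#' @param control see [boostControl].
#' @return list: `selected` (names), `mstop`, `selSequence`, `cvCurve`,
#'   `trainRss`, plus the full-data run (`run`).
#' @export
l2boost <- function(y, mats, control = boostControl()) {
  n <- length(y)
  if (n < 30) stop("need at least 30 observations for boosting selection")
  if (stats::var(y) < 1e-24)
    return(list(selected = character(0), mstop = 0L,
                selSequence = integer(0),
                cvCurve = NULL, run = NULL, intercept = mean(y)))
  grid <- control$mstopGrid
  mmax <- max(grid)
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(control$seed)
  folds <- sample(rep(seq_len(control$innerFolds), length.out = n))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sse <- numeric(length(grid))
  for (f in seq_len(control$innerFolds)) {
    tr <- which(folds != f); va <- which(folds == f)
    if (!length(va)) next
    runf <- boostRun(y, mats, control$nu, mmax, snapshotAt = grid,
                     trainIdx = tr, valIdx = va)
    sse <- sse + runf$valSse
  }
  mstop <- grid[which.min(sse)]
  run <- boostRun(y, mats, control$nu, mstop)
  selIdx <- unique(run$sel)
  list(selected = vapply(mats[selIdx], `[[`, character(1), "name"),
       mstop = mstop, selSequence = run$sel,
       cvCurve = data.frame(mstop = grid, cvSse = sse),
       trainRss = run$trainRss, run = run, intercept = run$intercept)
}

## ---- joint penalized refit ------------------------------------------------

# Joint fit of the selected smooths: per-term smoothing parameters by
# GCV, returning coefficients, per-term edf and fit statistics. The
# effective-df inflation gamma = 1.4 counters the well-known tendency of
# plain GCV to undersmooth.
gcvRefit <- function(y, mats, initLogLambda = NULL, gamma = 1.4) {
  n <- length(y)
  ybar <- mean(y); yc <- y - ybar
  Xs <- lapply(mats, `[[`, "Bc")
  X <- do.call(cbind, Xs)
  ks <- vapply(Xs, ncol, integer(1))
  blockEnd <- cumsum(ks); blockStart <- c(1, utils::head(blockEnd, -1) + 1)
  XtX <- crossprod(X); Xty <- crossprod(X, yc)
  Pens <- lapply(mats, `[[`, "Pc")
  p <- ncol(X)
  buildPen <- function(loglam) {
    Pen <- matrix(0, p, p)
    for (j in seq_along(mats)) {
      idx <- blockStart[j]:blockEnd[j]
      Pen[idx, idx] <- exp(loglam[j]) * Pens[[j]]
    }
    Pen + diag(1e-9 * mean(diag(XtX)), p)
  }
  yty <- sum(yc^2)
  gcv <- function(loglam) {
    loglam <- pmin(pmax(loglam, -15), 20)
    Pen <- buildPen(loglam)
    M <- XtX + Pen
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(1e300)
    beta <- backsolve(ch, forwardsolve(t(ch), Xty))
    edf <- sum(diag(chol2inv(ch) %*% XtX))
    rss <- yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
    n * rss / max(n - 1 - gamma * edf, 1)^2
  }
  if (is.null(initLogLambda)) initLogLambda <- log(vapply(mats, `[[`,
                                                          numeric(1), "lambda"))
  opt <- stats::optim(initLogLambda, gcv, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-7))
  loglam <- pmin(pmax(opt$par, -15), 20)
  Pen <- buildPen(loglam)
  M <- XtX + Pen
  ch <- chol(M)
  beta <- backsolve(ch, forwardsolve(t(ch), Xty))
  H <- chol2inv(ch) %*% XtX
  edfPer <- vapply(seq_along(mats), function(j) {
    idx <- blockStart[j]:blockEnd[j]
    sum(diag(H)[idx])
  }, numeric(1))
  rss <- yty - 2 * sum(beta * Xty) + sum(beta * (XtX %*% beta))
  rss <- max(rss, 0)
  edf <- sum(edfPer)
  fitted <- ybar + as.numeric(X %*% beta)
  r2 <- 1 - rss / yty
  adjR2 <- 1 - (1 - r2) * (n - 1) / max(n - 1 - edf, 1)
  list(intercept = ybar, beta = beta, lambda = exp(loglam),
       blockStart = blockStart, blockEnd = blockEnd, edfPer = edfPer,
       rss = rss, adjR2 = adjR2, fitted = fitted,
       sigma2 = rss / max(n - 1 - edf, 1))
}

#' Classify the shape of a partial-effect curve
#'
#' Maps a fitted smooth evaluated on a grid to one of five classes:
#' monotone increasing, monotone decreasing, unimodal (single interior
#' maximum), inverse-unimodal (single interior minimum), or flat when the
#' curve's range is below `tol`. Curves with more sign changes are
#' assigned the nearest class by their overall sign pattern and flagged
#' with attribute `flagged`.
#'
#' @param fx effect values on an ordered grid (>= 50 points recommended).
#' @param tol absolute range below which the curve counts as flat.
#' @return one of `"increasing"`, `"decreasing"`, `"unimodal"`,
#'   `"inverse_unimodal"`, `"flat"`.
#' @export
classifyShape <- function(fx, tol = 1e-6) {
  rng <- diff(range(fx))
  if (!is.finite(rng) || rng < tol) return("flat")
  d <- diff(fx)
  eps <- 1e-9 * rng
  sgn <- sign(d); sgn[abs(d) <= eps] <- 0
  sgn <- sgn[sgn != 0]
  if (!length(sgn)) return("flat")
  flips <- sum(diff(sgn) != 0)
  out <- if (flips == 0) {
    if (sgn[1] > 0) "increasing" else "decreasing"
  } else if (flips == 1) {
    if (sgn[1] > 0) "unimodal" else "inverse_unimodal"
  } else {
    # beyond the four classes: nearest by dominant pattern
    res <- if (sum(d) > 0) "increasing" else "decreasing"
    attr(res, "flagged") <- TRUE
    return(res)
  }
  out
}

#' @rdname classifyShape
#' @param shape a shape class string.
#' @return `shapeSymbol`: the display symbol used in model tables.
#' @export
shapeSymbol <- function(shape) {
  c(increasing = "↑", decreasing = "↓", unimodal = "∩",
    inverse_unimodal = "∪", flat = "")[shape]
}

## ---- model assembly -------------------------------------------------------

buildModelTerms <- function(mats, refit) {
  terms <- vector("list", length(mats))
  for (j in seq_along(mats)) {
    m <- mats[[j]]
    coef <- refit$beta[refit$blockStart[j]:refit$blockEnd[j]]
    shape <- NA_character_
    if (m$kind == "univariate_pspline") {
      g <- seq(m$bases[[1]]$range[1], m$bases[[1]]$range[2], length.out = 100)
      Bg <- evalPsplineBasis(m$bases[[1]], g) %*% m$Z
      shape <- classifyShape(as.numeric(Bg %*% coef))
    }
    terms[[j]] <- list(name = m$name, kind = m$kind, vars = m$vars,
                       bases = m$bases, Z = m$Z, marginZ = m$marginZ,
                       coef = coef, lambda = refit$lambda[j],
                       edf = refit$edfPer[j], shape = shape,
                       trainRange = m$trainRange)
  }
  stats::setNames(terms, vapply(mats, `[[`, character(1), "name"))
}

evalTermDesign <- function(term, data) {
  for (v in term$vars) if (!v %in% names(data))
    stop("missing predictor column '", v, "'")
  if (term$kind == "univariate_pspline") {
    B <- evalPsplineBasis(term$bases[[1]], data[[term$vars]])
  } else {
    b1 <- term$bases[[1]]; b2 <- term$bases[[2]]
    x1 <- pmin(pmax(data[[term$vars[1]]], b1$range[1]), b1$range[2])
    x2 <- pmin(pmax(data[[term$vars[2]]], b2$range[1]), b2$range[2])
    B1 <- splines::splineDesign(b1$knots, x1, ord = b1$degree + 1, outer.ok = TRUE)
    B2 <- splines::splineDesign(b2$knots, x2, ord = b2$degree + 1, outer.ok = TRUE)
    if (!is.null(term$marginZ)) { B1 <- rowwiseMatProduct(B1, term$marginZ[[1]])
                                  B2 <- rowwiseMatProduct(B2, term$marginZ[[2]]) }
    B <- tensorDesign(B1, B2)
  }
  rowwiseMatProduct(B, term$Z)
}

# Shape-independent matrix product (see rowwiseProduct): used on the
# prediction path so chunked evaluation is bit-reproducible.
rowwiseMatProduct <- function(M, A) {
  out <- matrix(0, nrow(M), ncol(A))
  for (j in seq_len(ncol(A))) out[, j] <- rowwiseProduct(M, A[, j])
  out
}

# Centered penalty matrix of a fitted term (for coefficient refits).
termPenalty <- function(term) {
  if (term$kind == "univariate_pspline") {
    P <- term$bases[[1]]$P
  } else if (!is.null(term$marginZ)) {
    Z1 <- term$marginZ[[1]]; Z2 <- term$marginZ[[2]]
    P <- tensorPenalty(crossprod(Z1, term$bases[[1]]$P %*% Z1),
                       crossprod(Z2, term$bases[[2]]$P %*% Z2))
  } else {
    P <- tensorPenalty(term$bases[[1]]$P, term$bases[[2]]$P)
  }
  crossprod(term$Z, P %*% term$Z)
}

#' Fit a boosted spatial GAM
#'
#' The full modelling engine: candidate construction, componentwise
#' boosting selection with inner-CV stopping, then a joint penalized
#' refit of the selected smooths plus the spatial tensor with GCV-chosen
#' smoothing parameters.
#'
#' @param data training data.frame (must include the coordinates).
#' @param response response column name.
#' @param predictors candidate predictor names.
#' @param coords coordinate column names (default `c("x", "y")`).
#' @param control see [boostControl].
#' @param extraLearners additional learner definitions forced into the
#'   final model (used for the interaction tensor).
#' @return a [BoostedGAMModel-class].
#' @export
fitBoostedGAM <- function(data, response, predictors, coords = c("x", "y"),
                          control = boostControl(), extraLearners = NULL) {
  y <- data[[response]]
  if (is.null(y)) stop("response column '", response, "' not found")
  defs <- buildCandidates(data, predictors, coords, control)
  mats <- lapply(defs, materializeLearner, data = data, df = control$df)
  if (stats::var(y) < 1e-24) {
    return(new("BoostedGAMModel", response = response, intercept = mean(y),
               terms = list(), mstop = 0, adjR2 = 0,
               interactionIncluded = FALSE, seed = control$seed, sigma2 = 0))
  }
  boost <- l2boost(y, mats, control)
  keep <- union(boost$selected, "SpatialTensor")
  sel <- mats[names(mats) %in% keep]
  if (!is.null(extraLearners)) {
    extraMats <- lapply(extraLearners, materializeLearner, data = data,
                        df = control$df)
    sel <- c(sel, extraMats)
  }
  refit <- gcvRefit(y, sel)
  new("BoostedGAMModel", response = response, intercept = refit$intercept,
      terms = buildModelTerms(sel, refit), mstop = as.numeric(boost$mstop),
      adjR2 = refit$adjR2,
      interactionIncluded = any(vapply(sel, `[[`, character(1), "kind") ==
                                  "interaction_tensor"),
      seed = control$seed, sigma2 = refit$sigma2)
}

setMethod("show", "BoostedGAMModel", function(object) {
  cat(sprintf("BoostedGAMModel for %s: %d terms, mstop %d, adj R2 %.3f\n",
              object@response, length(object@terms), as.integer(object@mstop),
              object@adjR2))
  for (t in object@terms)
    cat(sprintf("  %-22s edf %5.2f %s\n", t$name, t$edf,
                if (is.na(t$shape)) "" else shapeSymbol(t$shape)))
})

#' @rdname fitBoostedGAM
#' @param model a fitted [BoostedGAMModel-class].
#' @export
setGeneric("modelTerms", function(model) standardGeneric("modelTerms"))
#' @rdname fitBoostedGAM
#' @export
setMethod("modelTerms", "BoostedGAMModel", function(model) model@terms)

#' Predict at sites
#'
#' Sum of the intercept and every fitted smooth evaluated at the new
#' predictor values; univariate smooths extend linearly beyond the
#' training range, tensor smooths extend as constants (clamped margins).
#'
#' @param model a [BoostedGAMModel-class].
#' @param newdata data.frame with every model predictor (and the
#'   coordinates for the spatial tensor).
#' @return numeric vector of predictions.
#' @export
predictSites <- function(model, newdata) {
  isOrtho <- vapply(model@terms, function(t) !is.null(t$orthoGamma), logical(1))
  contribs <- lapply(model@terms[!isOrtho], function(t)
    rowwiseProduct(evalTermDesign(t, newdata), t$coef))
  out <- rep(model@intercept, nrow(newdata)) +
    if (length(contribs)) Reduce(`+`, contribs) else 0
  for (j in which(isOrtho)) {
    term <- model@terms[[j]]
    B <- evalTermDesign(term, newdata)
    Xb1 <- cbind(1, do.call(cbind, contribs))
    for (k in seq_len(ncol(B)))
      B[, k] <- B[, k] - rowwiseProduct(Xb1, term$orthoGamma[, k])
    out <- out + rowwiseProduct(B, term$coef)
  }
  out
}

# Matrix-vector product evaluated row by row in a fixed summation order,
# so results do not depend on how many rows are evaluated at once (the
# chunking contract of predictGrid).
rowwiseProduct <- function(M, v) {
  out <- M[, 1] * v[1]
  for (k in seq_along(v)[-1]) out <- out + M[, k] * v[k]
  as.numeric(out)
}

#' Decide the DAH-by-canopy interaction by spatial CV
#'
#' Fits the model with and without the interaction tensor between the
#' heat-load index and canopy density, scores both by spatial block CV
#' (same folds, coefficients refit per fold with the term set and
#' smoothing parameters fixed), and keeps the interaction only when it
#' lowers the CV RMSE by more than `margin` (relative).
#'
#' @param data training data.frame.
#' @param response response column name.
#' @param predictors candidate predictor names.
#' @param folds integer fold id per row (spatial blocks; see
#'   [allocateFolds]).
#' @param dahName,praName columns entering the interaction tensor.
#' @param coords coordinate column names.
#' @param control see [boostControl].
#' @param margin required relative RMSE improvement (default 0.03): the
#'   tensor must beat the base model by clearly more than fold-resampling
#'   noise (~2% here) before the extra complexity is accepted.
#' @return the chosen [BoostedGAMModel-class]; attributes `cvRmseWith`
#'   and `cvRmseWithout` carry the comparison.
#' @export
testInteraction <- function(data, response, predictors, folds,
                            dahName = "DAH", praName = "PRA2m",
                            coords = c("x", "y"), control = boostControl(),
                            margin = 0.03) {
  stopifnot(dahName %in% names(data), praName %in% names(data))
  base <- fitBoostedGAM(data, response, predictors, coords, control)
  with <- addInteractionTerm(base, data, response, dahName, praName, control)
  rmseOf <- function(withInteraction) {
    se <- numeric(0)
    for (f in sort(unique(folds))) {
      tr <- folds != f
      trd <- data[tr, , drop = FALSE]
      refit <- refitCoefficients(base, trd, response)
      if (withInteraction)
        refit <- addInteractionTerm(refit, trd, response, dahName, praName,
                                    control)
      pred <- predictSites(refit, data[!tr, , drop = FALSE])
      se <- c(se, sqrt(mean((data[[response]][!tr] - pred)^2)))
    }
    mean(se)
  }
  rWithout <- rmseOf(FALSE); rWith <- rmseOf(TRUE)
  chosen <- if (rWith < (1 - margin) * rWithout) with else base
  attr(chosen, "cvRmseWith") <- rWith
  attr(chosen, "cvRmseWithout") <- rWithout
  chosen
}

# Add the interaction tensor to an already-fitted model as an
# added-variable term: the tensor design is orthogonalized against the
# base model's design (intercept + all fitted smooths), so the base
# coefficients are untouched and the tensor can only pick up structure
# the base model cannot represent. Its smoothing parameter is chosen by
# GCV (with the base model's effective df held fixed).
addInteractionTerm <- function(base, data, response, dahName, praName,
                               control, gamma = 1.4) {
  def <- interactionLearner(data, dahName, praName, control)
  mat <- materializeLearner(def, data, control$df)
  y <- data[[response]]
  n <- length(y)
  # orthogonalize the tensor against the base model's fitted effects
  # (intercept + one column per fitted smooth): low-dimensional, bounded
  # out of sample, and prevents the tensor from absorbing main-effect or
  # spatial structure the base model already represents
  Feff <- vapply(base@terms, function(t)
    as.numeric(evalTermDesign(t, data) %*% t$coef), numeric(n))
  Xbase1 <- cbind(1, Feff)
  Xint <- mat$Bc
  G <- qr.coef(qr(Xbase1), Xint)
  G[!is.finite(G)] <- 0
  XintO <- Xint - Xbase1 %*% G
  resid <- y - predictSites(base, data)
  XtX <- crossprod(XintO); Xtr <- crossprod(XintO, resid)
  edfBase <- sum(vapply(base@terms, `[[`, numeric(1), "edf"))
  rss0 <- sum(resid^2)
  ridge <- diag(1e-8 * max(mean(diag(XtX)), 1e-12), ncol(XintO))
  fitAt <- function(loglam) {
    M <- XtX + exp(loglam) * mat$Pc + ridge
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), Xtr))
    edf <- sum(diag(chol2inv(ch) %*% XtX))
    rss <- max(rss0 - 2 * sum(beta * Xtr) + sum(beta * (XtX %*% beta)), 0)
    list(beta = beta, edf = edf, rss = rss,
         gcv = n * rss / max(n - 1 - gamma * (edfBase + edf), 1)^2)
  }
  opt <- stats::optimize(function(ll) {
    f <- fitAt(ll); if (is.null(f)) 1e300 else f$gcv
  }, c(-10, 20))
  fit <- fitAt(opt$minimum)
  if (is.null(fit)) {
    # numerically degenerate tensor (orthogonalization removed nearly all
    # signal): report a zero-effect term rather than failing
    fit <- list(beta = numeric(ncol(XintO)), edf = 0, rss = rss0)
    opt$minimum <- 20
  }
  out <- base
  out@terms[[def$name]] <- list(
    name = def$name, kind = def$kind, vars = def$vars, bases = mat$bases,
    Z = mat$Z, marginZ = mat$marginZ, orthoGamma = G,
    coef = as.numeric(fit$beta), lambda = exp(opt$minimum), edf = fit$edf,
    shape = NA_character_, trainRange = mat$trainRange)
  yc <- y - mean(y)
  r2 <- 1 - fit$rss / sum(yc^2)
  edfTot <- edfBase + fit$edf
  out@adjR2 <- 1 - (1 - r2) * (n - 1) / max(n - 1 - edfTot, 1)
  out@sigma2 <- fit$rss / max(n - 1 - edfTot, 1)
  out@interactionIncluded <- TRUE
  out
}

# Refit only the coefficients of an existing model on a data subset,
# keeping term set and smoothing parameters fixed.
refitCoefficients <- function(model, data, response) {
  y <- data[[response]]
  Xs <- lapply(model@terms, evalTermDesign, data = data)
  X <- do.call(cbind, Xs)
  ks <- vapply(Xs, ncol, integer(1))
  be <- cumsum(ks); bs <- c(1, utils::head(be, -1) + 1)
  p <- ncol(X)
  Pen <- matrix(0, p, p)
  for (j in seq_along(model@terms)) {
    term <- model@terms[[j]]
    Pen[bs[j]:be[j], bs[j]:be[j]] <- term$lambda * termPenalty(term)
  }
  ybar <- mean(y); yc <- y - ybar
  XtX <- crossprod(X)
  beta <- penalizedSolve(XtX, Pen + diag(1e-7 * mean(diag(XtX)), p),
                         crossprod(X, yc))
  out <- model
  out@intercept <- ybar
  for (j in seq_along(out@terms)) out@terms[[j]]$coef <- beta[bs[j]:be[j]]
  out
}

## ---- serialization --------------------------------------------------------

#' Save / load a fitted model as JSON
#'
#' A self-describing container: response, intercept, per-term kind,
#' variables, knots, centering transform, coefficients, smoothing
#' parameters, training ranges, shapes and the selection seed.
#'
#' @param model a [BoostedGAMModel-class].
#' @param path file path.
#' @export
writeBoostedGAM <- function(model, path) {
  terms <- lapply(model@terms, function(t) list(
    name = t$name, kind = t$kind, vars = t$vars,
    bases = lapply(t$bases, function(b) b[c("knots", "degree", "range", "K")]),
    Z = t$Z, marginZ = t$marginZ, orthoGamma = t$orthoGamma, coef = t$coef,
    lambda = t$lambda, edf = t$edf, shape = t$shape,
    trainRange = t$trainRange))
  obj <- list(container = "microgrid-boosted-gam", version = 1,
              response = model@response, intercept = model@intercept,
              mstop = model@mstop, adjR2 = model@adjR2,
              interactionIncluded = model@interactionIncluded,
              seed = model@seed, sigma2 = model@sigma2, terms = terms)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeBoostedGAM
#' @export
readBoostedGAM <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = TRUE)
  rebuildBasis <- function(b) {
    b$knots <- as.numeric(b$knots); b$range <- as.numeric(b$range)
    d <- diff(diag(b$K), differences = 2)
    b$D <- d; b$P <- crossprod(d)
    b
  }
  terms <- lapply(obj$terms, function(t) {
    t$bases <- lapply(t$bases, rebuildBasis)
    t$Z <- as.matrix(t$Z); t$coef <- as.numeric(t$coef)
    t$marginZ <- if (length(t$marginZ)) lapply(t$marginZ, as.matrix)
    t$orthoGamma <- if (length(t$orthoGamma)) as.matrix(t$orthoGamma)
    t$trainRange <- lapply(t$trainRange, as.numeric)
    t
  })
  names(terms) <- vapply(terms, `[[`, character(1), "name")
  new("BoostedGAMModel", response = obj$response, intercept = obj$intercept,
      terms = terms, mstop = obj$mstop, adjR2 = obj$adjR2,
      interactionIncluded = obj$interactionIncluded, seed = obj$seed,
      sigma2 = obj$sigma2)
}
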