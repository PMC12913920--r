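## P-spline base-learner machinery: B-spline bases with difference
## penalties, sum-to-zero centering, fixed-df smoothers for boosting.

#' Define a univariate P-spline basis
#'
#' Cubic B-splines on equally spaced knots over the training range with a
#' second-order difference penalty on adjacent coefficients (the classic
#' P-spline). Interior knot count, degree and penalty order are
#' configurable.
#'
#' @param x training values (sets the knot range).
#' @param nKnots number of interior knots (default 20).
#' @param degree spline degree (default 3, cubic).
#' @param penaltyOrder difference-penalty order (default 2).
#' @return list describing the basis: `knots` (full extended sequence),
#'   `degree`, `range`, `K` (number of basis functions), `D` (difference
#'   matrix) and `P` (penalty matrix `t(D) %*% D`).
#' @export
psplineBasis <- function(x, nKnots = 20, degree = 3, penaltyOrder = 2) {
  rng <- range(x, finite = TRUE)
  if (diff(rng) <= 0) rng <- rng + c(-0.5, 0.5)
  h <- diff(rng) / (nKnots + 1)
  knots <- seq(rng[1] - degree * h, rng[2] + degree * h, by = h)
  K <- length(knots) - degree - 1
  D <- diff(diag(K), differences = penaltyOrder)
  list(knots = knots, degree = degree, range = rng, K = K,
       D = D, P = crossprod(D))
}

#' Evaluate a P-spline basis
#'
#' Inside the training range this is the raw B-spline design matrix
#' (rows sum to 1). Beyond the range the basis is extended linearly:
#' value and first derivative at the nearest boundary.
#'
#' @param basis result of [psplineBasis].
#' @param x evaluation points.
#' @return design matrix with `basis$K` columns.
#' @export
evalPsplineBasis <- function(basis, x) {
  lo <- basis$range[1]; hi <- basis$range[2]
  xc <- pmin(pmax(x, lo), hi)
  B <- splines::splineDesign(basis$knots, xc, ord = basis$degree + 1, outer.ok = TRUE)
  out <- which(x < lo | x > hi)
  if (length(out)) {
    Bd <- splines::splineDesign(basis$knots, xc[out], ord = basis$degree + 1,
                                derivs = rep(1L, length(out)), outer.ok = TRUE)
    B[out, ] <- B[out, , drop = FALSE] + (x[out] - xc[out]) * Bd
  }
  B
}

# Sum-to-zero constraint: Z spans the null space of colMeans(B).
centeringTransform <- function(B) {
  cm <- colMeans(B)
  qr.Q(qr(matrix(cm, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
}

# Tensor-product design (row-wise Kronecker) and additive penalty.
tensorDesign <- function(B1, B2) {
  n <- nrow(B1); k1 <- ncol(B1); k2 <- ncol(B2)
  B <- matrix(0, n, k1 * k2)
  for (a in seq_len(k1)) {
    B[, (a - 1) * k2 + seq_len(k2)] <- B1[, a] * B2
  }
  B
}

tensorPenalty <- function(P1, P2) {
  k1 <- nrow(P1); k2 <- nrow(P2)
  kronecker(P1, diag(k2)) + kronecker(diag(k1), P2)
}

# Effective df of the penalized smoother B (B'B + lambda P)^-1 B'.
smootherEdf <- function(BtB, P, lambda) {
  M <- BtB + lambda * P
  sum(diag(solve(M, BtB)))
}

# Find lambda giving the target boosting-stage df (trace of the hat
# matrix). Falls back to the nearest attainable df at the search bounds.
lambdaForDf <- function(BtB, P, df, interval = c(-12, 16)) {
  # guard: ridge the penalty's null space so edf is monotone in lambda
  f <- function(loglam) smootherEdf(BtB, P, exp(loglam)) - df
  lo <- f(interval[1]); hi <- f(interval[2])
  if (lo < 0) return(exp(interval[1]))   # even tiny lambda too stiff
  if (hi > 0) return(exp(interval[2]))   # penalty null space >= df
  exp(stats::uniroot(f, interval, tol = 1e-4)$root)
}

# Penalized least squares: solve (X'X + Pen) beta = X'y, with a tiny
# ridge retry on numerically singular systems.
penalizedSolve <- function(XtX, Pen, Xty) {
  M <- XtX + Pen
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch)) {
    ch <- chol(M + diag(1e-8 * mean(diag(M)), nrow(M)))
    warning("rank-deficient penalized system; ridge fallback applied")
  }
  backsolve(ch, forwardsolve(t(ch), Xty))
}
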