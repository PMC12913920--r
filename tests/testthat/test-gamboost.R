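simData <- function(n = 200, seed = 42, f = function(d) 3 * sin(2 * pi * d$x1),
                    noise = 0.25) {
  set.seed(seed)
  d <- data.frame(x = runif(n) * 100, y = runif(n) * 100,
                  x1 = runif(n), x2 = runif(n), x3 = runif(n),
                  x4 = runif(n), x5 = runif(n))
  d$resp <- f(d) + noise * rnorm(n)
  d
}

fastControl <- function(seed = 1, ...) {
  boostControl(mstopGrid = seq(25, 400, by = 25), innerFolds = 5,
               seed = seed, ...)
}

test_that("B-spline bases sum to one inside the range and extend linearly outside", {
  b <- psplineBasis(seq(0, 1, length.out = 50))
  B <- evalPsplineBasis(b, seq(0.01, 0.99, length.out = 31))
  expect_equal(rowSums(B), rep(1, 31), tolerance = 1e-12)
  # penalty is positive semi-definite
  ev <- eigen(b$P, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # a linear function stays linear under extrapolation
  x <- seq(0, 1, length.out = 80)
  coef <- qr.solve(evalPsplineBasis(b, x), 2 + 3 * x)
  xOut <- c(-0.5, -0.1, 1.1, 1.7)
  expect_equal(as.numeric(evalPsplineBasis(b, xOut) %*% coef), 2 + 3 * xOut,
               tolerance = 1e-6)
})

test_that("boosting-stage smoothers hit the fair-selection df", {
  d <- simData()
  ctl <- boostControl()
  defs <- buildCandidates(d, paste0("x", 1:5), control = ctl)
  mats <- lapply(defs, microgrid:::materializeLearner, data = d, df = ctl$df)
  for (m in mats) {
    edf <- microgrid:::smootherEdf(crossprod(m$Bc), m$Pc, m$lambda)
    expect_equal(edf, 4, tolerance = 0.1)
  }
})

test_that("candidate construction counts learners and drops constants", {
  d <- simData()
  defs <- buildCandidates(d, paste0("x", 1:5))
  expect_length(defs, 6)                      # 5 predictors + spatial tensor
  expect_true("SpatialTensor" %in% names(defs))
  d$x9 <- 1
  expect_warning(defs2 <- buildCandidates(d, c(paste0("x", 1:5), "x9")),
                 "constant")
  expect_length(defs2, 6)
  expect_error(buildCandidates(d, c("x1", "nope")), "missing predictor")
})

test_that("componentwise boosting selects the informative predictor and trains monotonically", {
  hits <- 0
  for (s in 1:10) {
    # signal var(3 sin(2 pi U)) = 4.5; SNR 4 -> noise sd sqrt(4.5 / 4)
    d <- simData(seed = 500 + s, noise = sqrt(4.5 / 4))
    ctl <- fastControl(seed = s)
    defs <- buildCandidates(d, paste0("x", 1:5), control = ctl)
    mats <- lapply(defs, microgrid:::materializeLearner, data = d, df = ctl$df)
    res <- l2boost(d$resp, mats, ctl)
    if ("x1" %in% res$selected) hits <- hits + 1
    expect_true(all(diff(res$trainRss) <= 1e-9))
  }
  expect_gte(hits, 9)
})

test_that("degenerate responses give an intercept-only model", {
  d <- simData()
  d$resp <- 5
  m <- fitBoostedGAM(d, "resp", paste0("x", 1:5), control = fastControl())
  expect_length(modelTerms(m), 0)
  expect_equal(predictSites(m, d), rep(5, nrow(d)))
})

test_that("with a single candidate the boosting limit approaches the basis least-squares fit", {
  set.seed(16)
  n <- 150
  d <- data.frame(x = runif(n), y = runif(n), x1 = sort(runif(n)))
  d$resp <- sin(2 * pi * d$x1)      # smooth, noiseless
  ctl <- boostControl()
  def <- buildCandidates(d, "x1", control = ctl)["x1"]
  mat <- lapply(def, microgrid:::materializeLearner, data = d, df = ctl$df)
  run <- microgrid:::boostRun(d$resp, mat, nu = 0.1, mstopMax = 3000)
  fitted <- run$intercept + as.numeric(mat$x1$Bc %*% run$coefs[[1]])
  expect_lt(sqrt(mean((fitted - d$resp)^2)), 1e-3)
})

test_that("the GCV refit recovers term complexity and shape", {
  set.seed(17)
  n <- 220
  d <- data.frame(x = runif(n) * 10, y = runif(n) * 10,
                  x1 = runif(n), x2 = runif(n))
  d$resp <- 2 * d$x1 + 0.1 * rnorm(n)
  m <- fitBoostedGAM(d, "resp", c("x1", "x2"), control = fastControl(seed = 2))
  t1 <- modelTerms(m)[["x1"]]
  expect_equal(t1$edf, 1, tolerance = 0.35)
  expect_equal(t1$shape, "increasing")
  expect_gte(m@adjR2, 0); expect_lte(m@adjR2, 1)

  d$resp <- -(d$x1 - 0.5)^2 * 8 + 0.1 * rnorm(n)
  m2 <- fitBoostedGAM(d, "resp", c("x1", "x2"), control = fastControl(seed = 3))
  expect_equal(modelTerms(m2)[["x1"]]$shape, "unimodal")
})

test_that("shape classification covers the five classes", {
  g <- seq(0, 1, length.out = 100)
  expect_equal(classifyShape(g), "increasing")
  expect_equal(classifyShape(-g), "decreasing")
  expect_equal(classifyShape(-(g - 0.5)^2), "unimodal")
  expect_equal(classifyShape((g - 0.5)^2), "inverse_unimodal")
  expect_equal(classifyShape(rep(0, 100)), "flat")
  wig <- sin(6 * pi * g) + 3 * g
  expect_equal(as.character(classifyShape(wig)), "increasing")
})

test_that("predictions reproduce training fits, respect permutations and name missing columns", {
  d <- simData(seed = 18)
  m <- fitBoostedGAM(d, "resp", paste0("x", 1:3), control = fastControl(seed = 4))
  pr <- predictSites(m, d)
  expect_lt(abs(mean(d$resp - pr)), 1e-9)          # residuals centred
  perm <- sample(nrow(d))
  expect_equal(predictSites(m, d[perm, ]), pr[perm])
  expect_error(predictSites(m, d[, setdiff(names(d), "x1")]),
               "missing predictor column 'x1'")
})

test_that("refitting on a model's own predictions reproduces them", {
  d <- simData(seed = 19)
  m <- fitBoostedGAM(d, "resp", paste0("x", 1:3), control = fastControl(seed = 5))
  d2 <- d
  d2$resp <- predictSites(m, d)
  m2 <- fitBoostedGAM(d2, "resp", paste0("x", 1:3), control = fastControl(seed = 5))
  expect_lt(sqrt(mean((predictSites(m2, d2) - d2$resp)^2)), 1e-3)
})

test_that("model JSON serialization round-trips predictions exactly", {
  d <- simData(seed = 20)
  m <- fitBoostedGAM(d, "resp", paste0("x", 1:3), control = fastControl(seed = 6))
  p <- tempfile(fileext = ".json")
  writeBoostedGAM(m, p)
  m2 <- readBoostedGAM(p)
  expect_equal(predictSites(m2, d), predictSites(m, d), tolerance = 1e-12)
  expect_equal(m2@adjR2, m@adjR2)
  unlink(p)
})

test_that("the penalized refit agrees with an independent GAM implementation", {
  skip_if_not_installed("mgcv")
  set.seed(21)
  n <- 300
  d <- data.frame(x = runif(n), y = runif(n), x1 = runif(n))
  d$resp <- sin(2 * pi * d$x1) + 0.2 * rnorm(n)
  m <- fitBoostedGAM(d, "resp", "x1", control = fastControl(seed = 7))
  g <- mgcv::gam(resp ~ s(x1, bs = "ps", k = 20), data = d, method = "GCV.Cp")
  grid <- data.frame(x = mean(d$x), y = mean(d$y),
                     x1 = seq(0.05, 0.95, length.out = 50))
  pMine <- predictSites(m, grid)
  pRef <- as.numeric(predict(g, grid))
  expect_gt(cor(pMine, pRef), 0.999)
  expect_lt(sqrt(mean((pMine - pRef)^2)), 0.1)
})
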