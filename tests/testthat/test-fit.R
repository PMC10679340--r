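# Minimal hand-built designs for oracle checks.
interceptDesign <- function(E) {
  new("EdgeDesign",
    X = matrix(1, E, 1, dimnames = list(NULL, "intercept")),
    groups = "intercept", penalized = FALSE, penalties = list(),
    dropped = data.frame(), spec = modelSpec("reference", penaltySelection = "none"))
}

test_that("rSquared matches hand computations and rejects constant data", {
  expect_equal(rSquared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(rSquared(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  expect_equal(rSquared(c(1, 2, 3, 4), c(1.5, 1.5, 3.5, 3.5)), 0.8)  # RSS 1, TSS 5
  expect_error(rSquared(rep(1, 4), rep(1, 4)), "constant")
})

test_that("an intercept-only fit returns the mean with R^2 = 0", {
  set.seed(1)
  z <- rnorm(30)
  f <- fitModel(z, interceptDesign(30))
  expect_equal(fittedEdges(f), rep(mean(z), 30))
  expect_equal(pve(f), 0)
  expect_equal(fittedEdges(f) + residualEdges(f), z)
})

test_that("noiseless data generated from the design is recovered exactly", {
  p <- randomParcellation(R = 14L, K = 3L, seed = 2L)
  d <- buildDesign(p, modelSpec("full", basisDim = 6L, penaltySelection = "none"))
  set.seed(3)
  beta <- rnorm(ncol(designMatrix(d)))
  z <- as.numeric(designMatrix(d) %*% beta)
  f <- fitModel(z, d)
  expect_equal(unname(coef(f)), beta, tolerance = 1e-8)
  expect_equal(pve(f), 1, tolerance = 1e-10)
})

test_that("unpenalized fits agree with an independent normal-equations solve", {
  set.seed(4)
  E <- 10L
  X <- cbind(intercept = 1, a = rnorm(E), b = rnorm(E))
  z <- rnorm(E)
  d <- new("EdgeDesign", X = X, groups = c("intercept", "regions", "regions"),
    penalized = rep(FALSE, 3), penalties = list(), dropped = data.frame(),
    spec = modelSpec("reference+regions", penaltySelection = "none"))
  f <- fitModel(z, d)
  expect_equal(unname(coef(f)), olsOracle(X, z), tolerance = 1e-10)
})

test_that("region means of fitted values equal region means of observations", {
  cfg <- syntheticConfig(nSubjects = 1L, nSessions = 1L, R = 20L, K = 4L, seed = 5L)
  ce <- simulateEdges(cfg)
  p <- parcellationOf(ce)
  z <- edgeZ(ce)[, 1]
  M <- regionIndicators(p)
  for (variant in c("full", "reference+regions"))
    for (sel in c("REML", "none")) {
      f <- fitModel(z, buildDesign(p, modelSpec(variant, penaltySelection = sel)))
      mo <- colSums(M * z) / colSums(M)
      mf <- colSums(M * fittedEdges(f)) / colSums(M)
      expect_lt(max(abs(mo - mf)), 1e-8)
    }
})

test_that("residuals are orthogonal to every unpenalized column", {
  cfg <- syntheticConfig(nSubjects = 1L, nSessions = 1L, R = 16L, K = 4L, seed = 6L)
  ce <- simulateEdges(cfg)
  d <- buildDesign(parcellationOf(ce), modelSpec("full"))
  f <- fitModel(edgeZ(ce)[, 1], d)
  U <- designMatrix(d)[, !d@penalized, drop = FALSE]
  expect_lt(max(abs(crossprod(U, residualEdges(f)))), 1e-8)
})

test_that("R^2 is monotone over the nested model ladder under OLS", {
  cfg <- syntheticConfig(nSubjects = 1L, nSessions = 1L, R = 18L, K = 3L, seed = 7L)
  ce <- simulateEdges(cfg)
  p <- parcellationOf(ce)
  z <- edgeZ(ce)[, 1]
  r2 <- vapply(c("reference", "reference+networks", "reference+regions", "full"),
    function(v) pve(fitModel(z, buildDesign(p,
      modelSpec(v, basisDim = 6L, penaltySelection = "none")))), numeric(1))
  expect_gte(r2[["full"]] + 1e-12, r2[["reference+regions"]])
  expect_gte(r2[["full"]] + 1e-12, r2[["reference+networks"]])
  expect_gte(r2[["reference+regions"]] + 1e-12, r2[["reference"]])
  expect_gte(r2[["reference+networks"]] + 1e-12, r2[["reference"]])
})

test_that("vectorized least squares equals the Frobenius-norm matrix regression", {
  for (seed in 1:3) {
    cfg <- syntheticConfig(nSubjects = 1L, nSessions = 1L, R = 10L, K = 2L,
                           seed = seed)
    ce <- simulateEdges(cfg)
    p <- parcellationOf(ce)
    z <- edgeZ(ce)[, 1]
    d <- buildDesign(p, modelSpec("full", basisDim = 4L, penaltySelection = "none"))
    f <- fitModel(z, d)
    A <- edgesToMatrix(z, nRegions(p))
    expect_equal(matrixRegressionCheck(A, d), coef(f), tolerance = 1e-8)
  }
  # intercept-only: the minimizer is the off-diagonal mean
  z <- rnorm(45)
  A <- edgesToMatrix(z, 10)
  b <- matrixRegressionCheck(A, interceptDesign(45))
  expect_equal(unname(b), mean(z), tolerance = 1e-10)
  expect_equal(unname(matrixRegressionCheck(matrix(0, 10, 10), interceptDesign(45))), 0)
})

test_that("fitAllScans fits every scan and returns aligned fitted values", {
  cfg <- syntheticConfig(nSubjects = 2L, nSessions = 2L, R = 12L, K = 3L, seed = 8L)
  ce <- simulateEdges(cfg)
  fa <- fitAllScans(ce, modelSpec("reference", basisDim = 5L))
  expect_length(fa$fits, 4L)
  expect_equal(dim(fa$fitted), dim(edgeZ(ce)))
  expect_equal(fa$fitted[, 2], fittedEdges(fa$fits[[2]]), ignore_attr = TRUE)
})
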