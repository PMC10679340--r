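test_that("region indicators mark both endpoints of every edge", {
  p <- testParcellation()
  M <- regionIndicators(p)
  expect_equal(dim(M), c(15L, 6L))
  expect_equal(M[1, ], c(1, 1, 0, 0, 0, 0), ignore_attr = TRUE)  # edge (1,2)
  expect_equal(unname(rowSums(M)), rep(2, 15))
  expect_equal(unname(colSums(M)), rep(5, 6))  # each region pairs with R-1 others
  # sum of region columns equals twice the intercept column
  expect_equal(unname(rowSums(M)) - 2, rep(0, 15))
})

test_that("network indicators partition edges into K(K+1)/2 cells", {
  p <- randomParcellation(R = 32L, K = 8L, seed = 2L)
  ni <- networkIndicators(p)
  expect_equal(ncol(ni$X), 36L)        # 8 + choose(8,2)
  expect_equal(sum(ni$intra), 8L)
  expect_equal(sum(!ni$intra), 28L)
  expect_equal(unname(rowSums(ni$X)), rep(1, nrow(ni$X)))
  # K = 1: the single intra column duplicates the intercept
  q <- Parcellation(1:4, cbind(c(5, 6, -5, -6), c(0, 10, 0, 10), c(1, 2, 1, 2)),
    hemisphere = c("R", "R", "L", "L"), network = rep(1L, 4))
  n1 <- networkIndicators(q)
  expect_equal(unname(n1$X[, 1]), rep(1, 6))
})

test_that("smooth bases are centered on the mask, zero off it, with a linear penalty null space", {
  p <- randomParcellation(R = 20L, K = 4L, seed = 7L)
  cov <- edgeCovariates(p)
  sb <- smoothBasis(cov$geog_dist, cov$same_hemisphere, 10L, "s")
  expect_true(all(sb$X[!cov$same_hemisphere, ] == 0))
  expect_equal(colSums(sb$X[cov$same_hemisphere, ]), rep(0, ncol(sb$X)),
               tolerance = 1e-8, ignore_attr = TRUE)
  # penalty is PSD
  ev <- eigen(sb$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))
  # the covariate itself lies in the basis span (plus constant), and its
  # representation has zero penalty: the infinite-penalty limit is a line
  d <- cov$geog_dist[cov$same_hemisphere]
  B <- sb$X[cov$same_hemisphere, ]
  fit <- lm(d ~ B)
  expect_lt(max(abs(residuals(fit))), 1e-8)
  b <- coef(fit)[-1]
  expect_lt(abs(t(b) %*% sb$S %*% b), 1e-8)

  expect_error(smoothBasis(rep(1, 10), rep(TRUE, 10)), "distinct")
  expect_warning(smoothBasis(rep(1:4, 5), rep(TRUE, 20), 10L), "reduced")
})

test_that("the assembled design is full rank with deterministic, recorded drops", {
  p <- randomParcellation(R = 20L, K = 4L, seed = 1L)
  d <- buildDesign(p, modelSpec("full"))
  X <- designMatrix(d)
  expect_equal(qr(X)$rank, ncol(X))
  # K+1 dependencies among intercept/region/network indicator columns
  expect_equal(nrow(droppedColumns(d)), nNetworks(p) + 1L)
  expect_setequal(unique(columnGroups(d)),
    c("intercept", "geography", "homotopy", "regions",
      "networks_intra", "networks_inter"))
  # bit-identical across rebuilds
  d2 <- buildDesign(p, modelSpec("full"))
  expect_identical(designMatrix(d2), X)

  ref <- buildDesign(p, modelSpec("reference"))
  expect_equal(nrow(droppedColumns(ref)), 0L)
  expect_setequal(unique(columnGroups(ref)), c("intercept", "geography", "homotopy"))
})

test_that("single-indicator-block designs need exactly one drop", {
  p <- randomParcellation(R = 20L, K = 4L, seed = 1L)
  dn <- buildDesign(p, modelSpec("reference+networks"))
  expect_equal(droppedColumns(dn)$name, "net_4_4")
  expect_equal(sum(columnGroups(dn) %in% c("networks_intra", "networks_inter")),
               nNetworks(p) * (nNetworks(p) + 1) / 2 - 1)
  dr <- buildDesign(p, modelSpec("reference+regions"))
  expect_equal(droppedColumns(dr)$name, "region_20")
  expect_equal(sum(columnGroups(dr) == "regions"), nRegions(p) - 1L)
})

test_that("homotopy basis columns vanish on same-hemisphere pairs", {
  p <- randomParcellation(R = 16L, K = 4L, seed = 4L)
  d <- buildDesign(p, modelSpec("reference"))
  same <- edgeCovariates(p)$same_hemisphere
  H <- designMatrix(d)[, columnGroups(d) == "homotopy", drop = FALSE]
  expect_true(all(H[same, ] == 0))
  expect_gt(max(abs(H[!same, ])), 0)
})

test_that("pre-reduction indicator blocks satisfy the intercept sum identities", {
  p <- randomParcellation(R = 14L, K = 3L, seed = 6L)
  M <- regionIndicators(p)
  N <- networkIndicators(p)$X
  E <- nEdges(p)
  expect_equal(unname(rowSums(M)) - 2 * rep(1, E), rep(0, E))
  expect_equal(unname(rowSums(N)) - rep(1, E), rep(0, E))
})

test_that("design export writes the two-row header dialect", {
  p <- testParcellation()
  d <- buildDesign(p, modelSpec("reference", basisDim = 4L))
  f <- withr::local_tempfile(fileext = ".csv")
  writeDesignMatrix(d, f)
  lines <- readLines(f)
  expect_equal(strsplit(lines[2], ",")[[1]], columnGroups(d))
  expect_equal(length(lines), 2L + nrow(designMatrix(d)))
})
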