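test_that("parcellation TSV loading validates its input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "region_id\tlabel\tx_mm\ty_mm\tz_mm\themisphere\tnetwork",
    "1\ta\t10\t0\t0\tR\t1",
    "2\tb\t-10\t0\t0\tL\t1",
    "3\tc\t5\t20\t0\tR\t1"), f)
  p <- readParcellation(f)
  expect_s4_class(p, "Parcellation")
  expect_equal(nRegions(p), 3L)
  expect_equal(nEdges(p), 3L)

  writeLines(c(
    "region_id\tlabel\tx_mm\ty_mm\tz_mm\themisphere\tnetwork",
    "1\ta\t10\t0\t0\tR\t1",
    "1\tb\t-10\t0\t0\tL\t1",
    "2\tc\t5\t20\t0\tR\t1"), f)
  expect_error(readParcellation(f), "duplicate region_id")

  writeLines(c(
    "region_id\tlabel\tx_mm\ty_mm\tz_mm\themisphere\tnetwork",
    "1\ta\t10\t0\t0\tQ\t1",
    "2\tb\t-10\t0\t0\tL\t1",
    "3\tc\t5\t20\t0\tR\t1"), f)
  expect_error(readParcellation(f), "hemisphere")

  writeLines(c(
    "region_id\tlabel\tx_mm\ty_mm\tz_mm\themisphere\tnetwork",
    "1\ta\t\t0\t0\tR\t1",
    "2\tb\t-10\t0\t0\tL\t1",
    "3\tc\t5\t20\t0\tR\t1"), f)
  expect_error(readParcellation(f), "coordinates")
})

test_that("a written parcellation reads back identically", {
  p <- randomParcellation(R = 20L, K = 4L, seed = 11L)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeParcellation(p, f)
  q <- readParcellation(f)
  expect_equal(regionIds(q), regionIds(p))
  expect_equal(regionCenters(q), regionCenters(p), tolerance = 1e-12)
  expect_equal(hemispheres(q), hemispheres(p))
  expect_equal(networks(q), networks(p))
})

test_that("geographic distance is the Euclidean center distance", {
  p <- Parcellation(1:3,
    rbind(c(0, 0, 0), c(3, 4, 0), c(30, -20, 40)),
    hemisphere = c("R", "R", "R"), network = c(1L, 1L, 1L))
  expect_equal(geographicDistance(p, 1, 2), 5)
  expect_equal(geographicDistance(p, 3, 3), 0)
  q <- Parcellation(1:3,
    rbind(c(30, -20, 40), c(-28, -20, 40), c(0, 0, 0)),
    hemisphere = c("R", "L", "R"), network = c(1L, 1L, 1L))
  expect_equal(geographicDistance(q, 1, 2), 58)
})

test_that("homotopic distance reflects across the mid-sagittal plane", {
  p <- Parcellation(1:3,
    rbind(c(30, -20, 40), c(-30, -20, 40), c(-28, -20, 40)),
    hemisphere = c("R", "L", "L"), network = c(1L, 1L, 1L))
  expect_equal(homotopicDistance(p, 1, 2), 0)       # perfect mirror pair
  expect_equal(homotopicDistance(p, 1, 3), 2)       # reflect then measure
  expect_equal(homotopicDistance(p, 3, 1), 2)       # swap-invariant
})

test_that("hemisphere relation is symmetric and label-driven", {
  p <- testParcellation()
  expect_equal(hemisphereRelation(p, 1, 2), "opposite")
  expect_equal(hemisphereRelation(p, 1, 3), "same")
  pr <- edgePairs(p)
  expect_equal(hemisphereRelation(p, pr$region_i, pr$region_j),
               hemisphereRelation(p, pr$region_j, pr$region_i))
})

test_that("mirror-built parcellations have zero homotopic distance and 2|x| geographic distance per pair", {
  p <- randomParcellation(R = 16L, K = 4L, seed = 3L)
  half <- 8L
  for (r in seq_len(half)) {
    expect_equal(homotopicDistance(p, r, r + half), 0, tolerance = 1e-12)
    expect_equal(geographicDistance(p, r, r + half),
                 unname(2 * abs(regionCenters(p)[r, 1])), tolerance = 1e-12)
  }
})

test_that("homotopic distance is swap-invariant and geographic distance satisfies the triangle inequality", {
  p <- randomParcellation(R = 12L, K = 3L, seed = 5L)
  pr <- edgePairs(p)
  expect_equal(homotopicDistance(p, pr$region_i, pr$region_j),
               homotopicDistance(p, pr$region_j, pr$region_i))
  trip <- t(combn(regionIds(p), 3L))
  dab <- geographicDistance(p, trip[, 1], trip[, 2])
  dbc <- geographicDistance(p, trip[, 2], trip[, 3])
  dac <- geographicDistance(p, trip[, 1], trip[, 3])
  expect_true(all(dac <= dab + dbc + 1e-12))
})

test_that("hemisphere labels are authoritative but sign contradictions warn", {
  expect_warning(
    Parcellation(1:3, rbind(c(10, 0, 0), c(-10, 0, 0), c(5, 1, 1)),
      hemisphere = c("L", "L", "R"), network = c(1L, 1L, 1L)),
    "contradicts")
  # a midline region (x = 0) is consistent with either label
  expect_silent(
    Parcellation(1:3, rbind(c(0, 0, 0), c(-10, 0, 0), c(5, 1, 1)),
      hemisphere = c("L", "L", "R"), network = c(1L, 1L, 1L)))
})

test_that("parcellation invariants are enforced", {
  expect_error(
    Parcellation(c(1L, 1L, 2L), diag(3), c("R", "R", "L"), c(1L, 1L, 1L)),
    "duplicate")
  # network ids must cover 1..K
  expect_error(
    Parcellation(1:3, diag(3), c("R", "R", "L"), c(1L, 3L, 3L)),
    "network")
})
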