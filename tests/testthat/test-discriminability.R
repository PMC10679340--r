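test_that("vector and Wasserstein distances satisfy their defining identities", {
  expect_equal(vectorDistance(c(1, 2), c(1, 2)), 0)
  expect_equal(vectorDistance(c(0, 0), c(3, 4)), 5)
  expect_error(vectorDistance(1:3, 1:2), "length")

  expect_equal(wasserstein2Distance(c(2, 1, 3), c(3, 1, 2)), 0)
  expect_equal(wasserstein2Distance(c(0, 0), c(1, 1)), sqrt(2))
  expect_error(wasserstein2Distance(1:3, 1:2), "cardinality")

  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(12); b <- rnorm(12)
    expect_equal(vectorDistance(a, b), vectorDistance(b, a))
    # rearrangement inequality: matching order statistics is optimal
    expect_lte(wasserstein2Distance(a, b), vectorDistance(a, b) + 1e-12)
  }
})

test_that("the scalar toy reproduces the exhaustive Eq.-2 enumeration", {
  v <- matrix(c(0, 5, 3, 4), ncol = 1)
  subj <- c("s1", "s1", "s2", "s2")
  sess <- c("t1", "t2", "t1", "t2")
  res <- discriminability(measurementSet(v, subj, sess, "ordered_vector"))
  expect_equal(deltaHat(res), 3 / 8)
  expect_equal(res@numerator, 3)
  expect_equal(res@denominator, 8)
  expect_equal(tieCount(res), 1)
  oracle <- discrimByEnumeration(v, subj, sess)
  expect_equal(deltaHat(res), oracle$delta)
  expect_equal(tieCount(res), oracle$ties)
})

test_that("discriminability agrees with exhaustive enumeration on random designs", {
  set.seed(2)
  for (i in 1:5) {
    n <- sample(3:5, 1); Tn <- sample(2:3, 1)
    subj <- rep(sprintf("s%d", 1:n), each = Tn)
    sess <- rep(sprintf("t%d", 1:Tn), n)
    v <- matrix(rnorm(n * Tn * 4), n * Tn, 4)
    mine <- discriminability(measurementSet(v, subj, sess, "ordered_vector"))
    oracle <- discrimByEnumeration(v, subj, sess)
    expect_equal(deltaHat(mine), oracle$delta)
    expect_equal(mine@denominator, oracle$denominator)
  }
})

test_that("perfect separation gives 1, duplicated measurements give 0 with all ties", {
  subj <- rep(c("a", "b"), each = 2)
  sess <- rep(c("t1", "t2"), 2)
  tight <- matrix(c(0, 0.01, 10, 10.01), ncol = 1)
  expect_equal(deltaHat(discriminability(measurementSet(tight, subj, sess))), 1)
  dup <- matrix(rep(1, 4), ncol = 1)
  res <- discriminability(measurementSet(dup, subj, sess))
  expect_equal(deltaHat(res), 0)
  expect_equal(tieCount(res), res@denominator)
})

test_that("i.i.d. measurements give discriminability near one half", {
  set.seed(3)
  vals <- replicate(60, {
    v <- matrix(rnorm(10 * 2 * 3), 20, 3)
    deltaHat(discriminability(measurementSet(v,
      rep(sprintf("s%d", 1:10), each = 2), rep(c("t1", "t2"), 10))))
  })
  expect_lt(abs(mean(vals) - 0.5), 0.02)
})

test_that("discriminability is invariant to rigid motions of ordered vectors", {
  set.seed(4)
  v <- matrix(rnorm(8 * 5), 8, 5)
  subj <- rep(sprintf("s%d", 1:4), each = 2)
  sess <- rep(c("t1", "t2"), 4)
  base <- deltaHat(discriminability(measurementSet(v, subj, sess)))
  Q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))  # random rotation
  moved <- v %*% Q + matrix(rnorm(5), 8, 5, byrow = TRUE)
  expect_equal(deltaHat(discriminability(measurementSet(moved, subj, sess))), base)
})

test_that("multiset discriminability ignores within-measurement order", {
  set.seed(5)
  v <- matrix(rnorm(8 * 6), 8, 6)
  subj <- rep(sprintf("s%d", 1:4), each = 2)
  sess <- rep(c("t1", "t2"), 4)
  base <- deltaHat(discriminability(measurementSet(v, subj, sess, "multiset")))
  shuf <- t(apply(v, 1, sample))
  expect_equal(deltaHat(discriminability(measurementSet(shuf, subj, sess, "multiset"))),
               base)
})

test_that("the estimator is unbiased against a numerically integrated population value", {
  # 1-D Gaussian model: subject means N(0, sb^2), session noise N(0, sw^2).
  # With A = M[i,t1] - M[i,t2], B = M[i,t1] - M[i',t'], (A, B) are jointly
  # normal with Var(A) = 2 sw^2, Var(B) = 2 sb^2 + 2 sw^2, Cov = sw^2, and
  # delta = P(|A| < |B|), computable by 1-D integration.
  sb <- 1; sw <- 1
  vA <- 2 * sw^2; vB <- 2 * sb^2 + 2 * sw^2; cAB <- sw^2
  condVar <- vB - cAB^2 / vA
  delta <- integrate(function(a) {
    mu <- cAB / vA * a
    tail <- 1 - (pnorm((abs(a) - mu) / sqrt(condVar)) -
                 pnorm((-abs(a) - mu) / sqrt(condVar)))
    tail * dnorm(a, sd = sqrt(vA))
  }, -Inf, Inf)$value
  set.seed(6)
  sims <- replicate(250, {
    mu <- rnorm(15, 0, sb)
    v <- matrix(rep(mu, each = 2) + rnorm(30, 0, sw), ncol = 1)
    deltaHat(discriminability(measurementSet(v,
      rep(sprintf("s%d", 1:15), each = 2), rep(c("t1", "t2"), 15))))
  })
  mcErr <- 3 * sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - delta), mcErr + 0.005)
})

test_that("the permutation null is seeded, reproducible, and centered at one half", {
  set.seed(7)
  cfg <- syntheticConfig(nSubjects = 30L, R = 10L, K = 2L, seed = 30L)
  ce <- simulateEdges(cfg)
  ms <- measurementSet(t(edgeZ(ce)), scanSubjects(ce), scanSessions(ce))
  pn1 <- permutationNull(ms, nPerm = 50L, seed = 42L)
  pn2 <- permutationNull(ms, nPerm = 50L, seed = 42L)
  expect_identical(pn1$values, pn2$values)
  expect_equal(pn1$observed, deltaHat(discriminability(ms)))
  expect_lt(abs(pn1$mean - 0.5), 0.05)
  expect_true(pn1$q025 <= pn1$mean && pn1$mean <= pn1$q975)
  expect_error(permutationNull(ms, nPerm = 0L), "nPerm")
})

test_that("identical sessions give perfect discriminability; comparison table is complete", {
  cfg <- syntheticConfig(nSubjects = 4L, R = 12L, K = 3L, sessionSd = 0,
                         seed = 21L)
  ce <- simulateEdges(cfg)
  ms <- measurementSet(t(edgeZ(ce)), scanSubjects(ce), scanSessions(ce))
  res <- discriminability(ms)
  expect_equal(deltaHat(res), 1)
  expect_equal(tieCount(res), 0)

  tab <- compareSummaries(ce, variants = c("reference"), basisDim = 5L)
  expect_setequal(tab$approach, c("edge_at_a_time", "reference", "edge_distribution"))
  expect_equal(tab$distance[tab$approach == "edge_distribution"], "wasserstein2")
  expect_true(all(tab$delta_hat >= 0 & tab$delta_hat <= 1))
})
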