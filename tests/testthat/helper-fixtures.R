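# Deterministic 6-region, 2-network parcellation with two exact mirror pairs
# and one slightly asymmetric pair; used wherever hand-checkable geometry is
# needed.
testParcellation <- function() {
  Parcellation(
    regionId = 1:6,
    centers = rbind(
      c(30, -20, 40),   # 1 R, mirror of 2
      c(-30, -20, 40),  # 2 L
      c(10, 50, 0),     # 3 R, mirror of 4
      c(-10, 50, 0),    # 4 L
      c(40, 0, -10),    # 5 R
      c(-38, 0, -10)),  # 6 L, 2 mm off mirror of 5
    hemisphere = c("R", "L", "R", "L", "R", "L"),
    network = c(1L, 1L, 2L, 2L, 1L, 2L))
}

# Random mirror-paired parcellation via the synthetic generator.
randomParcellation <- function(R = 20L, K = 4L, seed = 1L) {
  makeParcellation(syntheticConfig(R = R, K = K, seed = seed))
}

# Independent ordinary-least-squares oracle: solve the normal equations
# directly (never the package's fitting path).
olsOracle <- function(X, y) {
  as.numeric(solve(crossprod(X), crossprod(X, y)))
}

# Raw (pre-reduction) design blocks per importance group, built from the
# exported block primitives; used by the LMG enumeration oracle so subset
# models keep full block spans.
rawGroupBlocks <- function(parcellation, basisDim = 10L) {
  cov <- edgeCovariates(parcellation)
  opp <- !cov$same_hemisphere
  s0 <- smoothBasis(cov$geog_dist, cov$same_hemisphere, basisDim, "s0")
  s1 <- smoothBasis(cov$geog_dist, opp, basisDim, "s1")
  s2 <- smoothBasis(cov$homotop_dist, opp, basisDim, "s2")
  list(
    geography = cbind(s0$X, s1$X),
    homotopy = s2$X,
    regions = regionIndicators(parcellation),
    networks = networkIndicators(parcellation)$X)
}

# R-squared of an lm() fit of z on the given raw blocks (with intercept);
# lm's pivoting handles the rank-deficient indicator blocks.
lmR2 <- function(z, blocks, groups) {
  if (!length(groups)) return(0)
  X <- do.call(cbind, blocks[groups])
  summary(stats::lm(z ~ X))$r.squared
}

# All permutations of a character vector (small G only).
allOrderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (rest in allOrderings(v[-i]))
      out[[length(out) + 1L]] <- c(v[i], rest)
  out
}

# Literal LMG: average R-squared increments over every ordering of the
# groups, with subset R-squared supplied by `r2fun(subset)`.
lmgByEnumeration <- function(groups, r2fun) {
  contrib <- stats::setNames(numeric(length(groups)), groups)
  orderings <- allOrderings(groups)
  for (ord in orderings) {
    prev <- 0
    sofar <- character(0)
    for (g in ord) {
      sofar <- c(sofar, g)
      r2 <- r2fun(sofar)
      contrib[g] <- contrib[g] + (r2 - prev)
      prev <- r2
    }
  }
  contrib / length(orderings)
}

# Exhaustive Eq.-2 evaluation by direct 5-fold summation over index tuples;
# quadratic and slow, independent of the package's implementation.
discrimByEnumeration <- function(values, subject, session) {
  idx <- seq_along(subject)
  num <- 0; ties <- 0; denom <- 0
  d <- function(a, b) sqrt(sum((values[a, ] - values[b, ])^2))
  for (a in idx) for (b in idx) {
    if (subject[b] != subject[a] || session[b] == session[a]) next
    for (cc in idx) {
      if (subject[cc] == subject[a]) next
      denom <- denom + 1
      if (d(a, b) < d(a, cc)) num <- num + 1
      if (d(a, b) == d(a, cc)) ties <- ties + 1
    }
  }
  list(delta = num / denom, numerator = num, denominator = denom, ties = ties)
}
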