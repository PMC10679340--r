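#' Create a ModelSpec
#'
#' @param variant one of `"reference"`, `"reference+networks"`,
#'   `"reference+regions"`, `"full"`, `"intra_inter"`.
#' @param basisDim basis dimension per smooth term (default 10).
#' @param penaltySelection `"REML"` (default), `"GCV"`, or `"none"` for
#'   unpenalized least squares.
#' @return a [ModelSpec-class].
#' @export
modelSpec <- function(variant = "full", basisDim = 10L,
                      penaltySelection = c("REML", "GCV", "none")) {
  new("ModelSpec", variant = variant, basisDim = as.integer(basisDim),
      penaltySelection = match.arg(penaltySelection))
}

#' Covariate groups implied by a model variant
#'
#' All variants contain the reference smooths (geography, homotopy); the
#' variant adds network membership terms, region terms, both, or splits the
#' network terms into intra- and inter-network groups.
#'
#' @param spec a [ModelSpec-class] or variant string.
#' @return character vector of importance-group labels.
#' @export
variantGroups <- function(spec) {
  v <- if (is(spec, "ModelSpec")) spec@variant else spec
  switch(v,
    "reference" = c("geography", "homotopy"),
    "reference+networks" = c("geography", "homotopy", "networks"),
    "reference+regions" = c("geography", "homotopy", "regions"),
    "full" = c("geography", "homotopy", "networks", "regions"),
    "intra_inter" = c("geography", "homotopy", "networks_intra", "networks_inter"),
    stop(sprintf("unknown variant '%s'", v)))
}

#' Region-involvement indicator matrix
#'
#' Entry `(e, r)` is 1 when region `r` is one of the two endpoints of edge
#' `e`; every row sums to 2 and the column for region `r` sums to `R - 1`.
#'
#' @param parcellation a [Parcellation-class].
#' @return edges x R 0/1 matrix, columns named by region id.
#' @export
regionIndicators <- function(parcellation) {
  R <- nRegions(parcellation)
  pr <- t(combn(R, 2L))
  E <- nrow(pr)
  M <- matrix(0, E, R,
    dimnames = list(NULL, sprintf("region_%d", parcellation@regionId)))
  M[cbind(seq_len(E), pr[, 1L])] <- 1
  M[cbind(seq_len(E), pr[, 2L])] <- 1
  M
}

#' Network membership indicator matrix
#'
#' One column per network cell `(k, k')`, `k <= k'`, ordered
#' `(1,1), (1,2), ..., (1,K), (2,2), ..., (K,K)`. The `(k, k)` columns flag
#' pairs with both endpoints in network `k` (intra); the `(k, k')` columns
#' flag pairs with one endpoint in each (inter). Exactly one entry per row
#' is 1.
#'
#' @param parcellation a [Parcellation-class].
#' @return list with `X` (edges x K(K+1)/2 0/1 matrix, columns named
#'   `net_k_k'`), and `intra` (logical per column).
#' @export
networkIndicators <- function(parcellation) {
  net <- parcellation@network
  if (anyNA(net)) stop("unlabeled region: every region needs a network id")
  K <- nNetworks(parcellation)
  R <- nRegions(parcellation)
  cells <- do.call(rbind, lapply(seq_len(K), function(k) cbind(k, k:K)))
  pr <- t(combn(R, 2L))
  k1 <- pmin(net[pr[, 1L]], net[pr[, 2L]])
  k2 <- pmax(net[pr[, 1L]], net[pr[, 2L]])
  cellOf <- match(paste(k1, k2), paste(cells[, 1L], cells[, 2L]))
  X <- matrix(0, nrow(pr), nrow(cells),
    dimnames = list(NULL, sprintf("net_%d_%d", cells[, 1L], cells[, 2L])))
  X[cbind(seq_len(nrow(pr)), cellOf)] <- 1
  list(X = X, intra = cells[, 1L] == cells[, 2L])
}

#' Masked, centered thin-plate smooth basis
#'
#' Builds a low-rank thin plate regression spline basis (via
#' [mgcv::smoothCon()]) over the covariate values of the masked edges, with
#' the sum-to-zero identifiability constraint absorbed (columns centered over
#' the masked edges). Rows outside the mask are exactly zero. The penalty's
#' null space after centering contains the linear trend, so in the infinite-
#' penalty limit the smooth degenerates to a straight line.
#'
#' @param values numeric per-edge covariate.
#' @param mask logical per-edge inclusion flag.
#' @param basisDim target basis dimension; silently reduced (with a warning)
#'   when the masked covariate has fewer distinct values.
#' @param label name for the smooth (used for penalty bookkeeping).
#' @return list with `X` (edges x (k-1) matrix), `S` (penalty block,
#'   positive semidefinite), `label`.
#' @export
smoothBasis <- function(values, mask = rep(TRUE, length(values)),
                        basisDim = 10L, label = "s") {
  vals <- values[mask]
  nd <- length(unique(vals))
  if (nd < 3L)
    stop(sprintf("smooth '%s': fewer than 3 distinct covariate values", label))
  k <- as.integer(basisDim)
  if (nd < k) {
    warning(sprintf("smooth '%s': basis dimension reduced from %d to %d (distinct values)",
      label, k, nd))
    k <- nd
  }
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "tp", k = k),
    data = data.frame(x = vals), absorb.cons = TRUE)[[1L]]
  X <- matrix(0, length(values), ncol(sm$X),
    dimnames = list(NULL, sprintf("%s.%d", label, seq_len(ncol(sm$X)))))
  X[mask, ] <- sm$X
  list(X = X, S = sm$S[[1L]], label = label)
}

## Assemble the per-group column blocks for a parcellation + spec.
## Returned in canonical order; each block: name (column-group label),
## importance group, X, penalty matrix or NULL.
.designBlocks <- function(parcellation, spec) {
  cov <- edgeCovariates(parcellation)
  opp <- !cov$same_hemisphere
  blocks <- list()
  blocks$intercept <- list(group = "intercept",
    X = matrix(1, nrow(cov), 1L, dimnames = list(NULL, "intercept")), S = NULL)
  s0 <- smoothBasis(cov$geog_dist, cov$same_hemisphere, spec@basisDim, "s0_geog_same")
  s1 <- smoothBasis(cov$geog_dist, opp, spec@basisDim, "s1_geog_opp")
  blocks$s0 <- list(group = "geography", X = s0$X, S = s0$S)
  blocks$s1 <- list(group = "geography", X = s1$X, S = s1$S)
  s2 <- smoothBasis(cov$homotop_dist, opp, spec@basisDim, "s2_homotop_opp")
  blocks$s2 <- list(group = "homotopy", X = s2$X, S = s2$S)
  groups <- variantGroups(spec)
  if ("regions" %in% groups)
    blocks$regions <- list(group = "regions", X = regionIndicators(parcellation),
                           S = NULL)
  if (any(c("networks", "networks_intra", "networks_inter") %in% groups)) {
    ni <- networkIndicators(parcellation)
    lab <- ifelse(ni$intra, "networks_intra", "networks_inter")
    blocks$networks <- list(group = "networks", X = ni$X, S = NULL,
                            colGroup = lab)
  }
  blocks
}

## Deterministic full-rank reduction. Canonical drops first (last region
## indicator; the (K,K) network cell when the whole network block is present
## alongside the intercept), then a greedy forward rank scan in column order
## that drops any remaining dependent column. Columns are unit-normalized
## for the rank test only.
.reduceRank <- function(X, colGroup, canonical) {
  p <- ncol(X)
  keep <- rep(TRUE, p)
  reason <- rep(NA_character_, p)
  for (nm in canonical) {
    j <- match(nm, colnames(X))
    if (!is.na(j)) { keep[j] <- FALSE; reason[j] <- "block-sum collinearity (canonical drop)" }
  }
  nrm <- sqrt(colSums(X^2))
  nrm[nrm == 0] <- 1
  Xn <- sweep(X, 2L, nrm, "/")
  kept <- integer(0)
  for (j in seq_len(p)) {
    if (!keep[j]) next
    cand <- c(kept, j)
    if (qr(Xn[, cand, drop = FALSE], tol = 1e-9)$rank == length(cand)) {
      kept <- cand
    } else {
      keep[j] <- FALSE
      reason[j] <- "linearly dependent (rank scan)"
    }
  }
  dropped <- data.frame(name = colnames(X)[!keep],
                        group = colGroup[!keep],
                        reason = reason[!keep],
                        stringsAsFactors = FALSE)
  list(keep = keep, dropped = dropped)
}

#' Build the design matrix for a model variant
#'
#' Assembles, in fixed order: intercept; centered thin-plate basis for
#' geographic distance on same-hemisphere pairs; the same on
#' opposite-hemisphere pairs; a centered basis for homotopic distance on
#' opposite-hemisphere pairs (no homotopy term exists for same-hemisphere
#' pairs); region-involvement indicators; network membership indicators.
#' The result is then reduced to full column rank deterministically: the
#' last region indicator and the `(K,K)` network cell are the canonical
#' drops, and a greedy forward rank scan in column order removes any
#' remaining dependent columns (when both the region and network blocks are
#' present there are `K+1` dependencies in total, because summing the region
#' indicators over the members of one network reproduces a combination of
#' network columns). Every removal is recorded in `dropped`.
#'
#' The design is a deterministic function of (parcellation, spec): identical
#' inputs give a bit-identical matrix.
#'
#' @param parcellation a [Parcellation-class].
#' @param spec a [ModelSpec-class].
#' @return an [EdgeDesign-class].
#' @export
buildDesign <- function(parcellation, spec = modelSpec()) {
  blocks <- .designBlocks(parcellation, spec)
  .assembleDesign(blocks, names(blocks), parcellation, spec)
}

## Assemble + reduce a subset of blocks (always including the intercept).
## colGroupsWanted optionally restricts the columns (by column-group label,
## e.g. just "networks_intra") BEFORE rank reduction, so subset models keep
## their full span; canonical drops only apply to wholly-present blocks.
.assembleDesign <- function(blocks, include, parcellation, spec,
                            colGroupsWanted = NULL) {
  include <- union("intercept", include)
  include <- names(blocks)[names(blocks) %in% include]
  Xs <- lapply(include, function(b) blocks[[b]]$X)
  X <- do.call(cbind, Xs)
  colGroup <- unlist(lapply(include, function(b) {
    bl <- blocks[[b]]
    if (!is.null(bl$colGroup)) bl$colGroup else rep(bl$group, ncol(bl$X))
  }))
  penalized <- rep(FALSE, ncol(X))
  penaltyOf <- rep(NA_integer_, ncol(X))
  penalties <- list()
  offset <- 0L
  for (b in include) {
    bl <- blocks[[b]]
    cols <- offset + seq_len(ncol(bl$X))
    if (!is.null(bl$S)) {
      penalized[cols] <- TRUE
      penalties[[length(penalties) + 1L]] <- list(label = b, cols = cols, S = bl$S)
      penaltyOf[cols] <- length(penalties)
    }
    offset <- offset + ncol(bl$X)
  }
  if (!is.null(colGroupsWanted)) {
    wanted <- colGroup %in% c("intercept", colGroupsWanted)
    X <- X[, wanted, drop = FALSE]
    colGroup <- colGroup[wanted]
    penalized <- penalized[wanted]
    idx <- cumsum(wanted)
    penalties <- Filter(Negate(is.null), lapply(penalties, function(p) {
      sel <- wanted[p$cols]
      if (!any(sel)) return(NULL)
      p$cols <- idx[p$cols[sel]]
      p$S <- p$S[sel, sel, drop = FALSE]
      p
    }))
  }
  canonical <- character(0)
  if ("regions" %in% include && "regions" %in% colGroup)
    canonical <- c(canonical, sprintf("region_%d", max(parcellation@regionId)))
  if ("networks" %in% include &&
      all(c("networks_intra", "networks_inter") %in% colGroup)) {
    K <- nNetworks(parcellation)
    canonical <- c(canonical, sprintf("net_%d_%d", K, K))
  }
  red <- .reduceRank(X, colGroup, canonical)
  keep <- red$keep
  newIndex <- cumsum(keep)
  penalties <- Filter(Negate(is.null), lapply(penalties, function(p) {
    sel <- keep[p$cols]
    if (!any(sel)) return(NULL)
    p$S <- p$S[sel, sel, drop = FALSE]
    p$cols <- newIndex[p$cols[sel]]
    p
  }))
  new("EdgeDesign",
    X = X[, keep, drop = FALSE],
    groups = colGroup[keep],
    penalized = penalized[keep],
    penalties = penalties,
    dropped = red$dropped,
    spec = spec)
}

#' @describeIn buildDesign retained design matrix of an [EdgeDesign-class].
#' @param design an `EdgeDesign`.
#' @export
designMatrix <- function(design) design@X

#' @describeIn buildDesign column-group labels of an [EdgeDesign-class].
#' @export
columnGroups <- function(design) design@groups

#' @describeIn buildDesign record of columns dropped for rank.
#' @export
droppedColumns <- function(design) design@dropped

#' @export
setMethod("show", "EdgeDesign", function(object) {
  cat(sprintf("EdgeDesign (%s): %d edges x %d columns, %d dropped for rank\n",
    object@spec@variant, nrow(object@X), ncol(object@X), nrow(object@dropped)))
  print(table(object@groups))
})

#' Export a design matrix as CSV with a two-row header
#'
#' First header row: column names; second: group labels; then the numeric
#' matrix. Intended for debugging.
#'
#' @param design an [EdgeDesign-class].
#' @param path file path.
#' @export
writeDesignMatrix <- function(design, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(design@X), collapse = ","), con)
  writeLines(paste(design@groups, collapse = ","), con)
  write.table(design@X, con, sep = ",", col.names = FALSE, row.names = FALSE)
  invisible(path)
}
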