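#' Pearson correlation matrix of region time series
#'
#' @param timeseries numeric T x R matrix (rows = time points, columns =
#'   regions; column names, if present, are taken as region ids).
#' @return symmetric R x R correlation matrix with unit diagonal.
#' @export
correlationMatrix <- function(timeseries) {
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) < 3L)
    stop("need at least 3 time points")
  sds <- apply(timeseries, 2L, sd)
  if (any(sds == 0)) {
    who <- colnames(timeseries)[sds == 0]
    if (is.null(who)) who <- which(sds == 0)
    stop(sprintf("constant time series for region(s): %s", paste(who, collapse = ", ")))
  }
  C <- cor(timeseries)
  # guard against tiny asymmetries from floating point
  (C + t(C)) / 2
}

#' Fisher's Z (variance-stabilizing) transform of a correlation
#'
#' `atanh(r)`, with `|r|` clipped to `1 - 1e-7` (and a warning) so that a
#' perfectly correlated pair yields a large finite value rather than an
#' infinity that would poison downstream Euclidean distances.
#'
#' @param r correlations in `[-1, 1]` (vectorized).
#' @return transformed values; an odd, strictly increasing function of `r`.
#' @export
fisherZ <- function(r) {
  if (any(abs(r) > 1))
    stop("correlation outside [-1, 1]")
  clip <- 1 - 1e-7
  if (any(abs(r) > clip)) {
    warning(sprintf("%d correlation(s) with |r| > %.7f clipped before atanh",
      sum(abs(r) > clip), clip))
    r <- pmin(pmax(r, -clip), clip)
  }
  atanh(r)
}

#' Vectorize the strictly upper triangle of a connectivity matrix
#'
#' Returns the ordered edge vector: entries `A[j, j']` for `j < j'` in
#' row-major order, matching [edgePairs()].
#'
#' @param A symmetric R x R matrix.
#' @param parcellation optional [Parcellation-class]; when given, `R` must
#'   match and the result is ordered by its region ids.
#' @param tol symmetry tolerance.
#' @return numeric vector of length `R*(R-1)/2`.
#' @export
vectorizeEdges <- function(A, parcellation = NULL, tol = 1e-8) {
  A <- as.matrix(A)
  R <- nrow(A)
  if (ncol(A) != R) stop("A must be square")
  if (max(abs(A - t(A))) > tol)
    stop("A is not symmetric within tolerance")
  if (!is.null(parcellation) && R != nRegions(parcellation))
    stop("matrix dimension does not match parcellation")
  pr <- t(combn(R, 2L))
  A[pr]
}

#' Rebuild a symmetric matrix (zero diagonal) from an edge vector
#'
#' Inverse of [vectorizeEdges()] off the diagonal.
#'
#' @param z edge vector of length `R*(R-1)/2` in canonical order.
#' @param R region count.
#' @return symmetric R x R matrix with zero diagonal.
#' @export
edgesToMatrix <- function(z, R) {
  if (length(z) != R * (R - 1L) / 2L)
    stop("edge vector length does not match R")
  A <- matrix(0, R, R)
  pr <- t(combn(R, 2L))
  A[pr] <- z
  A[pr[, 2:1]] <- z
  A
}

#' The edge-distribution view of an edge vector
#'
#' The multiset of edge values, represented by their order statistics
#' (sorted ascending). Invariant to any permutation of the edge order;
#' multiplicities are preserved.
#'
#' @param z numeric edge values.
#' @return sorted numeric vector of the same length.
#' @export
edgeMultiset <- function(z) sort(as.numeric(z))

#' Assemble a ConnectivityExperiment
#'
#' @param z either an edges x N numeric matrix of Fisher-Z values (rows in
#'   canonical edge order), or a list of per-scan symmetric R x R Fisher-Z
#'   matrices (vectorized internally).
#' @param parcellation the [Parcellation-class] the edges refer to.
#' @param subject,session identifiers, one per column/scan.
#' @return a [ConnectivityExperiment-class].
#' @export
ConnectivityExperiment <- function(z, parcellation, subject, session) {
  if (is.list(z))
    z <- vapply(z, vectorizeEdges, numeric(nEdges(parcellation)),
                parcellation = parcellation)
  z <- as.matrix(z)
  subject <- as.character(subject)
  session <- as.character(session)
  colnames(z) <- paste(subject, session, sep = ".")
  cov <- edgeCovariates(parcellation)
  rownames(z) <- paste(cov$region_i, cov$region_j, sep = "_")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(z = z),
    rowData = S4Vectors::DataFrame(cov),
    colData = S4Vectors::DataFrame(subject = subject, session = session))
  new("ConnectivityExperiment", se, parcellation = parcellation)
}

#' Accessors for ConnectivityExperiment
#'
#' @param object a [ConnectivityExperiment-class].
#' @return `parcellationOf`: the embedded [Parcellation-class]; `edgeZ`: the
#'   edges x scans Fisher-Z matrix; `scanSubjects` / `scanSessions`:
#'   per-column identifiers.
#' @name connectivity-accessors
NULL

#' @rdname connectivity-accessors
#' @export
parcellationOf <- function(object) object@parcellation

#' @rdname connectivity-accessors
#' @export
edgeZ <- function(object) SummarizedExperiment::assay(object, "z")

#' @rdname connectivity-accessors
#' @export
scanSubjects <- function(object)
  as.character(SummarizedExperiment::colData(object)$subject)

#' @rdname connectivity-accessors
#' @export
scanSessions <- function(object)
  as.character(SummarizedExperiment::colData(object)$session)

#' @export
setMethod("show", "ConnectivityExperiment", function(object) {
  cat(sprintf("ConnectivityExperiment: %d edges x %d scans (%d subjects, %d sessions)\n",
    nrow(object), ncol(object),
    length(unique(scanSubjects(object))), length(unique(scanSessions(object)))))
  cat(sprintf("  parcellation: %d regions, %d networks\n",
    nRegions(object@parcellation), nNetworks(object@parcellation)))
})

#' Build a ConnectivityExperiment from region time series
#'
#' Correlation, Fisher-Z and vectorization for a set of scans. No temporal
#' preprocessing is applied; time series are taken as given.
#'
#' @param tsList list of T x R time-series matrices, one per scan, columns in
#'   parcellation region order.
#' @inheritParams ConnectivityExperiment
#' @export
connectivityFromTimeSeries <- function(tsList, parcellation, subject, session) {
  mats <- lapply(tsList, function(ts) {
    C <- correlationMatrix(ts)
    diag(C) <- 0  # self-correlations are not edges; avoids spurious clipping
    fisherZ(C)
  })
  ConnectivityExperiment(mats, parcellation, subject, session)
}

#' Read / write edge tables as long-format CSV
#'
#' Columns `subject_id, session_id, region_i, region_j, z`; edges appear in
#' canonical order within each scan.
#'
#' @param object a [ConnectivityExperiment-class].
#' @param path file path.
#' @export
writeEdgeTable <- function(object, path) {
  cov <- as.data.frame(SummarizedExperiment::rowData(object))
  z <- edgeZ(object)
  subj <- scanSubjects(object); sess <- scanSessions(object)
  out <- do.call(rbind, lapply(seq_len(ncol(z)), function(c)
    data.frame(subject_id = subj[c], session_id = sess[c],
               region_i = cov$region_i, region_j = cov$region_j, z = z[, c])))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEdgeTable
#' @param parcellation the [Parcellation-class] the edges refer to.
#' @return [readEdgeTable()]: a [ConnectivityExperiment-class].
#' @export
readEdgeTable <- function(path, parcellation) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "session_id", "region_i", "region_j", "z")
  if (!all(need %in% colnames(df)))
    stop(sprintf("edge table lacks column(s): %s",
      paste(setdiff(need, colnames(df)), collapse = ", ")))
  cov <- edgeCovariates(parcellation)
  key <- paste(cov$region_i, cov$region_j, sep = "_")
  scans <- unique(df[, c("subject_id", "session_id")])
  z <- vapply(seq_len(nrow(scans)), function(s) {
    sub <- df[df$subject_id == scans$subject_id[s] &
              df$session_id == scans$session_id[s], ]
    v <- setNames(sub$z, paste(sub$region_i, sub$region_j, sep = "_"))
    if (!all(key %in% names(v)))
      stop("edge table is missing region pairs for a scan")
    as.numeric(v[key])
  }, numeric(nrow(cov)))
  ConnectivityExperiment(z, parcellation,
    subject = scans$subject_id, session = scans$session_id)
}

#' Read a square connectivity-matrix CSV
#'
#' R x R numeric values with region ids as header row and first column.
#'
#' @param path file path.
#' @return symmetric numeric matrix with region-id dimnames.
#' @export
readConnectivityMatrix <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  storage.mode(m) <- "double"
  m
}
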