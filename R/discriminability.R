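#' Euclidean distance between two ordered vectors
#'
#' @param a,b numeric vectors of equal length.
#' @return the Euclidean norm of `a - b`.
#' @export
vectorDistance <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  sqrt(sum((a - b)^2))
}

#' 2-Wasserstein distance between two multisets
#'
#' For one-dimensional empirical distributions of equal size this is simply
#' the Euclidean distance between the vectors of order statistics, so it is
#' invariant to the order in which values are listed and never exceeds the
#' Euclidean distance of the same values in any fixed common order
#' (rearrangement inequality).
#'
#' @param a,b numeric value collections of equal cardinality.
#' @return the distance.
#' @export
wasserstein2Distance <- function(a, b) {
  if (length(a) != length(b)) stop("cardinality mismatch")
  sqrt(sum((sort(a) - sort(b))^2))
}

#' Construct a MeasurementSet
#'
#' @param values numeric (n*T) x p matrix, one measurement per row; or a
#'   list of equal-length numeric vectors.
#' @param subject,session identifiers per row (complete design required).
#' @param kind `"ordered_vector"` (Euclidean distance) or `"multiset"`
#'   (2-Wasserstein).
#' @return a [MeasurementSet-class].
#' @export
measurementSet <- function(values, subject, session,
                           kind = c("ordered_vector", "multiset")) {
  if (is.list(values)) values <- do.call(rbind, values)
  values <- as.matrix(values)
  new("MeasurementSet", values = values,
      subject = as.character(subject), session = as.character(session),
      kind = match.arg(kind))
}

## Pairwise distance matrix for a MeasurementSet. For multisets each row is
## sorted first, after which Euclidean distance IS the 2-Wasserstein
## distance.
.distanceMatrix <- function(ms) {
  v <- ms@values
  if (ms@kind == "multiset")
    v <- t(apply(v, 1L, sort))
  as.matrix(dist(v))
}

## Eq.-2 evaluation from a precomputed distance matrix and labels.
## Strict inequality; ties contribute 0 and are counted.
.discrimFromD <- function(D, subject, session) {
  n <- length(unique(subject))
  Tn <- length(unique(session))
  num <- 0; ties <- 0
  for (a in seq_len(nrow(D))) {
    partners <- which(subject == subject[a] & session != session[a])
    others <- which(subject != subject[a])
    for (b in partners) {
      num <- num + sum(D[a, others] > D[a, b])
      ties <- ties + sum(D[a, others] == D[a, b])
    }
  }
  list(numerator = num, ties = ties,
       denominator = n * (n - 1) * Tn^2 * (Tn - 1), n = n, T = Tn)
}

#' Sample discriminability (test-retest repeatability U-statistic)
#'
#' The proportion, over all valid comparisons, of cases where two
#' measurements of the same subject are strictly closer than a measurement
#' of that subject and one of a different subject:
#' `delta_hat = sum I(d(M[i,t1], M[i,t2]) < d(M[i,t1], M[i',t'])) /
#'   (n (n-1) T^2 (T-1))`.
#' An unbiased and consistent estimator of the population discriminability.
#' The inequality is strict: exactly tied comparisons contribute 0 to the
#' numerator and are reported in `ties` so degenerate data are detectable.
#' The distance follows the measurement kind: Euclidean for ordered vectors,
#' 2-Wasserstein for multisets.
#'
#' @param ms a [MeasurementSet-class].
#' @return a [DiscriminabilityResult-class].
#' @export
discriminability <- function(ms) {
  stopifnot(is(ms, "MeasurementSet"))
  validObject(ms)
  D <- .distanceMatrix(ms)
  r <- .discrimFromD(D, ms@subject, ms@session)
  new("DiscriminabilityResult",
    deltaHat = r$numerator / r$denominator,
    numerator = r$numerator, denominator = r$denominator, ties = r$ties,
    n = as.integer(r$n), T = as.integer(r$T),
    distance = if (ms@kind == "multiset") "wasserstein2" else "euclidean")
}

#' @describeIn discriminability the point estimate of an
#'   [DiscriminabilityResult-class].
#' @param object a `DiscriminabilityResult`.
#' @export
deltaHat <- function(object) object@deltaHat

#' @describeIn discriminability tie diagnostics.
#' @export
tieCount <- function(object) object@ties

#' @export
setMethod("show", "DiscriminabilityResult", function(object) {
  cat(sprintf(
    "DiscriminabilityResult: delta_hat = %.4f (%d / %d, %d ties; n = %d, T = %d, %s)\n",
    object@deltaHat, object@numerator, object@denominator, object@ties,
    object@n, object@T, object@distance))
})

#' Permutation reference distribution of discriminability
#'
#' Re-pairs each subject's session-1 measurement with the session-2
#' measurement of a uniformly random subject (fixed points allowed) and
#' recomputes the discriminability estimator for each permutation. For
#' continuously distributed measurements, pairing a subject with a random
#' other subject destroys the within-subject signal, so the permuted
#' estimator averages 0.50.
#'
#' @param ms a [MeasurementSet-class] with exactly `T = 2` sessions.
#' @param nPerm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return list with `values` (one estimate per permutation), `mean`,
#'   `q025`, `q975` (central 95% empirical interval), `observed` (the
#'   unpermuted estimate), `nPerm`, `seed`.
#' @export
permutationNull <- function(ms, nPerm = 1000L, seed = 1L) {
  stopifnot(is(ms, "MeasurementSet"))
  validObject(ms)
  if (nPerm < 1L) stop("nPerm must be at least 1")
  sessions <- sort(unique(ms@session))
  if (length(sessions) != 2L)
    stop("permutation null requires exactly T = 2 sessions")
  D <- .distanceMatrix(ms)
  obs <- .discrimFromD(D, ms@subject, ms@session)
  s2 <- which(ms@session == sessions[2L])
  subj2 <- ms@subject[s2]
  set.seed(seed)
  values <- vapply(seq_len(nPerm), function(p) {
    lab <- ms@subject
    lab[s2] <- subj2[sample(length(subj2))]
    r <- .discrimFromD(D, lab, ms@session)
    r$numerator / r$denominator
  }, numeric(1L))
  list(values = values, mean = mean(values),
       q025 = as.numeric(quantile(values, 0.025)),
       q975 = as.numeric(quantile(values, 0.975)),
       observed = obs$numerator / obs$denominator,
       nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Compare discriminability across connectivity summaries
#'
#' One row per approach: the edge-at-a-time approach (raw Fisher-Z edge
#' vectors, Euclidean distance), each requested connectivity regression
#' variant (vectors of fitted values, Euclidean distance), and the edge
#' distribution approach (the multiset of edge values, 2-Wasserstein
#' distance).
#'
#' @param object a [ConnectivityExperiment-class] with a complete
#'   subject-by-session design.
#' @param variants character vector of model variants to fit.
#' @param basisDim,penaltySelection passed to [modelSpec()].
#' @return `data.frame` with columns `approach`, `delta_hat`, `numerator`,
#'   `denominator`, `ties`, `n`, `T`, `distance`.
#' @export
compareSummaries <- function(object, variants = c("reference", "full"),
                             basisDim = 10L, penaltySelection = "REML") {
  z <- edgeZ(object)
  subj <- scanSubjects(object); sess <- scanSessions(object)
  rows <- list()
  asRow <- function(approach, res) data.frame(approach = approach,
    delta_hat = res@deltaHat, numerator = res@numerator,
    denominator = res@denominator, ties = res@ties,
    n = res@n, T = res@T, distance = res@distance)
  rows$edge <- asRow("edge_at_a_time",
    discriminability(measurementSet(t(z), subj, sess, "ordered_vector")))
  for (v in variants) {
    fa <- fitAllScans(object, modelSpec(v, basisDim, penaltySelection))
    rows[[v]] <- asRow(v,
      discriminability(measurementSet(t(fa$fitted), subj, sess, "ordered_vector")))
  }
  rows$dist <- asRow("edge_distribution",
    discriminability(measurementSet(t(z), subj, sess, "multiset")))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
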