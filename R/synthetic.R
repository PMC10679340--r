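#' Create a SyntheticConfig
#'
#' Defaults describe the generator's reference conditions: 20 subjects, 2
#' sessions, 20 mirror-paired regions in 4 networks, exponential distance
#' decay (amplitude 0.6, length scale 40 mm), exponential homotopy effect on
#' opposite-hemisphere pairs (0.4, 30 mm), region effects with sd 0.1,
#' network-cell effects with sd 0.15, subject-level perturbation sds of 0.05
#' (intercept), 0.1 (smooth amplitudes), 0.05 (region effects), 0.05
#' (network effects) and 0.1 (a subject-specific per-edge effect stable
#' across sessions, emulating subject-private connectivity structure not
#' captured by any covariate), and session noise sd 0.1.
#'
#' @param nSubjects,nSessions,R,K design sizes (`R` even, `R >= 2K`).
#' @param beta0,geogAmp,geogScale,homotAmp,homotScale fixed-effect settings.
#' @param regionSd,networkSd population effect sds.
#' @param subjectInterceptSd,subjectAmpSd,subjectRegionSd,subjectNetworkSd,subjectEdgeSd
#'   subject-level perturbation sds.
#' @param sessionSd per-session measurement noise sd.
#' @param seed mandatory integer seed.
#' @return a [SyntheticConfig-class].
#' @export
syntheticConfig <- function(nSubjects = 20L, nSessions = 2L, R = 20L, K = 4L,
                            beta0 = 0.3,
                            geogAmp = 0.6, geogScale = 40,
                            homotAmp = 0.4, homotScale = 30,
                            regionSd = 0.1, networkSd = 0.15,
                            subjectInterceptSd = 0.05, subjectAmpSd = 0.1,
                            subjectRegionSd = 0.05, subjectNetworkSd = 0.05,
                            subjectEdgeSd = 0.1, sessionSd = 0.1,
                            seed) {
  if (missing(seed)) stop("seed is mandatory")
  new("SyntheticConfig",
    nSubjects = as.integer(nSubjects), nSessions = as.integer(nSessions),
    R = as.integer(R), K = as.integer(K),
    beta0 = beta0, geogAmp = geogAmp, geogScale = geogScale,
    homotAmp = homotAmp, homotScale = homotScale,
    regionSd = regionSd, networkSd = networkSd,
    subjectInterceptSd = subjectInterceptSd, subjectAmpSd = subjectAmpSd,
    subjectRegionSd = subjectRegionSd, subjectNetworkSd = subjectNetworkSd,
    subjectEdgeSd = subjectEdgeSd, sessionSd = sessionSd,
    seed = as.integer(seed))
}

#' Generate a mirror-paired synthetic parcellation
#'
#' Samples `R/2` region centers uniformly in the right half-space
#' (lateral coordinate in 8-65 mm, anterior-posterior -90-55 mm, axial
#' -45-65 mm, roughly an adult MNI bounding box) and mirrors them across the
#' mid-sagittal plane, so every region has a partner with homotopic distance
#' exactly zero. Networks are assigned mirror-symmetrically (partners share
#' a network) with every network represented. Deterministic given the
#' config's seed.
#'
#' @param config a [SyntheticConfig-class].
#' @return a [Parcellation-class] with `R` regions.
#' @export
makeParcellation <- function(config) {
  if (config@R %% 2L != 0L) stop("R must be even")
  set.seed(config@seed)
  half <- config@R / 2L
  right <- cbind(x_mm = runif(half, 8, 65),
                 y_mm = runif(half, -90, 55),
                 z_mm = runif(half, -45, 65))
  left <- right
  left[, 1L] <- -left[, 1L]
  net <- sample(rep_len(seq_len(config@K), half))
  Parcellation(
    regionId = seq_len(config@R),
    centers = rbind(right, left),
    hemisphere = c(rep("R", half), rep("L", half)),
    network = c(net, net))
}

#' Simulate multi-subject, multi-session edge data with known structure
#'
#' The generative model mirrors the additive regression structure: for
#' subject `i`, edge `(j, j')`,
#' `z = beta0_i + geogAmp_i * exp(-d/geogScale)
#'    + [opposite] * homotAmp_i * exp(-h/homotScale)
#'    + u_i[j] + u_i[j'] + gamma_i[cell(j,j')] + e_i[edge] + noise`,
#' where each subject-level quantity is the population value plus a Gaussian
#' perturbation, `e_i` is the subject-specific edge-level effect (stable
#' across sessions), and the final term is i.i.d. session noise. The truth
#' functions are smooth exponentials, not splines, so fitted smooths must
#' approximate rather than memorize them.
#'
#' The complete ground truth (population effects, every per-subject
#' coefficient, the noiseless covariate signal and total signal per subject)
#' is stored in `metadata(result)$truth`.
#'
#' @param config a [SyntheticConfig-class].
#' @param parcellation optionally a pre-built [Parcellation-class]
#'   (defaults to [makeParcellation()] on the same config).
#' @return a [ConnectivityExperiment-class] with
#'   `nSubjects * nSessions` columns.
#' @export
simulateEdges <- function(config, parcellation = makeParcellation(config)) {
  cov <- edgeCovariates(parcellation)
  E <- nrow(cov)
  R <- nRegions(parcellation)
  K <- nNetworks(parcellation)
  net <- networks(parcellation)
  iIdx <- match(cov$region_i, regionIds(parcellation))
  jIdx <- match(cov$region_j, regionIds(parcellation))
  cellNames <- {
    cells <- do.call(rbind, lapply(seq_len(K), function(k) cbind(k, k:K)))
    sprintf("net_%d_%d", cells[, 1L], cells[, 2L])
  }
  cellOf <- sprintf("net_%d_%d", pmin(net[iIdx], net[jIdx]),
                    pmax(net[iIdx], net[jIdx]))
  opp <- as.numeric(!cov$same_hemisphere)
  gBase <- exp(-cov$geog_dist / config@geogScale)
  hBase <- exp(-cov$homotop_dist / config@homotScale) * opp

  set.seed(config@seed + 1L)
  u <- rnorm(R, 0, config@regionSd)
  gamma <- setNames(rnorm(length(cellNames), 0, config@networkSd), cellNames)

  n <- config@nSubjects
  Tn <- config@nSessions
  subjects <- sprintf("sub%03d", seq_len(n))
  perSubject <- vector("list", n)
  names(perSubject) <- subjects
  z <- matrix(0, E, n * Tn)
  subjCol <- character(n * Tn)
  sessCol <- character(n * Tn)
  col <- 0L
  for (i in seq_len(n)) {
    si <- list(
      beta0 = config@beta0 + rnorm(1L, 0, config@subjectInterceptSd),
      geogAmp = config@geogAmp + rnorm(1L, 0, config@subjectAmpSd),
      homotAmp = config@homotAmp + rnorm(1L, 0, config@subjectAmpSd),
      region = u + rnorm(R, 0, config@subjectRegionSd),
      network = gamma + rnorm(length(gamma), 0, config@subjectNetworkSd),
      edgeEffect = rnorm(E, 0, config@subjectEdgeSd))
    covSignal <- si$beta0 + si$geogAmp * gBase + si$homotAmp * hBase +
      si$region[iIdx] + si$region[jIdx] + as.numeric(si$network[cellOf])
    signal <- covSignal + si$edgeEffect
    si$covSignal <- covSignal
    si$signal <- signal
    perSubject[[i]] <- si
    for (t in seq_len(Tn)) {
      col <- col + 1L
      z[, col] <- signal + rnorm(E, 0, config@sessionSd)
      subjCol[col] <- subjects[i]
      sessCol[col] <- sprintf("ses%d", t)
    }
  }
  ce <- ConnectivityExperiment(z, parcellation, subjCol, sessCol)
  S4Vectors::metadata(ce)$truth <- list(
    config = config,
    population = list(region = u, network = gamma),
    subjects = perSubject)
  S4Vectors::metadata(ce)$seed <- config@seed
  ce
}

#' Population variance-budget proportion of variation explained
#'
#' For each simulated subject, the share of total edge variance the
#' covariate structure accounts for:
#' `var(covariate signal) / (var(covariate signal) + subjectEdgeSd^2 +
#' sessionSd^2)`, using the realized covariate signal over the enumerated
#' edges. This is the population R-squared a correctly specified model would
#' attain on that subject's data.
#'
#' @param object a [ConnectivityExperiment-class] produced by
#'   [simulateEdges()].
#' @return named numeric vector, one value per subject.
#' @export
truePVE <- function(object) {
  truth <- S4Vectors::metadata(object)$truth
  if (is.null(truth)) stop("object carries no generator ground truth")
  cfg <- truth$config
  E <- nrow(object)
  vapply(truth$subjects, function(si) {
    vc <- var(si$covSignal) * (E - 1) / E
    vc / (vc + cfg@subjectEdgeSd^2 + cfg@sessionSd^2)
  }, numeric(1L))
}

#' Generate Gaussian time series matching simulated connectivity
#'
#' Optional end-to-end mode: for each scan, back-transforms the Fisher-Z
#' edge matrix to correlations, projects to the nearest positive-definite
#' correlation matrix (eigenvalue clipping), and draws `nTimepoints`
#' i.i.d. Gaussian vectors with that correlation. Intended for small `R`
#' only; the empirical correlations of the output approach the target as
#' `nTimepoints` grows.
#'
#' @param object a [ConnectivityExperiment-class].
#' @param nTimepoints number of time points per scan.
#' @param seed integer seed.
#' @return named list of T x R time-series matrices, one per scan.
#' @export
simulateTimeSeries <- function(object, nTimepoints = 200L, seed = 1L) {
  set.seed(seed)
  parc <- parcellationOf(object)
  R <- nRegions(parc)
  z <- edgeZ(object)
  out <- lapply(seq_len(ncol(z)), function(c) {
    C <- tanh(edgesToMatrix(z[, c], R))
    diag(C) <- 1
    eg <- eigen(C, symmetric = TRUE)
    vals <- pmax(eg$values, 1e-6)
    C <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(C))
    C <- C / tcrossprod(d)
    ts <- matrix(rnorm(nTimepoints * R), nTimepoints, R) %*% chol(C)
    colnames(ts) <- regionIds(parc)
    ts
  })
  names(out) <- colnames(z)
  out
}
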