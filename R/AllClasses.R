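#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats cor dist quantile rnorm runif sd var integrate pnorm dnorm setNames coef
#' @importFrom utils read.delim write.table read.csv write.csv combn head
NULL

#' Parcellation: region geometry and network labels
#'
#' An atlas-style parcellation: one row per region of interest (ROI), with a
#' center coordinate in mm (first axis lateral, mid-sagittal plane at 0), a
#' hemisphere label, and a functional-network label in `1..K`. The
#' parcellation fixes the coordinate frame for every distance covariate used
#' by the connectivity regression models.
#'
#' @slot regionId integer vector of unique region ids, ascending.
#' @slot label character vector of region names.
#' @slot centers numeric R x 3 matrix of center coordinates (mm), columns
#'   `x_mm`, `y_mm`, `z_mm`; `x_mm` is the lateral axis.
#' @slot hemisphere character vector, `"L"` or `"R"` per region.
#' @slot network integer vector of network memberships in `1..K`.
#'
#' @export
setClass("Parcellation",
  representation(
    regionId = "integer",
    label = "character",
    centers = "matrix",
    hemisphere = "character",
    network = "integer"
  )
)

setValidity("Parcellation", function(object) {
  R <- length(object@regionId)
  msg <- character(0)
  if (R < 3L)
    msg <- c(msg, "a parcellation needs at least 3 regions")
  if (anyDuplicated(object@regionId))
    msg <- c(msg, sprintf("duplicate region_id: %s",
      paste(unique(object@regionId[duplicated(object@regionId)]), collapse = ", ")))
  if (is.unsorted(object@regionId))
    msg <- c(msg, "regions must be ordered by region_id ascending")
  if (length(object@label) != R || length(object@hemisphere) != R ||
      length(object@network) != R || nrow(object@centers) != R)
    msg <- c(msg, "all per-region slots must have one entry per region")
  if (ncol(object@centers) != 3L)
    msg <- c(msg, "centers must be an R x 3 matrix")
  if (anyNA(object@centers))
    msg <- c(msg, "missing center coordinates")
  if (!all(object@hemisphere %in% c("L", "R")))
    msg <- c(msg, sprintf("unknown hemisphere token: %s",
      paste(setdiff(unique(object@hemisphere), c("L", "R")), collapse = ", ")))
  K <- suppressWarnings(max(object@network))
  if (anyNA(object@network) || (length(object@network) && any(object@network < 1L)))
    msg <- c(msg, "network labels must be positive integers")
  else if (R >= 3L && !all(seq_len(K) %in% object@network))
    msg <- c(msg, "every network id in 1..K must label at least one region")
  if (length(msg)) msg else TRUE
})

#' Model specification for a connectivity regression variant
#'
#' @slot variant one of `"reference"`, `"reference+networks"`,
#'   `"reference+regions"`, `"full"`, `"intra_inter"`. All variants include
#'   the intercept and the reference smooths (geographic distance split by
#'   hemisphere relation, homotopic distance on opposite-hemisphere pairs).
#' @slot basisDim integer, target basis dimension per smooth term.
#' @slot penaltySelection `"REML"`, `"GCV"`, or `"none"` (unpenalized
#'   ordinary least squares, useful for exact nesting arguments).
#'
#' @export
setClass("ModelSpec",
  representation(
    variant = "character",
    basisDim = "integer",
    penaltySelection = "character"
  )
)

.variants <- c("reference", "reference+networks", "reference+regions",
               "full", "intra_inter")

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (!object@variant %in% .variants)
    msg <- c(msg, sprintf("unknown variant '%s'", object@variant))
  if (object@basisDim < 3L)
    msg <- c(msg, "basisDim must be at least 3")
  if (!object@penaltySelection %in% c("REML", "GCV", "none"))
    msg <- c(msg, "penaltySelection must be REML, GCV or none")
  if (length(msg)) msg else TRUE
})

#' Multi-subject, multi-session edge data
#'
#' A [SummarizedExperiment::SummarizedExperiment] whose rows are region pairs
#' (edges, strictly-upper-triangular row-major order by ascending region id)
#' and whose columns are subject-session scans. The `"z"` assay holds the
#' Fisher-Z transformed correlations; `rowData` carries the per-edge
#' covariates (region ids, geographic distance, homotopic distance,
#' hemisphere relation); `colData` carries `subject` and `session`.
#'
#' @slot parcellation the [Parcellation-class] the edges refer to.
#'
#' @export
setClass("ConnectivityExperiment",
  contains = "SummarizedExperiment",
  representation(parcellation = "Parcellation")
)

setValidity("ConnectivityExperiment", function(object) {
  msg <- character(0)
  if (!"z" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'z' is required")
  R <- length(object@parcellation@regionId)
  if (nrow(object) != R * (R - 1L) / 2L)
    msg <- c(msg, "row count must be R*(R-1)/2 for the parcellation")
  if (!all(c("subject", "session") %in% colnames(SummarizedExperiment::colData(object))))
    msg <- c(msg, "colData must contain 'subject' and 'session'")
  z <- SummarizedExperiment::assay(object, "z")
  if (length(z) && !all(is.finite(z)))
    msg <- c(msg, "all z values must be finite")
  if (length(msg)) msg else TRUE
})

#' Column-grouped design matrix for one model variant
#'
#' The assembled covariate matrix for an edge set: intercept, centered
#' thin-plate smooth bases, region-involvement indicators and network
#' membership indicators, reduced to full column rank with the removed
#' columns recorded.
#'
#' @slot X numeric edges x p matrix (retained columns only).
#' @slot groups character group label per retained column, from
#'   `intercept`, `geography`, `homotopy`, `regions`, `networks_intra`,
#'   `networks_inter`.
#' @slot penalized logical per retained column; `TRUE` only for smooth-basis
#'   columns.
#' @slot penalties list of smooth penalty blocks, each `list(label, cols, S)`
#'   with `cols` indexing retained columns.
#' @slot dropped data.frame of removed columns (`name`, `group`, `reason`).
#' @slot spec the [ModelSpec-class] the design realizes.
#'
#' @export
setClass("EdgeDesign",
  representation(
    X = "matrix",
    groups = "character",
    penalized = "logical",
    penalties = "list",
    dropped = "data.frame",
    spec = "ModelSpec"
  )
)

setValidity("EdgeDesign", function(object) {
  msg <- character(0)
  p <- ncol(object@X)
  if (length(object@groups) != p || length(object@penalized) != p)
    msg <- c(msg, "groups and penalized must have one entry per column")
  if (length(msg)) msg else TRUE
})

#' A fitted subject-level connectivity regression
#'
#' @slot spec the [ModelSpec-class] fitted.
#' @slot coefficients named numeric vector over retained design columns.
#' @slot sp named numeric vector of selected smoothing parameters (empty for
#'   unpenalized fits).
#' @slot fitted numeric per-edge fitted values.
#' @slot residuals numeric per-edge residuals.
#' @slot rSquared unadjusted proportion of variation explained, 1 - RSS/TSS.
#' @slot edf effective degrees of freedom of the fit.
#' @slot groups group label per coefficient.
#' @slot subject,session identifiers of the scan the model was fit to.
#'
#' @export
setClass("ConnectivityFit",
  representation(
    spec = "ModelSpec",
    coefficients = "numeric",
    sp = "numeric",
    fitted = "numeric",
    residuals = "numeric",
    rSquared = "numeric",
    edf = "numeric",
    groups = "character",
    subject = "character",
    session = "character"
  )
)

#' Group-wise relative importance decomposition
#'
#' The orderings-averaged (LMG/Shapley) partition of a model's proportion of
#' variation explained into covariate-group contributions, together with
#' per-predictor relative importance (group contribution divided by the
#' nominal predictor count of the group, reported x100).
#'
#' @slot groupPVE named numeric, proportion of variation explained per group;
#'   sums to `total`.
#' @slot perPredictor named numeric, `100 * groupPVE / groupSizes`.
#' @slot total full-model R-squared.
#' @slot groupSizes named numeric nominal predictor counts.
#' @slot variant model variant the decomposition refers to.
#' @slot subject,session scan identifiers.
#'
#' @export
setClass("ImportanceResult",
  representation(
    groupPVE = "numeric",
    perPredictor = "numeric",
    total = "numeric",
    groupSizes = "numeric",
    variant = "character",
    subject = "character",
    session = "character"
  )
)

#' A set of repeated measurements for discriminability
#'
#' Measurements `M[i,t]` for subjects `i = 1..n` over sessions `t = 1..T`
#' (complete design). `kind` decides the distance: Euclidean for
#' `"ordered_vector"`, 2-Wasserstein (Euclidean distance of sorted values)
#' for `"multiset"`.
#'
#' @slot values numeric (n*T) x p matrix, one measurement per row.
#' @slot subject,session identifiers per row.
#' @slot kind `"ordered_vector"` or `"multiset"`.
#'
#' @export
setClass("MeasurementSet",
  representation(
    values = "matrix",
    subject = "character",
    session = "character",
    kind = "character"
  )
)

setValidity("MeasurementSet", function(object) {
  msg <- character(0)
  N <- nrow(object@values)
  if (length(object@subject) != N || length(object@session) != N)
    msg <- c(msg, "subject and session must label every row")
  if (!object@kind %in% c("ordered_vector", "multiset"))
    msg <- c(msg, "kind must be 'ordered_vector' or 'multiset'")
  tab <- table(object@subject, object@session)
  if (length(tab) && any(tab != 1L))
    msg <- c(msg, "design must be complete: one measurement per (subject, session)")
  if (length(unique(object@subject)) < 2L)
    msg <- c(msg, "at least 2 subjects required")
  if (length(unique(object@session)) < 2L)
    msg <- c(msg, "at least 2 sessions required")
  if (length(msg)) msg else TRUE
})

#' Sample discriminability estimate
#'
#' @slot deltaHat the discriminability U-statistic, in `[0, 1]`.
#' @slot numerator count of strict within-subject-closer comparisons.
#' @slot denominator `n * (n-1) * T^2 * (T-1)` comparisons.
#' @slot ties number of exactly tied comparisons (these count 0).
#' @slot n,T subjects and sessions.
#' @slot distance `"euclidean"` or `"wasserstein2"`.
#'
#' @export
setClass("DiscriminabilityResult",
  representation(
    deltaHat = "numeric",
    numerator = "numeric",
    denominator = "numeric",
    ties = "numeric",
    n = "integer",
    T = "integer",
    distance = "character"
  )
)

#' Synthetic connectome generator settings
#'
#' Defaults encode the study conditions the generator emulates: a modest
#' mirror-paired parcellation, exponential distance decay and homotopy
#' effects, Gaussian region and network-cell effects, subject-level Gaussian
#' perturbations of every coefficient group plus a subject-specific
#' edge-level effect stable across sessions, and i.i.d. session noise.
#'
#' @slot nSubjects,nSessions,R,K design sizes; `R` must be even (regions are
#'   generated as exact mirror pairs) and at least `2*K`.
#' @slot beta0 population intercept (mean Fisher-Z connectivity).
#' @slot geogAmp,geogScale geographic decay `g(d) = geogAmp * exp(-d/geogScale)`
#'   (mm scale).
#' @slot homotAmp,homotScale homotopy effect `h(d) = homotAmp * exp(-d/homotScale)`
#'   applied to opposite-hemisphere pairs.
#' @slot regionSd,networkSd sds of population region effects and network-cell
#'   effects.
#' @slot subjectInterceptSd,subjectAmpSd,subjectRegionSd,subjectNetworkSd,subjectEdgeSd
#'   sds of subject-level additive perturbations of the intercept, the smooth
#'   amplitudes, the region effects, the network effects, and of the
#'   subject-specific per-edge effect.
#' @slot sessionSd sd of per-session, per-edge measurement noise.
#' @slot seed mandatory integer seed.
#'
#' @export
setClass("SyntheticConfig",
  representation(
    nSubjects = "integer", nSessions = "integer", R = "integer", K = "integer",
    beta0 = "numeric",
    geogAmp = "numeric", geogScale = "numeric",
    homotAmp = "numeric", homotScale = "numeric",
    regionSd = "numeric", networkSd = "numeric",
    subjectInterceptSd = "numeric", subjectAmpSd = "numeric",
    subjectRegionSd = "numeric", subjectNetworkSd = "numeric",
    subjectEdgeSd = "numeric", sessionSd = "numeric",
    seed = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character(0)
  if (object@R %% 2L != 0L) msg <- c(msg, "R must be even (mirror-paired regions)")
  if (object@R < 2L * object@K) msg <- c(msg, "R must be at least 2*K")
  if (object@nSubjects < 1L || object@nSessions < 1L)
    msg <- c(msg, "need at least one subject and one session")
  sds <- c(object@regionSd, object@networkSd, object@subjectInterceptSd,
           object@subjectAmpSd, object@subjectRegionSd, object@subjectNetworkSd,
           object@subjectEdgeSd, object@sessionSd)
  if (any(sds < 0)) msg <- c(msg, "all sds must be nonnegative")
  if (length(object@seed) != 1L || is.na(object@seed))
    msg <- c(msg, "seed is mandatory")
  if (length(msg)) msg else TRUE
})
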