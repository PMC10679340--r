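#' Unadjusted proportion of variation explained
#'
#' `1 - sum((z - zhat)^2) / sum((z - mean(z))^2)`. Unadjusted on purpose: the
#' group-wise importance decomposition must sum to the total proportion of
#' variation explained, which an adjusted R-squared would break.
#'
#' @param observed,fitted numeric vectors of equal length.
#' @return a proportion (in `[0, 1]` for any model containing an intercept).
#' @export
rSquared <- function(observed, fitted) {
  if (length(observed) != length(fitted))
    stop("observed and fitted must have equal length")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0)
    stop("observed values are constant; R-squared is undefined")
  1 - sum((observed - fitted)^2) / tss
}

#' Fit a subject-level connectivity regression
#'
#' Penalized least squares with Gaussian family and identity link: smooth
#' basis columns carry their thin-plate penalties with smoothing parameters
#' selected by REML or GCV (via [mgcv::gam()] with `paraPen`); intercept,
#' region and network columns are unpenalized. With
#' `penaltySelection = "none"` (or a design without penalties) the fit is
#' exactly ordinary least squares.
#'
#' Because indicator columns are never penalized, the residuals are
#' orthogonal to them, which yields the region-mean property: the average
#' fitted value over the edges involving any given region equals the average
#' observed connectivity on those edges (this also holds for indicator
#' columns dropped during rank reduction, since they lie in the span of the
#' retained ones).
#'
#' @param z numeric per-edge Fisher-Z vector (one scan).
#' @param design an [EdgeDesign-class] built for the same parcellation.
#' @param subject,session identifiers stored on the result.
#' @return a [ConnectivityFit-class].
#' @export
fitModel <- function(z, design, subject = "s", session = "t") {
  X <- design@X
  if (length(z) != nrow(X))
    stop("edge vector length does not match design")
  if (nrow(X) <= ncol(X))
    stop("need more edges than design columns")
  usePen <- length(design@penalties) > 0L &&
    design@spec@penaltySelection != "none"
  if (usePen) {
    p <- ncol(X)
    Sfull <- lapply(design@penalties, function(pen) {
      S <- matrix(0, p, p)
      S[pen$cols, pen$cols] <- pen$S
      S
    })
    method <- if (design@spec@penaltySelection == "REML") "REML" else "GCV.Cp"
    dat <- list(z = z, X = X)
    fit <- mgcv::gam(z ~ X - 1, data = dat, paraPen = list(X = Sfull),
                     method = method)
    beta <- setNames(as.numeric(fit$coefficients), colnames(X))
    fitted <- as.numeric(fit$fitted.values)
    sp <- setNames(as.numeric(fit$sp),
                   vapply(design@penalties, `[[`, "", "label"))
    edf <- sum(fit$edf)
  } else {
    qrX <- qr(X)
    if (qrX$rank < ncol(X))
      stop(sprintf(
        "design is numerically singular (rank %d < %d columns); reciprocal condition ~ %.3g",
        qrX$rank, ncol(X), 1 / kappa(X)))
    beta <- setNames(qr.coef(qrX, z), colnames(X))
    fitted <- as.numeric(X %*% beta)
    sp <- numeric(0)
    edf <- ncol(X)
  }
  new("ConnectivityFit",
    spec = design@spec,
    coefficients = beta,
    sp = sp,
    fitted = fitted,
    residuals = z - fitted,
    rSquared = rSquared(z, fitted),
    edf = edf,
    groups = design@groups,
    subject = as.character(subject),
    session = as.character(session))
}

#' Accessors for ConnectivityFit
#'
#' @param object a [ConnectivityFit-class].
#' @name fit-accessors
NULL

#' @rdname fit-accessors
#' @export
fittedEdges <- function(object) object@fitted

#' @rdname fit-accessors
#' @export
residualEdges <- function(object) object@residuals

#' @rdname fit-accessors
#' @export
pve <- function(object) object@rSquared

#' @rdname fit-accessors
#' @export
smoothingParameters <- function(object) object@sp

#' @export
setMethod("coef", "ConnectivityFit", function(object) object@coefficients)

#' @export
setMethod("show", "ConnectivityFit", function(object) {
  cat(sprintf("ConnectivityFit [%s, subject %s session %s]\n",
    object@spec@variant, object@subject, object@session))
  cat(sprintf("  %d coefficients, edf %.1f, R^2 = %.4f\n",
    length(object@coefficients), object@edf, object@rSquared))
  if (length(object@sp))
    cat("  smoothing parameters:",
        paste(sprintf("%s=%.3g", names(object@sp), object@sp), collapse = ", "), "\n")
})

#' Fit every scan of a ConnectivityExperiment under one spec
#'
#' @param object a [ConnectivityExperiment-class].
#' @param spec a [ModelSpec-class].
#' @return list with `fits` (one [ConnectivityFit-class] per scan) and
#'   `fitted` (edges x scans matrix of fitted values).
#' @export
fitAllScans <- function(object, spec = modelSpec()) {
  design <- buildDesign(parcellationOf(object), spec)
  z <- edgeZ(object)
  subj <- scanSubjects(object); sess <- scanSessions(object)
  fits <- lapply(seq_len(ncol(z)), function(c)
    fitModel(z[, c], design, subject = subj[c], session = sess[c]))
  fitted <- vapply(fits, fittedEdges, numeric(nrow(z)))
  colnames(fitted) <- colnames(z)
  list(fits = fits, fitted = fitted, design = design)
}

#' Independent matrix-regression (Frobenius-norm) minimizer
#'
#' The subject-level model is a matrix regression: its coefficients minimize
#' `||Z - W_1 b_1 - ... - W_p b_p||_F^2` where `Z` is the connectivity
#' matrix with zeroed diagonal and `W_k` is the symmetric matrix whose
#' `(j, j')` entry is design column `k` evaluated at the pair `(j, j')`.
#' This routine minimizes the Frobenius objective directly, by least squares
#' over all `R^2` matrix entries, for cross-checking [fitModel()] on small
#' unpenalized instances.
#'
#' @param A symmetric connectivity matrix (diagonal ignored).
#' @param design an unpenalized [EdgeDesign-class]
#'   (`penaltySelection = "none"`).
#' @return named coefficient vector.
#' @export
matrixRegressionCheck <- function(A, design) {
  if (design@spec@penaltySelection != "none")
    stop("matrix-regression check requires an unpenalized design")
  R <- nrow(A)
  if (R > 12L) stop("intended for small instances (R <= 12)")
  Z <- as.matrix(A)
  diag(Z) <- 0
  pr <- t(combn(R, 2L))
  Wvec <- apply(design@X, 2L, function(col) {
    W <- matrix(0, R, R)
    W[pr] <- col
    W[pr[, 2:1]] <- col
    as.vector(W)
  })
  beta <- qr.coef(qr(Wvec), as.vector(Z))
  setNames(as.numeric(beta), colnames(design@X))
}
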