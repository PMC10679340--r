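## Subsets of a group set, encoded as a character key.
.subsetKey <- function(groups) {
  if (!length(groups)) return("(intercept)")
  paste(sort(groups), collapse = "+")
}

## Which design blocks realize each importance group.
.groupBlocks <- function(group) {
  switch(group,
    geography = c("s0", "s1"),
    homotopy = "s2",
    networks = "networks",
    networks_intra = "networks",
    networks_inter = "networks",
    regions = "regions",
    stop(sprintf("unknown group '%s'", group)))
}

## For the intra/inter split both groups live in the 'networks' block; the
## wanted column-groups are filtered before rank reduction so each subset
## model keeps the full span of its own groups.
.subsetDesign <- function(blocks, groups, parcellation, spec) {
  blockNames <- unique(unlist(lapply(groups, .groupBlocks)))
  wanted <- unlist(lapply(groups, function(g)
    switch(g, networks = c("networks_intra", "networks_inter"), g)))
  .assembleDesign(blocks, blockNames, parcellation, spec,
                  colGroupsWanted = wanted)
}

#' Nominal predictor counts per covariate group
#'
#' Counts are nominal (pre-drop): geography 2, homotopy 1, networks
#' `K(K+1)/2`, regions `R`, intra-network `K`, inter-network `K(K-1)/2`.
#' Columns dropped during rank reduction still count.
#'
#' @param parcellation a [Parcellation-class].
#' @param groups character vector of group labels.
#' @return named numeric vector of counts.
#' @export
groupSizes <- function(parcellation, groups) {
  R <- nRegions(parcellation)
  K <- nNetworks(parcellation)
  sizes <- c(geography = 2, homotopy = 1,
             networks = K * (K + 1) / 2, regions = R,
             networks_intra = K, networks_inter = K * (K - 1) / 2)
  sizes[groups]
}

#' Per-predictor relative importance
#'
#' The proportion of variation explained by a group divided by its number of
#' predictors, scaled by 100.
#'
#' @param groupPVE proportion of variation explained by the group.
#' @param groupSize number of predictors in the group (must be >= 1).
#' @return `100 * groupPVE / groupSize`.
#' @export
perPredictorImportance <- function(groupPVE, groupSize) {
  if (any(groupSize < 1)) stop("groupSize must be at least 1")
  100 * groupPVE / groupSize
}

#' Group-wise LMG (orderings-averaged) importance decomposition
#'
#' Decomposes the model's R-squared into covariate-group contributions by
#' averaging, over all orderings of the groups, the increase in R-squared
#' when the group enters the model. Computed with Shapley subset weights
#' (`2^G` refits instead of `G! * G`): the contribution of group `g` is
#' `sum over subsets S of the other groups of
#' |S|! (G-|S|-1)! / G! * (R2(S + g) - R2(S))`.
#' Every subset model is refit from scratch (intercept always included;
#' smoothing parameters re-selected per subset). The contributions sum
#' exactly to the full model's R-squared by telescoping.
#'
#' @param z numeric per-edge Fisher-Z vector (one scan).
#' @param parcellation the [Parcellation-class].
#' @param spec a [ModelSpec-class]; its variant decides the groups (see
#'   [variantGroups()]).
#' @param subject,session identifiers stored on the result.
#' @return an [ImportanceResult-class].
#' @export
groupLMG <- function(z, parcellation, spec = modelSpec(),
                     subject = "s", session = "t") {
  groups <- variantGroups(spec)
  G <- length(groups)
  if (G < 1L) stop("need at least one covariate group beyond the intercept")
  blocks <- .designBlocks(parcellation, spec)
  cache <- new.env(parent = emptyenv())
  r2 <- function(sub) {
    key <- .subsetKey(sub)
    if (is.null(cache[[key]])) {
      if (!length(sub)) {
        cache[[key]] <- 0  # intercept-only: fitted = mean(z)
      } else {
        d <- .subsetDesign(blocks, sub, parcellation, spec)
        cache[[key]] <- tryCatch(pve(fitModel(z, d)),
          error = function(e) stop(sprintf(
            "subset model {%s} failed to fit: %s", .subsetKey(sub),
            conditionMessage(e))))
      }
    }
    cache[[key]]
  }
  contrib <- setNames(numeric(G), groups)
  for (g in groups) {
    others <- setdiff(groups, g)
    for (m in 0:length(others)) {
      subs <- if (m == 0) list(character(0)) else
        combn(others, m, simplify = FALSE)
      w <- factorial(m) * factorial(G - m - 1L) / factorial(G)
      for (S in subs)
        contrib[g] <- contrib[g] + w * (r2(c(S, g)) - r2(S))
    }
  }
  sizes <- groupSizes(parcellation, groups)
  new("ImportanceResult",
    groupPVE = contrib,
    perPredictor = perPredictorImportance(contrib, sizes),
    total = r2(groups),
    groupSizes = sizes,
    variant = spec@variant,
    subject = as.character(subject), session = as.character(session))
}

#' @describeIn groupLMG group contributions of an [ImportanceResult-class].
#' @param object an `ImportanceResult`.
#' @export
groupPVE <- function(object) object@groupPVE

#' @describeIn groupLMG per-predictor relative importance (x100).
#' @export
perPredictor <- function(object) object@perPredictor

#' @describeIn groupLMG total model R-squared.
#' @export
totalPVE <- function(object) object@total

#' @export
setMethod("show", "ImportanceResult", function(object) {
  cat(sprintf("ImportanceResult [%s, subject %s session %s], total R^2 = %.4f\n",
    object@variant, object@subject, object@session, object@total))
  df <- data.frame(group = names(object@groupPVE),
    pve = round(object@groupPVE, 4),
    per_predictor_x100 = round(object@perPredictor, 4),
    size = object@groupSizes)
  print(df, row.names = FALSE)
})

#' Importance decomposition for every scan of an experiment
#'
#' @param object a [ConnectivityExperiment-class].
#' @param spec a [ModelSpec-class].
#' @return long-format `data.frame` with columns `subject_id`, `session_id`,
#'   `model_variant`, `group`, `pve`, `per_predictor_x100`, `total_r2`.
#' @export
importanceTable <- function(object, spec = modelSpec()) {
  parc <- parcellationOf(object)
  z <- edgeZ(object)
  subj <- scanSubjects(object); sess <- scanSessions(object)
  do.call(rbind, lapply(seq_len(ncol(z)), function(c) {
    imp <- groupLMG(z[, c], parc, spec, subject = subj[c], session = sess[c])
    data.frame(subject_id = subj[c], session_id = sess[c],
      model_variant = spec@variant,
      group = names(groupPVE(imp)),
      pve = as.numeric(groupPVE(imp)),
      per_predictor_x100 = as.numeric(perPredictor(imp)),
      total_r2 = totalPVE(imp))
  }))
}
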