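#' Construct a Parcellation
#'
#' Regions are reordered by ascending `region_id`. Hemisphere labels are
#' authoritative; when the sign of the lateral (first) coordinate contradicts
#' the label a warning is emitted (a lateral coordinate of exactly 0 is
#' treated as consistent with either hemisphere, so midline regions never
#' warn).
#'
#' @param regionId integer region ids (unique).
#' @param centers numeric R x 3 matrix of mm coordinates; first column is the
#'   lateral axis with the mid-sagittal plane at 0.
#' @param hemisphere `"L"`/`"R"` per region.
#' @param network positive integer network membership per region.
#' @param label optional region names; defaults to `region_<id>`.
#' @return a validated [Parcellation-class].
#' @export
Parcellation <- function(regionId, centers, hemisphere, network, label = NULL) {
  regionId <- as.integer(regionId)
  if (is.null(label)) label <- sprintf("region_%d", regionId)
  centers <- as.matrix(centers)
  colnames(centers) <- c("x_mm", "y_mm", "z_mm")
  ord <- order(regionId)
  obj <- new("Parcellation",
    regionId = regionId[ord], label = as.character(label)[ord],
    centers = centers[ord, , drop = FALSE],
    hemisphere = as.character(hemisphere)[ord],
    network = as.integer(network)[ord])
  x <- obj@centers[, 1L]
  bad <- (x > 0 & obj@hemisphere == "L") | (x < 0 & obj@hemisphere == "R")
  if (any(bad))
    warning(sprintf(
      "hemisphere label contradicts sign of lateral coordinate for region(s) %s; keeping the label",
      paste(obj@regionId[bad], collapse = ", ")))
  obj
}

#' @describeIn Parcellation number of regions.
#' @param object,x a `Parcellation`.
#' @export
nRegions <- function(object) length(object@regionId)

#' @describeIn Parcellation number of networks (max network id).
#' @export
nNetworks <- function(object) max(object@network)

#' @describeIn Parcellation number of distinct region pairs, `R*(R-1)/2`.
#' @export
nEdges <- function(object) {
  R <- nRegions(object)
  R * (R - 1L) / 2L
}

#' Accessors for parcellation slots
#'
#' @param object a [Parcellation-class].
#' @return `regionIds`: integer ids; `regionCenters`: R x 3 mm matrix;
#'   `hemispheres`: `"L"`/`"R"` vector; `networks`: integer memberships.
#' @name parcellation-accessors
NULL

#' @rdname parcellation-accessors
#' @export
regionIds <- function(object) object@regionId

#' @rdname parcellation-accessors
#' @export
regionCenters <- function(object) object@centers

#' @rdname parcellation-accessors
#' @export
hemispheres <- function(object) object@hemisphere

#' @rdname parcellation-accessors
#' @export
networks <- function(object) object@network

#' @export
setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d regions, %d networks, %d edges\n",
    nRegions(object), nNetworks(object), nEdges(object)))
  cat(sprintf("  hemispheres: %d L / %d R\n",
    sum(object@hemisphere == "L"), sum(object@hemisphere == "R")))
})

.regionIndex <- function(parcellation, id) {
  idx <- match(id, parcellation@regionId)
  if (anyNA(idx))
    stop(sprintf("unknown region id(s): %s", paste(id[is.na(idx)], collapse = ", ")))
  idx
}

#' Geographic (Euclidean) distance between region centers
#'
#' @param parcellation a [Parcellation-class].
#' @param a,b region ids (vectorized, recycled to common length).
#' @return distance(s) in mm.
#' @export
geographicDistance <- function(parcellation, a, b) {
  ia <- .regionIndex(parcellation, a)
  ib <- .regionIndex(parcellation, b)
  ca <- parcellation@centers[ia, , drop = FALSE]
  cb <- parcellation@centers[ib, , drop = FALSE]
  sqrt(rowSums((ca - cb)^2))
}

#' Homotopic distance between region centers
#'
#' The Euclidean distance between one center and the reflection of the other
#' across the mid-sagittal plane (lateral coordinate negated). Zero for a
#' perfectly mirror-symmetric pair; invariant to swapping `a` and `b`.
#' Defined for any pair, though the models only use it for
#' opposite-hemisphere pairs.
#'
#' @inheritParams geographicDistance
#' @return distance(s) in mm.
#' @export
homotopicDistance <- function(parcellation, a, b) {
  ia <- .regionIndex(parcellation, a)
  ib <- .regionIndex(parcellation, b)
  ca <- parcellation@centers[ia, , drop = FALSE]
  cb <- parcellation@centers[ib, , drop = FALSE]
  cb[, 1L] <- -cb[, 1L]
  sqrt(rowSums((ca - cb)^2))
}

#' Hemisphere relation of a region pair
#'
#' @inheritParams geographicDistance
#' @return `"same"` or `"opposite"` per pair.
#' @export
hemisphereRelation <- function(parcellation, a, b) {
  ha <- parcellation@hemisphere[.regionIndex(parcellation, a)]
  hb <- parcellation@hemisphere[.regionIndex(parcellation, b)]
  ifelse(ha == hb, "same", "opposite")
}

#' Enumerate region pairs in canonical edge order
#'
#' Strictly-upper-triangular, row-major order by ascending region id:
#' (1,2), (1,3), ..., (1,R), (2,3), ... This ordering is part of the file
#' contract so that Euclidean distances between subjects' edge vectors are
#' well defined.
#'
#' @param parcellation a [Parcellation-class].
#' @return a `data.frame` with columns `region_i`, `region_j` (ids, i < j in
#'   id order).
#' @export
edgePairs <- function(parcellation) {
  ids <- parcellation@regionId
  pr <- t(combn(length(ids), 2L))
  data.frame(region_i = ids[pr[, 1L]], region_j = ids[pr[, 2L]])
}

#' Per-edge covariates for a parcellation
#'
#' @param parcellation a [Parcellation-class].
#' @return a `data.frame` with one row per edge in canonical order:
#'   `region_i`, `region_j`, `geog_dist`, `homotop_dist`, `same_hemisphere`.
#' @export
edgeCovariates <- function(parcellation) {
  pr <- edgePairs(parcellation)
  data.frame(
    region_i = pr$region_i,
    region_j = pr$region_j,
    geog_dist = geographicDistance(parcellation, pr$region_i, pr$region_j),
    homotop_dist = homotopicDistance(parcellation, pr$region_i, pr$region_j),
    same_hemisphere =
      hemisphereRelation(parcellation, pr$region_i, pr$region_j) == "same"
  )
}

#' Read / write the parcellation TSV dialect
#'
#' Tab-separated with header
#' `region_id label x_mm y_mm z_mm hemisphere network`; hemisphere is `L` or
#' `R`, network a positive integer. [writeParcellation()] emits the same
#' dialect, so a written file reads back identically.
#'
#' @param path file path.
#' @return [readParcellation()]: a validated [Parcellation-class].
#' @export
readParcellation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("region_id", "label", "x_mm", "y_mm", "z_mm", "hemisphere", "network")
  missing <- setdiff(need, colnames(df))
  if (length(missing))
    stop(sprintf("parcellation file lacks column(s): %s", paste(missing, collapse = ", ")))
  if (anyNA(df[, c("x_mm", "y_mm", "z_mm")]))
    stop("missing coordinates in parcellation file")
  Parcellation(
    regionId = df$region_id,
    centers = as.matrix(df[, c("x_mm", "y_mm", "z_mm")]),
    hemisphere = df$hemisphere, network = df$network, label = df$label)
}

#' @rdname readParcellation
#' @param parcellation a [Parcellation-class] to write.
#' @export
writeParcellation <- function(parcellation, path) {
  df <- data.frame(
    region_id = parcellation@regionId,
    label = parcellation@label,
    x_mm = parcellation@centers[, 1L],
    y_mm = parcellation@centers[, 2L],
    z_mm = parcellation@centers[, 3L],
    hemisphere = parcellation@hemisphere,
    network = parcellation@network)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
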