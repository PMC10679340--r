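## Allowed config keys per command; unknown keys are an error so typos in a
## YAML file fail loudly.
.configKeys <- list(
  simulate = c("seed", "out_dir", "synthetic"),
  fit = c("seed", "out_dir", "parcellation", "edges", "variants",
          "basis_dim", "penalty_selection"),
  importance = c("seed", "out_dir", "parcellation", "edges", "variants",
                 "basis_dim", "penalty_selection"),
  discrim = c("seed", "out_dir", "parcellation", "edges", "variants",
              "basis_dim", "penalty_selection", "n_perm")
)

.syntheticKeys <- c("n_subjects", "n_sessions", "R", "K", "beta0",
  "geog_amp", "geog_scale", "homot_amp", "homot_scale", "region_sd",
  "network_sd", "subject_intercept_sd", "subject_amp_sd",
  "subject_region_sd", "subject_network_sd", "subject_edge_sd",
  "session_sd")

#' Read and validate a run configuration
#'
#' YAML with command-specific keys; any unknown key is an error naming the
#' key. Input paths are checked for existence at validation time.
#'
#' @param config path to a YAML file, or an equivalent named list.
#' @param command one of `"simulate"`, `"fit"`, `"importance"`, `"discrim"`.
#' @return validated config list; `$config_hash` carries an md5 of the file
#'   when one was read.
#' @export
readRunConfig <- function(config, command) {
  command <- match.arg(command, names(.configKeys))
  hash <- NA_character_
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: %s", config))
    hash <- unname(tools::md5sum(config))
    config <- yaml::read_yaml(config)
  }
  unknown <- setdiff(names(config), c(.configKeys[[command]], "config_hash"))
  if (length(unknown))
    stop(sprintf("invalid config key(s) for '%s': %s", command,
      paste(unknown, collapse = ", ")))
  if (!is.null(config$synthetic)) {
    bad <- setdiff(names(config$synthetic), .syntheticKeys)
    if (length(bad))
      stop(sprintf("invalid synthetic config key(s): %s", paste(bad, collapse = ", ")))
  }
  for (p in intersect(c("parcellation", "edges"), names(config)))
    if (!file.exists(config[[p]]))
      stop(sprintf("input path does not exist: %s = %s", p, config[[p]]))
  if (is.null(config$seed)) config$seed <- 1L
  config$config_hash <- hash
  config
}

.ensureDir <- function(d) {
  if (!dir.exists(d)) dir.create(d, recursive = TRUE)
  d
}

.provenance <- function(config) {
  list(seed = as.integer(config$seed),
       config_hash = if (is.null(config$config_hash) || is.na(config$config_hash))
         NULL else config$config_hash)
}

.specFromConfig <- function(config, variant) {
  modelSpec(variant,
    basisDim = if (is.null(config$basis_dim)) 10L else config$basis_dim,
    penaltySelection = if (is.null(config$penalty_selection)) "REML"
                       else config$penalty_selection)
}

.loadExperiment <- function(config) {
  parc <- readParcellation(config$parcellation)
  readEdgeTable(config$edges, parc)
}

#' Run the simulate command
#'
#' Generates a synthetic parcellation and edge data and writes
#' `parcellation.tsv`, `edges.csv` and `truth.json` (ground-truth
#' coefficients, seed, config echo) to the output directory, which is
#' created if missing.
#'
#' @param config YAML path or list (see [readRunConfig()]).
#' @return (invisibly) the output directory.
#' @export
runSimulate <- function(config) {
  config <- readRunConfig(config, "simulate")
  out <- .ensureDir(if (is.null(config$out_dir)) "." else config$out_dir)
  sc <- config$synthetic
  get <- function(nm, default) if (is.null(sc[[nm]])) default else sc[[nm]]
  cfg <- syntheticConfig(
    nSubjects = get("n_subjects", 20L), nSessions = get("n_sessions", 2L),
    R = get("R", 20L), K = get("K", 4L),
    beta0 = get("beta0", 0.3),
    geogAmp = get("geog_amp", 0.6), geogScale = get("geog_scale", 40),
    homotAmp = get("homot_amp", 0.4), homotScale = get("homot_scale", 30),
    regionSd = get("region_sd", 0.1), networkSd = get("network_sd", 0.15),
    subjectInterceptSd = get("subject_intercept_sd", 0.05),
    subjectAmpSd = get("subject_amp_sd", 0.1),
    subjectRegionSd = get("subject_region_sd", 0.05),
    subjectNetworkSd = get("subject_network_sd", 0.05),
    subjectEdgeSd = get("subject_edge_sd", 0.1),
    sessionSd = get("session_sd", 0.1),
    seed = config$seed)
  ce <- simulateEdges(cfg)
  writeParcellation(parcellationOf(ce), file.path(out, "parcellation.tsv"))
  writeEdgeTable(ce, file.path(out, "edges.csv"))
  truth <- S4Vectors::metadata(ce)$truth
  truthOut <- list(
    provenance = .provenance(config),
    population = truth$population,
    subjects = lapply(truth$subjects, function(si)
      si[c("beta0", "geogAmp", "homotAmp", "region", "network")]))
  jsonlite::write_json(truthOut, file.path(out, "truth.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out)
}

#' Run the fit command
#'
#' Fits every (subject, session) scan under every requested variant; writes
#' `r_squared.csv` (one row per scan and variant) and per-scan edge files
#' `fitted_<variant>_<subject>_<session>.csv` with columns
#' `region_i, region_j, z, fitted, residual`. Individual fit failures are
#' reported on stderr and the run continues.
#'
#' @inheritParams runSimulate
#' @export
runFit <- function(config) {
  config <- readRunConfig(config, "fit")
  out <- .ensureDir(if (is.null(config$out_dir)) "." else config$out_dir)
  ce <- .loadExperiment(config)
  variants <- if (is.null(config$variants)) "full" else unlist(config$variants)
  cov <- as.data.frame(SummarizedExperiment::rowData(ce))
  z <- edgeZ(ce)
  subj <- scanSubjects(ce); sess <- scanSessions(ce)
  rows <- list()
  for (v in variants) {
    design <- buildDesign(parcellationOf(ce), .specFromConfig(config, v))
    for (c in seq_len(ncol(z))) {
      fit <- tryCatch(fitModel(z[, c], design, subj[c], sess[c]),
        error = function(e) {
          message(sprintf("fit failed (%s, %s/%s): %s", v, subj[c], sess[c],
                          conditionMessage(e)))
          NULL
        })
      if (is.null(fit)) next
      message(sprintf("fit %s %s/%s: R^2 = %.4f", v, subj[c], sess[c], pve(fit)))
      rows[[length(rows) + 1L]] <- data.frame(subject_id = subj[c],
        session_id = sess[c], model_variant = v, r_squared = pve(fit),
        seed = config$seed)
      write.csv(data.frame(region_i = cov$region_i, region_j = cov$region_j,
          z = z[, c], fitted = fittedEdges(fit), residual = residualEdges(fit)),
        file.path(out, sprintf("fitted_%s_%s_%s.csv",
          gsub("[^A-Za-z0-9_]", "_", v), subj[c], sess[c])),
        row.names = FALSE, quote = FALSE)
    }
  }
  write.csv(do.call(rbind, rows), file.path(out, "r_squared.csv"),
            row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Run the importance command
#'
#' Writes `importance.csv` with columns `subject_id, session_id,
#' model_variant, group, pve, per_predictor_x100, total_r2, seed`.
#'
#' @inheritParams runSimulate
#' @export
runImportance <- function(config) {
  config <- readRunConfig(config, "importance")
  out <- .ensureDir(if (is.null(config$out_dir)) "." else config$out_dir)
  ce <- .loadExperiment(config)
  variants <- if (is.null(config$variants)) "full" else unlist(config$variants)
  tabs <- lapply(variants, function(v)
    importanceTable(ce, .specFromConfig(config, v)))
  tab <- do.call(rbind, tabs)
  tab$seed <- config$seed
  write.csv(tab, file.path(out, "importance.csv"), row.names = FALSE,
            quote = FALSE)
  invisible(out)
}

#' Run the discriminability command
#'
#' Compares the edge-at-a-time approach, each requested model variant's
#' fitted values, and the edge distribution approach; adds the permutation
#' reference distribution for the raw edge vectors. Writes
#' `discriminability.json`.
#'
#' @inheritParams runSimulate
#' @export
runDiscrim <- function(config) {
  config <- readRunConfig(config, "discrim")
  out <- .ensureDir(if (is.null(config$out_dir)) "." else config$out_dir)
  ce <- .loadExperiment(config)
  variants <- if (is.null(config$variants)) c("reference", "full")
              else unlist(config$variants)
  tab <- compareSummaries(ce, variants,
    basisDim = if (is.null(config$basis_dim)) 10L else config$basis_dim,
    penaltySelection = if (is.null(config$penalty_selection)) "REML"
                       else config$penalty_selection)
  nPerm <- if (is.null(config$n_perm)) 1000L else as.integer(config$n_perm)
  ms <- measurementSet(t(edgeZ(ce)), scanSubjects(ce), scanSessions(ce),
                       "ordered_vector")
  pn <- permutationNull(ms, nPerm = nPerm, seed = config$seed)
  result <- list(
    provenance = .provenance(config),
    approaches = lapply(seq_len(nrow(tab)), function(r) as.list(tab[r, ])),
    permutation_null = list(perm_mean = pn$mean, perm_q025 = pn$q025,
      perm_q975 = pn$q975, n_perm = pn$nPerm, seed = pn$seed))
  jsonlite::write_json(result, file.path(out, "discriminability.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(out)
}
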