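#' Graph metrics for a set of connectivity matrices
#'
#' Computes [local_metrics()] and [global_metrics()] for every
#' participant's connectivity matrix and stacks them into the long tables
#' consumed by [run_association_scan()].
#'
#' @param connectivity Named list of symmetric connectivity matrices,
#'   keyed by participant id.
#' @return List with `metrics` (participant x node long table) and
#'   `globals` (one row per participant).
#' @export
cohort_metrics <- function(connectivity) {
  if (length(connectivity) == 0) stop_data("no connectivity matrices")
  rows <- lapply(names(connectivity), function(id) {
    lm_ <- local_metrics(weighted_graph(connectivity[[id]]))
    cbind(participant_id = id, lm_, stringsAsFactors = FALSE)
  })
  metrics <- do.call(rbind, rows)
  globals <- do.call(rbind, lapply(names(connectivity), function(id) {
    g <- global_metrics(local_metrics(weighted_graph(connectivity[[id]])))
    data.frame(participant_id = id, global_strength = g[["global_strength"]],
               global_clustering = g[["global_clustering"]],
               global_efficiency = g[["global_efficiency"]],
               stringsAsFactors = FALSE)
  }))
  list(metrics = metrics, globals = globals)
}

pipeline_defaults <- function() {
  list(cohort = formals(cohort_config),
       mic = list(alpha = 0.6, c = 15, mode = "heuristic"),
       inference = list(train_fraction = 0.7, seed = 1, fdr_q = 0.01,
                        rrmse_norm = "rms", facet_mode = FALSE),
       io = list(input_dir = NULL, output_dir = NULL),
       log_level = "info")
}

#' Pipeline configuration
#'
#' Assembles and validates the full end-to-end configuration. Unknown keys
#' in any section are rejected, so config files cannot silently misspell a
#' parameter.
#'
#' @param cohort Named list of [cohort_config()] arguments (synthetic
#'   mode), or an already-built `cohort_config`.
#' @param mic Named list: `alpha`, `c`, `mode`.
#' @param inference Named list: `train_fraction`, `seed`, `fdr_q`,
#'   `rrmse_norm`, `facet_mode`.
#' @param io Named list: `input_dir` (read an existing cohort instead of
#'   simulating), `output_dir`.
#' @param log_level `"info"` or `"quiet"`.
#' @return Classed list (`pipeline_config`).
#' @export
pipeline_config <- function(cohort = list(), mic = list(),
                            inference = list(), io = list(),
                            log_level = "info") {
  defs <- pipeline_defaults()
  check_keys <- function(given, allowed, section) {
    extra <- setdiff(names(given), allowed)
    if (length(extra))
      stop_config("unknown ", section, " key(s): ",
                  paste(extra, collapse = ", "))
  }
  if (inherits(cohort, "cohort_config")) {
    cohort_cfg <- cohort
  } else {
    check_keys(cohort, names(defs$cohort), "cohort")
    cohort_cfg <- do.call(cohort_config, cohort)
  }
  check_keys(mic, names(defs$mic), "mic")
  check_keys(inference, names(defs$inference), "inference")
  check_keys(io, names(defs$io), "io")
  mic <- utils::modifyList(defs$mic, mic)
  inference <- utils::modifyList(defs$inference, inference)
  io <- utils::modifyList(defs$io, io, keep.null = TRUE)
  if (!mic$mode %in% c("heuristic", "exhaustive"))
    stop_config("mic mode must be heuristic or exhaustive")
  if (!log_level %in% c("info", "quiet"))
    stop_config("log_level must be info or quiet")
  structure(list(cohort = cohort_cfg, mic = mic, inference = inference,
                 io = io, log_level = log_level),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys mirror the
#'   [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
load_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_config("no such config file: ", path)
  raw <- yaml::read_yaml(path)
  allowed <- c("cohort", "mic", "inference", "io", "log_level")
  extra <- setdiff(names(raw), allowed)
  if (length(extra))
    stop_config("unknown top-level config key(s): ",
                paste(extra, collapse = ", "))
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  strip <- config
  strip$io <- NULL # hash covers the science, not where files live
  jsonlite::write_json(strip, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

decision_flags <- function(config) {
  list(edge_length_map = "1/weight",
       clustering = "onnela_geometric_mean_max_normalized",
       local_efficiency = "inverse_shortest_path_neighbor_subgraph",
       betweenness_normalization = "(N-1)(N-2)/2",
       mic_resolution = "B(n)=max(4,floor(n^alpha))",
       fdr_family = "within_trait_across_outcomes",
       rrmse_norm = config$inference$rrmse_norm,
       diagonal = "zero")
}

plog <- function(config, ...) {
  if (!identical(config$log_level, "quiet"))
    message("[micnet] ", ...)
}

#' Run the full analysis pipeline
#'
#' Executes cohort generation (or ingestion), MIC connectivity estimation,
#' graph-metric computation and the trait association scan in order,
#' writing every intermediate and final table under
#' `config$io$output_dir` together with a run manifest (config hash,
#' seeds, package version, per-file checksums and the methodological
#' decision flags). Re-running with the identical configuration reuses
#' cached per-participant connectivity matrices; a differing configuration
#' over a populated output directory is refused unless `force = TRUE`.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param force Overwrite outputs from a different configuration.
#' @return Invisibly, a list with the `trait_scan` object (`scan`), the
#'   facet scan (if enabled), the metric tables and the manifest.
#' @export
run_pipeline <- function(config, force = FALSE) {
  if (is.character(config)) config <- load_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$io$output_dir
  if (is.null(out_dir)) stop_config("io$output_dir is required")
  hash <- config_hash(config)
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path)) {
    old <- jsonlite::read_json(manifest_path)
    if (!identical(old$config_hash, hash) && !force)
      stop_config("output directory holds results from a different ",
                  "configuration (config hash mismatch); use force = TRUE ",
                  "to overwrite")
  }
  dir.create(file.path(out_dir, "connectivity"), recursive = TRUE,
             showWarnings = FALSE)

  # stage 1: cohort
  if (!is.null(config$io$input_dir)) {
    plog(config, "reading cohort from ", config$io$input_dir)
    participants <- read_participants(file.path(config$io$input_dir,
                                                "participants.csv"))
    ts_dir <- file.path(config$io$input_dir, "timeseries")
    series <- lapply(participants$participant_id, function(id) {
      read_time_series(file.path(ts_dir, paste0(id, ".tsv")))
    })
    names(series) <- participants$participant_id
  } else {
    plog(config, "simulating cohort (n = ", config$cohort$n_participants,
         ", seed = ", config$cohort$seed, ")")
    cohort <- generate_cohort(config$cohort)
    participants <- cohort$participants
    series <- cohort$series
    write_cohort(participants, series, out_dir)
  }

  # stage 2: connectivity (cached per participant under the config hash)
  plog(config, "estimating MIC connectivity for ", length(series),
       " participants")
  connectivity <- lapply(names(series), function(id) {
    cpath <- file.path(out_dir, "connectivity", paste0(id, ".tsv"))
    if (file.exists(cpath) && file.exists(manifest_path) &&
        identical(jsonlite::read_json(manifest_path)$config_hash, hash))
      return(read_connectivity(cpath))
    m <- tryCatch(
      mic_matrix(series[[id]], alpha = config$mic$alpha, c = config$mic$c,
                 mode = config$mic$mode),
      error = function(e)
        stop_data("connectivity estimation failed for participant ", id,
                  ": ", conditionMessage(e)))
    write_connectivity(m, cpath)
    m
  })
  names(connectivity) <- names(series)

  # stage 3: graph metrics
  plog(config, "computing graph metrics")
  mets <- cohort_metrics(connectivity)
  write.table(mets$metrics, file.path(out_dir, "metrics.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(mets$globals, file.path(out_dir, "globals.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  # stage 4: association scan + external validation
  plog(config, "running association scan")
  inf <- config$inference
  scan <- run_association_scan(mets$metrics, mets$globals, participants,
                               train_fraction = inf$train_fraction,
                               seed = inf$seed, fdr_q = inf$fdr_q,
                               rrmse_norm = inf$rrmse_norm)
  write.table(scan$associations, file.path(out_dir, "associations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(scan$validation, file.path(out_dir, "validation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  facet <- NULL
  if (isTRUE(inf$facet_mode)) {
    plog(config, "running facet scan")
    facet <- facet_scan(mets$metrics, mets$globals, participants,
                        train_fraction = inf$train_fraction,
                        seed = inf$seed, fdr_q = inf$fdr_q,
                        rrmse_norm = inf$rrmse_norm)
    write.table(facet$associations,
                file.path(out_dir, "facet_associations.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(facet$validation, file.path(out_dir, "facet_validation.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, manifest_path)
  checksums <- tools::md5sum(outputs)
  names(checksums) <- sub(paste0("^", out_dir, "/?"), "",
                          names(checksums))
  manifest <- list(config_hash = hash,
                   seeds = list(cohort = config$cohort$seed,
                                split = inf$seed),
                   package_version =
                     as.character(utils::packageVersion("micnet")),
                   decision_flags = decision_flags(config),
                   checksums = as.list(checksums))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  plog(config, "done; manifest at ", manifest_path)
  invisible(list(scan = scan, facet = facet, metrics = mets$metrics,
                 globals = mets$globals, participants = participants,
                 connectivity = connectivity, manifest = manifest))
}
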