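#' Save / load a model configuration
#'
#' Configurations round-trip through YAML (or JSON, by file extension). All
#' values are SI. On load the configuration is validated and unknown
#' top-level keys are rejected.
#'
#' @param config a `gait_model_config`
#' @param path file path ending in .yaml, .yml or .json
#' @return `load_model_config` returns a validated `gait_model_config`
#' @export
save_model_config <- function(config, path) {
  stopifnot(inherits(config, "gait_model_config"))
  obj <- unclass(config)
  obj$segments <- as.list(config$segments)
  obj$joints <- as.list(config$joints)
  obj$muscles <- as.list(config$muscles)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path, precision = 17)
  } else if (ext == "json") {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else stop("unsupported config format: .", ext)
  invisible(path)
}

#' @rdname save_model_config
#' @export
load_model_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("unsupported config format: .", ext)
  known <- names(default_model_config())
  unknown <- setdiff(names(obj), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- default_model_config()
  for (nm in intersect(names(obj), known)) {
    if (nm %in% c("segments", "joints", "muscles")) {
      cfg[[nm]] <- as.data.frame(obj[[nm]], stringsAsFactors = FALSE)
      if (nm == "muscles") rownames(cfg[[nm]]) <-
          paste(cfg[[nm]]$name, cfg[[nm]]$side, sep = "_")
    } else if (is.list(cfg[[nm]]) && is.list(obj[[nm]])) {
      cfg[[nm]] <- modifyList(cfg[[nm]], obj[[nm]])
    } else {
      cfg[[nm]] <- obj[[nm]]
    }
  }
  validate_model_config(cfg)
  cfg
}

#' Stable hash of a configuration
#'
#' Serializes to canonical JSON and hashes with md5; used in run manifests so
#' two runs with identical configs carry identical hashes.
#'
#' @param config any jsonlite-serializable object
#' @return character md5 hash
#' @export
config_hash <- function(config) {
  if (inherits(config, "gait_model_config")) config <- unclass(config)
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

#' Run manifest
#'
#' Records everything needed to reproduce a run bit-identically: the
#' configuration snapshot and its hash, the master seed, package version,
#' timestamps and per-stage outputs.
#'
#' @param config configuration object (snapshotted into the manifest)
#' @param seed master seed
#' @param protocol protocol label
#' @param outputs named list of output paths or stage summaries
#' @return list of class `run_manifest`
#' @export
run_manifest <- function(config, seed, protocol = "simulate",
                         outputs = list()) {
  m <- list(
    protocol = protocol,
    seed = seed,
    config = if (inherits(config, "gait_model_config")) unclass(config)
             else config,
    config_hash = config_hash(config),
    package_version = as.character(utils::packageVersion("neurogait")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = outputs
  )
  class(m) <- "run_manifest"
  m
}

#' Write a result bundle to a directory
#'
#' Deterministic file layout: `manifest.json`, `params.json` (best controller
#' + initial state, named and flat), `trace.csv` (+ JSON sidecar),
#' `cycles.csv` / `summary.json` when a gait summary exists. Re-running
#' overwrites atomically (write to a temp name, then rename).
#'
#' @param result a protocol result (from [run_self_selected()],
#'   [run_weakness()], one entry of [run_speed_sweep()], or a list with at
#'   least `opt` and `trace`)
#' @param out_dir output directory (created if missing)
#' @param config the model config used (for the manifest)
#' @param seed master seed (for the manifest)
#' @return invisible named vector of written paths
#' @export
write_results <- function(result, out_dir, config = default_model_config(),
                          seed = NA) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory is not writable: ", out_dir)
  paths <- c()
  atomically <- function(write_fn, final) {
    tmp <- paste0(final, ".tmp")
    write_fn(tmp)
    file.rename(tmp, final)
    final
  }
  if (!is.null(result$opt)) {
    pj <- file.path(out_dir, "params.json")
    atomically(function(p) {
      jsonlite::write_json(list(
        controller = as.list(result$opt$controller),
        controller_flat = as.numeric(
          pack_params(result$opt$controller)),
        initial_state = as.list(unclass(result$opt$init)),
        unit_box = as.numeric(result$opt$best_params),
        best_reward = result$opt$best_reward,
        seed_provenance = result$opt$seed_provenance
      ), p, auto_unbox = TRUE, digits = NA)
    }, pj)
    paths["params"] <- pj
    rh <- file.path(out_dir, "reward_history.csv")
    atomically(function(p) write.csv(result$opt$reward_history, p,
                                     row.names = FALSE), rh)
    paths["reward_history"] <- rh
  }
  if (!is.null(result$trace) && length(result$trace$time) > 0) {
    tc <- file.path(out_dir, "trace.csv")
    write_trace(result$trace, tc)
    paths["trace"] <- tc
  }
  if (!is.null(result$summary)) {
    corr <- result$correlations
    write_cycle_summary(result$summary, file.path(out_dir, "cycles.csv"),
                        file.path(out_dir, "summary.json"),
                        correlations = corr)
    paths["cycles"] <- file.path(out_dir, "cycles.csv")
    paths["summary"] <- file.path(out_dir, "summary.json")
  }
  extra <- list()
  if (!is.null(result$self_selected_speed))
    extra$self_selected_speed <- result$self_selected_speed
  if (!is.null(result$config_diff)) extra$config_diff <- result$config_diff
  if (!is.null(result$table)) extra$table <- result$table
  man <- run_manifest(config, seed,
                      protocol = if (!is.null(result$protocol))
                        result$protocol else "simulate",
                      outputs = c(as.list(paths), extra))
  mj <- file.path(out_dir, "manifest.json")
  atomically(function(p) {
    jsonlite::write_json(unclass(man), p, auto_unbox = TRUE, digits = NA,
                         force = TRUE)
  }, mj)
  paths["manifest"] <- mj
  invisible(paths)
}
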