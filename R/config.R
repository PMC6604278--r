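# Run configuration: YAML-backed, with validated keys and resolved defaults.

config_defaults <- function() {
  list(mode = "simulate",
       seed = 1L,
       replications = 500L,
       population_size = 10000L,
       bootstrap_samples = 999L,
       methods = c("or", "and", "rssa"),
       assumed_accuracy = list(
         source1 = list(sensitivity = 0.72, specificity = 0.95),
         source2 = list(sensitivity = 0.87, specificity = 0.90)),
       pssa = list(n_iter = 10000L, burn_in = 500L, n_chains = 2L),
       conditions = NULL,
       input = NULL,
       output_dir = ".")
}

#' Load and validate a run configuration
#'
#' Reads a YAML file describing a simulation or estimation run, rejects
#' unknown keys, fills defaults (500 replications, 999 bootstrap samples,
#' 10000 Gibbs iterations with 500 burn-in) and validates cross-field
#' constraints.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated list of class `"run_config"`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  defaults <- config_defaults()
  unknown <- setdiff(names(raw), names(defaults))
  if (length(unknown) > 0) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  if (!is.null(raw$pssa)) {
    unknown_p <- setdiff(names(raw$pssa), names(defaults$pssa))
    if (length(unknown_p) > 0) {
      stop(sprintf("unknown pssa key(s): %s",
                   paste(unknown_p, collapse = ", ")), call. = FALSE)
    }
    raw$pssa <- modifyList(defaults$pssa, raw$pssa)
  }
  cfg <- modifyList(defaults, raw)
  if (!cfg$mode %in% c("simulate", "estimate", "fixture")) {
    stop("`mode` must be one of simulate, estimate, fixture", call. = FALSE)
  }
  stopifnot(cfg$seed >= 1, cfg$replications >= 1, cfg$bootstrap_samples >= 1)
  if (cfg$pssa$burn_in >= cfg$pssa$n_iter) {
    stop("pssa burn_in must be smaller than n_iter", call. = FALSE)
  }
  if (cfg$mode == "estimate") {
    if (is.null(cfg$input) || !file.exists(cfg$input)) {
      stop("estimate mode requires an existing `input` path", call. = FALSE)
    }
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration back to YAML
#'
#' @param config A `"run_config"` (or plain list).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  cfg <- cfg[!vapply(cfg, is.null, logical(1))]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Expand the condition block of a configuration into a grid
#'
#' The `conditions` block lists factor levels (`true_prev`, `obs_prev` as a
#' list of pairs, `source_corr`, `n_markers`, `marker_corr`,
#' `marker_corr_pattern`); the full crossing is returned.
#'
#' @param config A `"run_config"` with a `conditions` block.
#' @return List of [sim_condition()] objects.
#' @export
build_condition_grid <- function(config) {
  cb <- config$conditions
  if (is.null(cb)) stop("configuration has no `conditions` block",
                        call. = FALSE)
  obs_pairs <- cb$obs_prev
  if (!is.list(obs_pairs)) obs_pairs <- list(obs_pairs)
  grid <- expand.grid(
    true_prev = cb$true_prev,
    obs_idx = seq_along(obs_pairs),
    source_corr = cb$source_corr,
    n_markers = cb$n_markers,
    marker_corr = if (is.null(cb$marker_corr)) 0 else cb$marker_corr,
    pattern = if (is.null(cb$marker_corr_pattern)) "exchangeable"
              else cb$marker_corr_pattern,
    stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sim_condition(grid$true_prev[i],
                  unlist(obs_pairs[[grid$obs_idx[i]]]),
                  grid$source_corr[i], grid$n_markers[i],
                  grid$marker_corr[i], grid$pattern[i],
                  population_size = config$population_size)
  })
}

#' Write a reproducibility manifest for a run
#'
#' Records the configuration (and its stable hash), base seed, package and R
#' versions — enough to reproduce the run's outputs bit for bit.
#'
#' @param config A `"run_config"`.
#' @param dir Output directory.
#' @return Manifest path, invisibly.
#' @export
write_manifest <- function(config, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "manifest.yaml")
  manifest <- list(
    config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
    config_hash = stable_hash(yaml::as.yaml(unclass(config))),
    package_version = as.character(packageVersion("prevcomb")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  yaml::write_yaml(manifest, path)
  invisible(path)
}
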