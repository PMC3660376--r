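# Configuration files, trajectory CSVs and schema-versioned run manifests.

MANIFEST_SCHEMA_VERSION <- "1.0"

# Table 1-style simulation parameters accepted in config files
config_param_keys <- c("X0", "N0", "Sd_copy", "Sd_elim", "I", "M", "K",
                       "P", "S", "pop_size", "n_iter", "seed")

#' Load a simulation or sweep configuration
#'
#' Reads a YAML or JSON configuration. Top-level keys are simulation
#' parameters (any subset of the [sim_params()] fields; missing fields take
#' their defaults). An optional `sweep` block with `values` (named lists of
#' swept values) and `replicates` turns the result into a [sweep_spec()].
#' Unknown keys -- including per-cell properties such as `E` or `G`, which
#' are state, not parameters -- are rejected by name.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `sim_params` or `sweep_spec` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: .", ext, " (use YAML or JSON)",
         call. = FALSE))
  if (is.null(cfg)) cfg <- list()
  sweep_block <- cfg$sweep
  cfg$sweep <- NULL
  unknown <- setdiff(names(cfg), config_param_keys)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  bad_type <- names(cfg)[!vapply(cfg, function(v)
    is.numeric(v) && length(v) == 1L, logical(1))]
  if (length(bad_type) > 0)
    stop("configuration key(s) must be single numbers: ",
         paste(bad_type, collapse = ", "), call. = FALSE)
  params <- do.call(sim_params, cfg)
  if (is.null(sweep_block)) return(params)
  sweep_spec(params,
             values = lapply(sweep_block$values, as.numeric),
             replicates = sweep_block$replicates %||% 5L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a trajectory to CSV
#'
#' Writes the per-iteration population summaries with a fixed column order
#' and full floating-point precision (17 significant digits), so that
#' [read_trajectory()] reproduces the values bit-exactly.
#'
#' @param summaries Summary data frame from [run_simulation()] (the
#'   `$summary` element is extracted from a `mac_sim` automatically).
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(summaries, path) {
  if (inherits(summaries, "mac_sim")) summaries <- summaries$summary
  if (!is.data.frame(summaries) || nrow(summaries) == 0L)
    stop("summaries must be a non-empty data frame", call. = FALSE)
  out <- summaries
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trajectory CSV written by [write_trajectory()]
#'
#' @param path CSV path.
#' @return A data frame of population summaries.
#' @export
read_trajectory <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = "numeric")
}

#' Write a run manifest
#'
#' A manifest captures everything needed to reproduce and audit a run:
#' the full parameter set (including the seed), the schema version,
#' end-state summaries, convergence report and collapse flag. Re-running
#' [run_simulation()] with the manifest's parameters reproduces the
#' trajectory exactly.
#'
#' @param sim A `mac_sim` from [run_simulation()].
#' @param path Output JSON path.
#' @param trajectory_path Optional path of the trajectory CSV this run was
#'   written to, recorded in the manifest.
#' @return The path, invisibly.
#' @export
write_manifest <- function(sim, path, trajectory_path = NULL) {
  stopifnot(inherits(sim, "mac_sim"))
  last <- sim$summary[nrow(sim$summary), ]
  s <- sim$summary
  span <- s$iteration[nrow(s)] - s$iteration[1L]
  conv <- detect_convergence(s, window = min(2000L, max(span, 1L)))
  manifest <- list(
    schema_version = MANIFEST_SCHEMA_VERSION,
    package_version = as.character(utils::packageVersion("macevol")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    params = unclass(sim$params),
    end_state = as.list(last),
    convergence = as.list(conv),
    collapsed = sim$collapsed,
    trajectory_path = trajectory_path
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a run manifest
#'
#' @param path JSON manifest path.
#' @return A list with a `params` element coerced back to [sim_params()].
#' @export
read_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$params <- do.call(sim_params, as.list(m$params))
  m
}
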