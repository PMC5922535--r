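# Run-configuration schema.  Every default is explicit here; load_config()
# validates user files against this structure and rejects unknown keys.
config_schema <- function() {
  list(
    network = list(topology = "line", n_neurons = NULL, coupling_strength = 1,
                   long_range = list()),
    drive = list(mode_rank = 1L, target_omega = NULL, center = NULL,
                 strengths = 1, half_length = NULL, max_half_length = NULL,
                 centers = NULL),
    solver = list(tolerance = 1e-10, max_iterations = 100L, damping = TRUE),
    integrator = list(rtol = 1e-9, atol = 1e-12, max_time = NULL, floor = NULL,
                      n_samples = 2000L),
    output = list(directory = "critnet-output", formats = "csv"),
    seed = 1L)
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, validates it against the package schema
#' (unknown keys are rejected, naming the offending key), and fills every
#' unset field with its documented default, so the returned object -- and
#' the run manifest written from it -- records the complete effective
#' configuration.
#'
#' @param path YAML file path.
#' @return An object of class `run_config` (nested list mirroring the
#'   schema: `network`, `drive`, `solver`, `integrator`, `output`, `seed`).
#' @seealso [dump_config()], [write_outputs()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    critnet_stop("critnet_config_error", sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path), error = function(e)
    critnet_stop("critnet_config_error",
                 sprintf("cannot parse %s: %s", path, conditionMessage(e))))
  validate_config(raw %||% list())
}

#' @rdname load_config
#' @param config a `run_config` (or compatible nested list).
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(drop_nulls(unclass(config)), path)
  invisible(path)
}

drop_nulls <- function(x) {
  if (!is.list(x)) return(x)
  x <- lapply(x, drop_nulls)
  x[!vapply(x, is.null, TRUE)]
}

#' Validate a configuration list against the schema
#'
#' @param raw nested list (for example from [load_config()] or built in
#'   code).
#' @return A complete `run_config` with defaults resolved.
#' @export
validate_config <- function(raw) {
  schema <- config_schema()
  if (!is.list(raw))
    critnet_stop("critnet_config_error", "configuration must be a mapping")
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    critnet_stop("critnet_config_error",
                 sprintf("unknown configuration key: `%s`", unknown[1]))
  cfg <- schema
  for (blk in names(raw)) {
    if (!is.list(schema[[blk]])) { cfg[[blk]] <- raw[[blk]]; next }
    if (!is.list(raw[[blk]]))
      critnet_stop("critnet_config_error",
                   sprintf("configuration block `%s` must be a mapping", blk))
    bad <- setdiff(names(raw[[blk]]), names(schema[[blk]]))
    if (length(bad))
      critnet_stop("critnet_config_error",
                   sprintf("unknown configuration key: `%s.%s`", blk, bad[1]))
    for (k in names(raw[[blk]])) cfg[[blk]][[k]] <- raw[[blk]][[k]]
  }
  if (is.null(cfg$network$n_neurons))
    critnet_stop("critnet_config_error", "`network.n_neurons` is required")
  cfg$network$n_neurons <- check_count(cfg$network$n_neurons, "network.n_neurons")
  cfg$network$coupling_strength <-
    check_positive(cfg$network$coupling_strength, "network.coupling_strength")
  if (!cfg$network$topology %in% c("line", "ring"))
    critnet_stop("critnet_config_error",
                 "`network.topology` must be \"line\" or \"ring\"")
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(yaml::as.yaml(drop_nulls(unclass(x))))
  invisible(x)
}

# build the network and driving mode described by a config
config_network <- function(config) {
  nw <- config$network
  if (nw$topology == "ring")
    ring_connectivity(nw$n_neurons, nw$coupling_strength, nw$long_range)
  else
    line_connectivity(nw$n_neurons, nw$coupling_strength)
}

config_mode <- function(config, connectivity) {
  sp <- eigenmodes(connectivity)
  if (!is.null(config$drive$target_omega))
    get_mode(sp, omega = config$drive$target_omega)
  else get_mode(sp, rank = config$drive$mode_rank)
}

#' Write experiment outputs and a run manifest
#'
#' Serializes a named list of results (anything with an
#' [as.data.frame()] method: spectra, steady-state grids, length-response
#' sets, suppression maps, decay scalings, traces) as CSV files with 12
#' significant digits, plus a `manifest.json` recording the package
#' version, the full effective configuration, the files written and a
#' convergence summary.  Re-running the same configuration reproduces the
#' CSV numeric content exactly (no experiment uses randomness).
#'
#' @param results named list of result objects (or a single object).
#' @param config the `run_config` (or compatible list) that produced them.
#' @param directory output directory; default taken from the config.
#' @return Invisibly, the vector of files written, with attribute
#'   `n_failed` (number of non-converged cells across all results) for use
#'   as a process exit status.
#' @export
write_outputs <- function(results, config = validate_config(list(network = list(n_neurons = 1))),
                          directory = NULL) {
  dir <- directory %||% config$output$directory
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    critnet_stop("critnet_io_error", sprintf("cannot create directory: %s", dir))
  if (!is.list(results) || !is.null(attr(results, "class")))
    results <- list(result = results)
  if (is.null(names(results)) || any(names(results) == ""))
    critnet_stop("critnet_invalid_argument", "`results` must be a named list")

  files <- character(0)
  n_failed <- 0L
  failed <- list()
  for (nm in names(results)) {
    df <- as.data.frame(results[[nm]])
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], signif, digits = 12)
    fp <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(df, fp, row.names = FALSE)
    files <- c(files, fp)
    if ("converged" %in% names(df) && any(!df$converged, na.rm = TRUE)) {
      bad <- df[!df$converged, , drop = FALSE]
      n_failed <- n_failed + nrow(bad)
      failed[[nm]] <- bad[intersect(c("strength", "half_length", "omega"),
                                    names(bad))]
    }
  }
  manifest <- list(
    package = "critnet",
    version = as.character(utils::packageVersion("critnet")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = drop_nulls(unclass(config)),
    files = basename(files),
    n_failed_cells = n_failed,
    failed_cells = failed)
  mf <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  structure(invisible(c(files, mf)), n_failed = n_failed)
}
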