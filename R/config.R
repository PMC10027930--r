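# Configuration loading and run-manifest helpers used by the analysis
# drivers: every run records its seed, solver settings and config hashes
# so numeric outputs are reproducible from the manifest alone.

#' Load dosing regimens from a YAML list
#'
#' @param path YAML file whose entries (or whose `regimens` key) are lists
#'   with `dose_mg`, `interval_h`, `infusion_h` and optional `label`.
#' @param group optional top-level key (e.g. `"stage3"` in the packaged
#'   CKD regimen file).
#' @param n_doses,start_h passed to every [dosing_regimen()].
#' @return List of [dosing_regimen()]s.
#' @export
load_regimens <- function(path, group = NULL, n_doses = 1, start_h = 0) {
  cfg <- yaml::read_yaml(path)
  entries <- if (!is.null(group)) cfg[[group]] else
    (cfg$regimens %||% cfg)
  if (is.null(entries))
    stop("configuration error: no regimens under group '", group, "' in ",
         path, call. = FALSE)
  lapply(entries, function(e) {
    dosing_regimen(e$dose_mg, e$interval_h, e$infusion_h,
                   n_doses = n_doses, start_h = start_h, label = e$label)
  })
}

#' Expand a regimen to repeated dosing over a horizon
#'
#' @param regimen a single-dose [dosing_regimen()] template.
#' @param horizon_h horizon, h; the number of doses becomes
#'   `floor(horizon / interval)`.
#' @return A [dosing_regimen()] with `n_doses` filled in.
#' @export
repeat_regimen <- function(regimen, horizon_h) {
  dosing_regimen(regimen$dose_mg, regimen$interval_h, regimen$infusion_h,
                 n_doses = max(1L, floor(horizon_h / regimen$interval_h)),
                 start_h = regimen$start_h, label = regimen$label)
}

#' Write a run manifest
#'
#' Records the seed, solver settings, package version and the MD5 hash of
#' every config file involved in a run.
#'
#' @param path output JSON path.
#' @param seed integer seed of the run.
#' @param config_files character vector of config paths.
#' @param settings named list of additional settings to record.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, seed, config_files = character(),
                               settings = list()) {
  manifest <- list(
    package = "meropbpk",
    version = as.character(utils::packageVersion("meropbpk")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    configs = if (length(config_files)) {
      setNames(as.list(unname(tools::md5sum(config_files))), config_files)
    } else list(),
    settings = settings
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
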