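#' Study-default pipeline configuration
#'
#' All tunables of the pipeline with their study defaults: 0.25-40 Hz
#' zero-phase band-pass, -100..800 ms epochs baselined on -100..0 ms,
#' canonical first-pass peak windows (P2 at FCz 200-280 ms, N2 at FCz
#' 280-380 ms, P3 at CPz 350-500 ms, re-centered per group by +/-25 ms for
#' P2/N2 and +/-50 ms for P3 in the second pass), cluster alpha 0.05 with a
#' 10-consecutive-sample run criterion, and gait peak-detection parameters.
#'
#' @return nested list of class `mobi_config`.
#' @export
default_config <- function() {
  structure(list(
    filter = list(low = 0.25, high = 40),
    epoch = list(window = c(-100, 800), baseline = c(-100, 0),
                 baseline_correct = TRUE),
    peaks = list(
      P2 = list(electrode = "FCz", window = c(200, 280), polarity = 1,
                half_width = 25),
      N2 = list(electrode = "FCz", window = c(280, 380), polarity = -1,
                half_width = 25),
      P3 = list(electrode = "CPz", window = c(350, 500), polarity = 1,
                half_width = 50)),
    cluster = list(alpha = 0.05, min_run = 10),
    gait = list(min_stride_time = 600, min_prominence = 20,
                smooth = TRUE, smooth_ms = 50),
    seed = 1
  ), class = "mobi_config")
}

merge_config <- function(base, user, path = character()) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(base))
      stopf("unknown config key%s: %s",
            if (length(path)) "" else "(s)", here)
    if (is.list(base[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        stopf("config key %s must be a mapping", here)
      base[[key]] <- merge_config(base[[key]], user[[key]], c(path, key))
    } else {
      base[[key]] <- user[[key]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' Absent keys fall back to the study defaults of [default_config()];
#' unknown keys raise an error naming them rather than being silently
#' ignored.
#'
#' @param path YAML file; an empty file yields the full default config.
#' @return `mobi_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(user)) return(cfg)
  if (!is.list(user)) stopf("config must be a YAML mapping")
  structure(merge_config(unclass(cfg), user), class = "mobi_config")
}

#' Write a configuration to YAML
#'
#' Round-trips losslessly through [load_config()].
#'
#' @param config `mobi_config` list.
#' @param path output file.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

## stable hash of a config for run manifests
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Write result tables and a run summary
#'
#' Writes each table as tidy CSV under `out_dir` and a `run_summary.json`
#' recording the seed, the config hash, and the file manifest.
#'
#' @param tables named list of data.frames.
#' @param out_dir output directory, created if needed.
#' @param config `mobi_config` used for the run.
#' @param seed integer seed used for the run.
#' @param warnings character vector of per-stage warnings to record.
#' @return invisibly, the manifest (named vector of file paths).
#' @export
write_results <- function(tables, out_dir, config = default_config(),
                          seed = config$seed, warnings = character()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character()
  for (nm in names(tables)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    manifest[nm] <- f
  }
  summary <- list(seed = seed, config_hash = config_hash(config),
                  files = as.list(manifest), warnings = warnings)
  sf <- file.path(out_dir, "run_summary.json")
  jsonlite::write_json(summary, sf, auto_unbox = TRUE, pretty = TRUE)
  manifest["run_summary"] <- sf
  invisible(manifest)
}
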