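#' Columnar text I/O with JSON manifests
#'
#' All recordings travel as delimited columnar text (one time column plus
#' one column per channel) with a JSON sidecar manifest carrying sample
#' rate, parameters and segment tables — readable by any tool, diffable,
#' and sufficient to regenerate an analysis.
#'
#' @name io
NULL

#' Write a sampled time series with a JSON manifest
#'
#' @param x Numeric vector or matrix (samples x channels).
#' @param fs Sample rate in Hz.
#' @param path Output path for the tab-delimited table (`time_s` first
#'   column); the manifest is written to `paste0(path, ".json")`.
#' @param manifest Named list of extra metadata (parameters, segments,
#'   pulse times); `fs` is always included.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(x, fs, path, manifest = list()) {
  x <- as.matrix(x)
  df <- data.frame(time_s = (seq_len(nrow(x)) - 1) / fs, x)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  manifest$fs <- fs
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a time series written by [write_timeseries()]
#'
#' @param path Path to the tab-delimited table.
#' @return List with `data` (matrix, channels only), `time_s`, `fs`,
#'   `manifest`.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  man_path <- paste0(path, ".json")
  manifest <- if (file.exists(man_path))
    jsonlite::read_json(man_path, simplifyVector = TRUE) else list()
  fs <- manifest$fs
  if (is.null(fs)) fs <- 1 / stats::median(diff(df$time_s))
  list(data = as.matrix(df[, -1, drop = FALSE]), time_s = df$time_s,
       fs = fs, manifest = manifest)
}

#' Write an experiment run's results bundle
#'
#' Writes the tidy result table (`results.tsv`), a manifest with the
#' config and seed (`manifest.json`) and, where present, the fixed-effect
#' table of the fitted model (`model.tsv`).
#'
#' @param run An `entrain_run` from [run_experiment()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "entrain_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$results, file.path(dir, "results.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(experiment = run$name, seed = run$seed, config = run$config,
         package_version = as.character(utils::packageVersion("entrainr"))),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(run$model))
    utils::write.table(run$model$coefficients, file.path(dir, "model.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read a pipeline configuration file
#'
#' YAML (if the `yaml` package is available) or JSON, by file extension.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config document.
#' @return Named list suitable for the `config` argument of
#'   [run_experiment()].
#' @export
read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the 'yaml' package",
           call. = FALSE)
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
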