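#' Read an RRI series from a file
#'
#' Accepts two dialects: a CSV with an `rri_ms` column (optionally a
#' `t_ms` timestamp column) or an `rri_s` column in seconds, which is
#' converted to ms; or plain text with one interval per line (assumed ms).
#' Non-positive or unparseable values are rejected with their line numbers.
#'
#' @param path file path.
#' @return numeric RRI series (ms); if a `t_ms` column was present it is
#'   attached as the `"t_ms"` attribute.
#' @export
read_rri <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  first <- readLines(path, n = 1)
  is_csv <- grepl("rri_ms|rri_s", first)
  if (is_csv) {
    df <- utils::read.csv(path)
    if ("rri_ms" %in% names(df)) {
      vals <- as.numeric(df$rri_ms)
    } else if ("rri_s" %in% names(df)) {
      vals <- as.numeric(df$rri_s) * 1000
    } else {
      stop("CSV must contain an 'rri_ms' or 'rri_s' column")
    }
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad))
      stop(sprintf("non-positive or malformed RRI value(s) on data row(s) %s",
                   paste(utils::head(bad, 10), collapse = ", ")))
    if ("t_ms" %in% names(df)) attr(vals, "t_ms") <- as.numeric(df$t_ms)
    return(vals)
  }
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  bad <- which(!is.finite(vals) | vals <= 0)
  if (length(bad))
    stop(sprintf("non-positive or malformed RRI value(s) on line(s) %s",
                 paste(utils::head(bad, 10), collapse = ", ")))
  vals
}

#' Write an RRI series to CSV
#'
#' Writes the standard dialect: columns `rri_ms` and `t_ms` (cumulative
#' beat time).
#'
#' @param series RRI series (ms).
#' @param path output path.
#' @export
write_rri <- function(series, path) {
  x <- as.numeric(series)
  utils::write.csv(data.frame(rri_ms = x, t_ms = cumsum(x)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Write interpolation events to CSV
#'
#' @param events event data frame from [process_stream()].
#' @param path output path.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' Load a run configuration from a YAML file
#'
#' Recognised top-level keys: `interpolator` (fields of
#' [interpolator_config()]), `hrv` (fields of [spectral_config()]) and
#' `simulation` (`alphas`, `reps`, `base_seed`). Missing keys fall back to
#' the package defaults; every value is validated by the corresponding
#' constructor.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list with `interpolator`, `hrv`, `simulation`.
#' @export
read_run_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read configuration files")
    yaml::read_yaml(path)
  }
  interp <- do.call(interpolator_config,
                    raw$interpolator %||% list())
  hrv <- do.call(spectral_config, raw$hrv %||% list())
  sim <- utils::modifyList(
    list(alphas = c(0.003, 0.005, 0.01), reps = 30, base_seed = 20181110),
    raw$simulation %||% list())
  list(interpolator = interp, hrv = hrv, simulation = sim)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
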