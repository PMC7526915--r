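#' Read an impedance signal from CSV
#'
#' Expects a header line and two columns, `time_s` and `impedance_ohm`, with
#' `.` as decimal separator. The sampling rate is inferred from the median
#' time step; the loader rejects files whose sampling deviates from uniform
#' by more than `jitter_tol_s` or which contain non-finite values, naming the
#' offending row.
#'
#' @param path Path to the CSV file.
#' @param jitter_tol_s Maximum tolerated deviation of any time step from the
#'   median step, in seconds.
#' @return A [impedance_signal()].
#' @export
read_signal_csv <- function(path, jitter_tol_s = 1e-6) {
  if (!file.exists(path)) {
    abort(sprintf("Signal file not found: %s", path), class = "ccrate_io_error")
  }
  df <- read.csv(path)
  if (!all(c("time_s", "impedance_ohm") %in% names(df))) {
    abort("Signal CSV must have columns `time_s` and `impedance_ohm`.",
          class = "ccrate_io_error")
  }
  bad <- which(!is.finite(df$time_s) | !is.finite(df$impedance_ohm))
  if (length(bad)) {
    abort(sprintf("Non-finite value in signal CSV at data row %d.", bad[1]),
          class = "ccrate_io_error")
  }
  if (nrow(df) < 2) {
    abort("Signal CSV needs at least two samples to infer the sampling rate.",
          class = "ccrate_io_error")
  }
  dt <- diff(df$time_s)
  step <- median(dt)
  if (step <= 0 || any(abs(dt - step) > jitter_tol_s)) {
    off <- which(abs(dt - step) > jitter_tol_s)[1]
    abort(sprintf("Non-uniform sampling in signal CSV near data row %d (step %.9g s vs %.9g s).",
                  off + 1, dt[off], step),
          class = "ccrate_io_error")
  }
  impedance_signal(df$impedance_ohm, fs = 1 / step, t0 = df$time_s[1])
}

#' Write an impedance signal to CSV
#'
#' Inverse of [read_signal_csv()]: two columns `time_s,impedance_ohm` with a
#' header. Values are written in full precision so a write/read round trip
#' reproduces the samples bit for bit.
#'
#' @param signal A [impedance_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_csv <- function(signal, path) {
  stopifnot(inherits(signal, "ti_signal"))
  df <- data.frame(
    time_s = format(signal$time_s, digits = 17, trim = TRUE, scientific = FALSE),
    impedance_ohm = format(signal$impedance_ohm, digits = 17, trim = TRUE)
  )
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write detector results as CSV
#'
#' The results table has columns
#' `window_index,start_s,end_s,detected,rate_cpm,peak_lag_s,peak_score`;
#' rates are stored at full precision.
#'
#' @param results A detection results tibble from [detect_compressions()].
#' @param path File path.
#' @return `read_results_csv()` returns the results tibble;
#'   `write_results_csv()` returns `path` invisibly.
#' @export
write_results_csv <- function(results, path) {
  write.csv(results, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Results file not found: %s", path), class = "ccrate_io_error")
  }
  df <- as_tibble(read.csv(path))
  need <- c("window_index", "start_s", "detected", "rate_cpm")
  if (!all(need %in% names(df))) {
    abort("Results CSV is missing required columns.", class = "ccrate_io_error")
  }
  df$detected <- as.logical(df$detected)
  df
}

#' Write a run manifest
#'
#' Every command-line run records, next to its outputs, the command name, the
#' configuration snapshot, input/output paths, seeds, the package version and
#' a timestamp; re-running a deterministic command with the same manifest
#' inputs reproduces its outputs bit for bit.
#'
#' @param path Manifest path (JSON).
#' @param command Command name.
#' @param inputs,outputs Named lists of file paths.
#' @param config Optional `detector_config` snapshot.
#' @param seed Optional seed(s).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, command, inputs = list(), outputs = list(),
                           config = NULL, seed = NULL) {
  payload <- list(
    command = command,
    inputs = inputs,
    outputs = outputs,
    config = if (!is.null(config)) unclass(config),
    seed = seed,
    package_version = as.character(packageVersion("ccrate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
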