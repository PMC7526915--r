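#' Run the detector on a single preprocessed window
#'
#' Composes [biased_autocorrelation()], [normalize_autocorrelation()] and
#' [find_rate_peak()]. A window with a qualifying periodicity peak is reported
#' as containing compressions with the rate implied by the peak lag; any other
#' window is reported with rate 0.
#'
#' @param samples Numeric vector: one preprocessed (filtered, zero-mean)
#'   analysis window.
#' @param config A [detector_config()].
#' @param window_index Index recorded in the result (0-based).
#' @return A one-row tibble: `window_index`, `detected`, `rate_cpm` (0 when
#'   not detected), `peak_lag_s` and `peak_score` (`NA` when not detected).
#' @export
process_window <- function(samples, config = detector_config(),
                           window_index = 0L) {
  acf <- biased_autocorrelation(samples, config$lag_max_s, config$fs_target)
  peak <- find_rate_peak(normalize_autocorrelation(acf), config)
  if (is.null(peak)) {
    tibble(window_index = as.integer(window_index), detected = FALSE,
           rate_cpm = 0, peak_lag_s = NA_real_, peak_score = NA_real_)
  } else {
    tibble(window_index = as.integer(window_index), detected = TRUE,
           rate_cpm = lag_to_rate(peak$lag_s), peak_lag_s = peak$lag_s,
           peak_score = peak$score)
  }
}

#' Detect chest compressions over a whole episode
#'
#' The top-level detector: resamples the impedance trace to the working rate
#' if needed, low-pass filters it once, cuts it into consecutive
#' non-overlapping 2-s windows, and emits one detection result per window
#' from the beginning to the end of the available signal. The output cadence
#' is one value per `config$window_s` seconds: an estimated compression rate
#' when compression activity is detected in the window, zero otherwise.
#'
#' @param signal A [impedance_signal()].
#' @param config A [detector_config()].
#' @return A tibble with one row per full window: `window_index`, `start_s`,
#'   `end_s`, `detected`, `rate_cpm`, `peak_lag_s`, `peak_score`.
#' @examples
#' scn <- episode_scenario(duration_s = 30, rate_cpm_mean = 110, seed = 1)
#' ep <- generate_episode(scn)
#' detect_compressions(ep$signal)
#' @export
detect_compressions <- function(signal, config = detector_config()) {
  stopifnot(inherits(signal, "ti_signal"))
  signal <- resample_signal(signal, config$fs_target)
  windows <- segment_windows(signal, config)
  if (nrow(windows) == 0) {
    return(dplyr::bind_cols(
      windows[, c("window_index", "start_s", "end_s")],
      tibble(detected = logical(), rate_cpm = numeric(),
             peak_lag_s = numeric(), peak_score = numeric())
    ))
  }
  filtered <- preprocess_signal(signal, config)
  windows$samples <- segment_windows(filtered, config)$samples
  res <- purrr::map2(windows$samples, windows$window_index, function(x, i) {
    process_window(preprocess_window(x, config, filter = FALSE), config,
                   window_index = i)
  })
  dplyr::bind_cols(
    windows[, c("window_index", "start_s", "end_s")],
    dplyr::bind_rows(res)[, c("detected", "rate_cpm", "peak_lag_s", "peak_score")]
  )
}

#' Alias for the per-episode detector
#'
#' `process_episode()` is the protocol-level name for running the detector
#' from the beginning to the end of an episode; it is identical to
#' [detect_compressions()].
#'
#' @inheritParams detect_compressions
#' @return See [detect_compressions()].
#' @export
process_episode <- function(signal, config = detector_config()) {
  detect_compressions(signal, config)
}
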