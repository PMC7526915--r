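#' Construct a transthoracic impedance signal
#'
#' A `ti_signal` is a tibble with columns `time_s` and `impedance_ohm` holding
#' a uniformly sampled, baseline-suppressed transthoracic impedance trace,
#' together with its sampling frequency (`fs`) and start time (`t0`) stored as
#' attributes. Chest compressions appear in such a trace as quasi-periodic
#' fluctuations around zero, one per compression; the slowly varying patient
#' baseline is assumed to have been removed by the recording device's
#' high-pass filter.
#'
#' @param samples Numeric vector of impedance values in ohms. Must be finite.
#' @param fs Sampling frequency in Hz (positive).
#' @param t0 Start time of the first sample in seconds (default 0).
#'
#' @return A tibble of class `ti_signal` with columns `time_s`, `impedance_ohm`.
#' @examples
#' sig <- impedance_signal(sin(2 * pi * 2 * seq(0, 2, by = 1 / 250)), fs = 250)
#' sig
#' @export
impedance_signal <- function(samples, fs, t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1) {
    abort("A signal needs at least one sample.", class = "ccrate_signal_error")
  }
  if (!all(is.finite(samples))) {
    bad <- which(!is.finite(samples))[1]
    abort(sprintf("Non-finite sample at position %d.", bad),
          class = "ccrate_signal_error")
  }
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number.",
          class = "ccrate_config_error")
  }
  out <- tibble(
    time_s = t0 + (seq_along(samples) - 1) / fs,
    impedance_ohm = samples
  )
  attr(out, "fs") <- as.numeric(fs)
  attr(out, "t0") <- as.numeric(t0)
  class(out) <- c("ti_signal", class(out))
  out
}

#' Signal accessors
#'
#' @param signal A [impedance_signal()] object.
#' @return `signal_fs()` the sampling frequency in Hz, `signal_t0()` the start
#'   time in seconds, `signal_samples()` the bare numeric sample vector,
#'   `signal_duration()` the duration `n / fs` in seconds.
#' @export
signal_fs <- function(signal) attr(signal, "fs")

#' @rdname signal_fs
#' @export
signal_t0 <- function(signal) attr(signal, "t0")

#' @rdname signal_fs
#' @export
signal_samples <- function(signal) signal$impedance_ohm

#' @rdname signal_fs
#' @export
signal_duration <- function(signal) nrow(signal) / signal_fs(signal)

#' @export
print.ti_signal <- function(x, ...) {
  cat(sprintf("<ti_signal> %d samples at %.6g Hz (%.6g s, t0 = %.6g s)\n",
              nrow(x), signal_fs(x), signal_duration(x), signal_t0(x)))
  NextMethod()
}

# ---- zero-phase IIR filtering --------------------------------------------

# Steady-state initial conditions of a direct-form-II-transposed IIR filter,
# so that filtering a constant input yields that constant from sample one.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  A <- diag(1, n - 1) - cbind(-a[2:n], rbind(diag(1, n - 2), 0))
  solve(A, b[2:n] - a[2:n] * b[1])
}

# One pass of the IIR filter with initial state z (transposed direct form II).
iir_filter <- function(b, a, x, z) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    out[i] <- b[1] * x[i] + z[1]
    if (n > 2) {
      for (j in seq_len(n - 2)) {
        z[j] <- b[j + 1] * x[i] + z[j + 1] - a[j + 1] * out[i]
      }
    }
    z[n - 1] <- b[n] * x[i] - a[n] * out[i]
  }
  out
}

# Zero-phase forward-backward filtering with odd-reflection padding and
# steady-state initialization at both ends. Transients from naive
# forward-backward application shift the autocorrelation peak of long-period
# windows by a lag sample; the padding suppresses them.
filtfilt_zp <- function(b, a, x) {
  n <- max(length(a), length(b))
  pad <- 3L * (n - 1L)
  if (length(x) <= pad) {
    abort(sprintf("Signal too short to filter (need > %d samples).", pad),
          class = "ccrate_signal_error")
  }
  m <- length(x)
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[m] - x[(m - 1):(m - pad)])
  zi <- lfilter_zi(b, a)
  y <- iir_filter(b, a, ext, zi * ext[1])
  y <- rev(iir_filter(b, a, rev(y), zi * y[length(y)]))
  y[(pad + 1):(pad + m)]
}

lowpass_coefs <- function(config) {
  signal::butter(config$lpf_order,
                 config$lpf_cutoff_hz / (config$fs_target / 2),
                 type = "low")
}

# ---- resampling -----------------------------------------------------------

#' Resample a signal to a target sampling frequency
#'
#' Evaluates the band-limited trace on the new uniform grid over the same
#' time span. When downsampling, a zero-phase Butterworth anti-alias filter
#' (8th order, cutoff at 45% of the target rate) is applied first; the values
#' at the new sample times are then obtained by cubic spline evaluation.
#' The identity case (`fs_target == fs`) returns the signal unchanged.
#'
#' @param signal A [impedance_signal()].
#' @param fs_target Target sampling frequency in Hz.
#' @return A `ti_signal` sampled at `fs_target`, spanning the same duration
#'   to within one output sample.
#' @examples
#' sig <- impedance_signal(sin(2 * pi * 2 * (0:4999) / 500), fs = 500)
#' resample_signal(sig, 250)
#' @export
resample_signal <- function(signal, fs_target) {
  stopifnot(inherits(signal, "ti_signal"))
  if (!is.numeric(fs_target) || length(fs_target) != 1 || fs_target <= 0) {
    abort("`fs_target` must be a single positive number.",
          class = "ccrate_config_error")
  }
  fs <- signal_fs(signal)
  if (isTRUE(all.equal(fs, fs_target))) {
    return(signal)
  }
  x <- signal_samples(signal)
  if (fs_target < fs) {
    aa <- signal::butter(8, 0.9 * (fs_target / 2) / (fs / 2), type = "low")
    x <- filtfilt_zp(aa$b, aa$a, x)
  }
  n_out <- floor(length(x) * fs_target / fs)
  t_old <- (seq_along(x) - 1) / fs
  t_new <- (seq_len(n_out) - 1) / fs_target
  y <- spline(t_old, x, xout = t_new, method = "natural")$y
  impedance_signal(y, fs = fs_target, t0 = signal_t0(signal))
}

# ---- preprocessing and windowing -----------------------------------------

#' Low-pass filter a whole episode
#'
#' Applies the detector's zero-phase low-pass once to the full trace. The
#' detector filters the episode as a whole (rather than each 2-s window
#' separately) so that windows interior to the episode carry no filter edge
#' transients.
#'
#' @param signal A [impedance_signal()] at the working sampling rate.
#' @param config A [detector_config()].
#' @return A filtered `ti_signal`.
#' @export
preprocess_signal <- function(signal, config = detector_config()) {
  stopifnot(inherits(signal, "ti_signal"))
  bf <- lowpass_coefs(config)
  impedance_signal(filtfilt_zp(bf$b, bf$a, signal_samples(signal)),
                   fs = signal_fs(signal), t0 = signal_t0(signal))
}

#' Cut a signal into consecutive non-overlapping analysis windows
#'
#' Windows are anchored at the episode start and tile the signal exactly; a
#' trailing stretch shorter than one full window is discarded, never padded.
#'
#' @param signal A [impedance_signal()] at `config$fs_target`.
#' @param config A [detector_config()].
#' @return A tibble with one row per window: `window_index` (0-based),
#'   `start_s`, `end_s` (half-open bounds) and `samples` (list column of
#'   numeric vectors of length `round(window_s * fs)`). A signal shorter than
#'   one window yields zero rows.
#' @examples
#' sig <- impedance_signal(rnorm(2500), fs = 250)
#' segment_windows(sig, detector_config())
#' @export
segment_windows <- function(signal, config = detector_config()) {
  stopifnot(inherits(signal, "ti_signal"))
  fs <- signal_fs(signal)
  n_win <- round(config$window_s * fs)
  n <- nrow(signal)
  k <- floor(n / n_win)
  if (k < 1) {
    return(tibble(window_index = integer(), start_s = numeric(),
                  end_s = numeric(), samples = list()))
  }
  x <- signal_samples(signal)
  t0 <- signal_t0(signal)
  idx <- 0:(k - 1)
  tibble(
    window_index = idx,
    start_s = t0 + idx * config$window_s,
    end_s = t0 + (idx + 1) * config$window_s,
    samples = lapply(idx, function(i) x[(i * n_win + 1):((i + 1) * n_win)])
  )
}

#' Preprocess one analysis window
#'
#' Low-pass filters the window (zero-phase, within the window) and removes its
#' mean. When the episode has already been filtered as a whole with
#' [preprocess_signal()], set `filter = FALSE` so that only the mean is
#' removed; residual offsets would otherwise inflate the lag-0
#' autocorrelation and mask the periodicity peak.
#'
#' @param samples Numeric vector, one full analysis window.
#' @param config A [detector_config()].
#' @param filter Apply the low-pass within the window (default `TRUE`).
#' @return Numeric vector of the same length with zero mean.
#' @export
preprocess_window <- function(samples, config = detector_config(),
                              filter = TRUE) {
  x <- as.numeric(samples)
  if (filter) {
    bf <- lowpass_coefs(config)
    x <- filtfilt_zp(bf$b, bf$a, x)
  }
  x - mean(x)
}
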