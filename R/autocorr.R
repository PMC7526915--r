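#' Biased autocorrelation estimate of a window
#'
#' Computes the biased estimator
#' \deqn{r[k] = \frac{1}{N} \sum_{n=0}^{N-1-k} x[n]\, x[n+k]}
#' for lags `k = 0 .. round(max_lag_s * fs)`. Dividing by the full window
#' length `N` (rather than `N - k`) guarantees `|r[k]| <= r[0]`, which makes
#' thresholding on the normalized function meaningful. The computation is
#' transform-based (zero-padded FFT) and agrees with the direct double-loop
#' definition to machine precision.
#'
#' The overlap energies
#' `e_head[k] = sum(x[0..N-1-k]^2)` and `e_tail[k] = sum(x[k..N-1]^2)` are
#' computed alongside; [normalize_autocorrelation()] uses them to build a
#' truncation-invariant periodicity score.
#'
#' @param x Numeric vector, a preprocessed (zero-mean) analysis window.
#' @param max_lag_s Maximum lag in seconds; `max_lag_s * fs` must be smaller
#'   than `length(x)`.
#' @param fs Sampling frequency in Hz.
#' @return A `cc_acf` object: a tibble with columns `lag_s` and `r`, carrying
#'   `fs`, `n` (window length) and the overlap energies as attributes.
#' @examples
#' biased_autocorrelation(c(1, -1, 1, -1), max_lag_s = 2, fs = 1)
#' @export
biased_autocorrelation <- function(x, max_lag_s, fs) {
  x <- as.numeric(x)
  n <- length(x)
  if (!all(is.finite(x))) {
    abort("Window contains non-finite samples.", class = "ccrate_signal_error")
  }
  k_max <- round(max_lag_s * fs)
  if (k_max >= n) {
    abort(sprintf("max_lag_s (%g s = %d samples) must be shorter than the window (%d samples).",
                  max_lag_s, k_max, n),
          class = "ccrate_config_error")
  }
  nfft <- nextn(2L * n, 2)
  X <- fft(c(x, rep(0, nfft - n)))
  r <- (Re(fft(Mod(X)^2, inverse = TRUE)) / nfft / n)[1:(k_max + 1)]
  cs <- cumsum(x^2)
  k <- 0:k_max
  out <- tibble(lag_s = k / fs, r = r)
  attr(out, "fs") <- fs
  attr(out, "n") <- n
  attr(out, "e_head") <- cs[n - k]
  attr(out, "e_tail") <- cs[n] - c(0, cs[k[-1]])
  attr(out, "normalized") <- FALSE
  class(out) <- c("cc_acf", class(out))
  out
}

#' Normalize an autocorrelation function
#'
#' Adds two normalized views of the biased autocorrelation:
#' * `rho = r[k] / r[0]`, the classical amplitude-normalized function with
#'   `rho[0] = 1` and `|rho[k]| <= 1`;
#' * `score = 2 N r[k] / (e_head[k] + e_tail[k])`, which renormalizes each lag
#'   by the energy actually present in the two overlapping segments. For a
#'   perfectly periodic window the score reaches 1 at the period regardless of
#'   where the window cuts the waveform, so peak position and height do not
#'   inherit the `(N - k) / N` taper of the biased estimate.
#'
#' A window with (numerically) zero energy is flagged as null; the peak search
#' treats a null function as "no compressions".
#'
#' @param acf A `cc_acf` from [biased_autocorrelation()].
#' @param null_floor Energy floor: if `r[0]` does not exceed it, the function
#'   is flagged null rather than divided by a vanishing number.
#' @return The same tibble with columns `rho` and `score` added and attribute
#'   `normalized = TRUE`; attribute `null` records degeneracy.
#' @export
normalize_autocorrelation <- function(acf, null_floor = 1e-30) {
  stopifnot(inherits(acf, "cc_acf"))
  if (isTRUE(attr(acf, "normalized"))) {
    abort("Autocorrelation is already normalized.", class = "ccrate_contract_error")
  }
  r0 <- acf$r[1]
  if (!is.finite(r0) || r0 <= null_floor) {
    acf$rho <- rep(0, nrow(acf))
    acf$score <- rep(0, nrow(acf))
    attr(acf, "null") <- TRUE
  } else {
    acf$rho <- acf$r / r0
    e <- attr(acf, "e_head") + attr(acf, "e_tail")
    acf$score <- 2 * attr(acf, "n") * acf$r / pmax(e, null_floor)
    attr(acf, "null") <- FALSE
  }
  attr(acf, "normalized") <- TRUE
  acf
}

#' Convert a peak lag to a compression rate
#'
#' The selected autocorrelation peak lag is the average time between
#' consecutive compressions; its inverse, scaled to a minute, is the average
#' compression rate: `rate_cpm = 60 / lag_s`. The bounds of the default lag
#' range map to the detectable rate range: 1.0 s gives 60 cpm and 0.24 s gives
#' 250 cpm.
#'
#' @param lag_s Peak lag in seconds (positive).
#' @return Rate in compressions per minute.
#' @examples
#' lag_to_rate(0.5)
#' @export
lag_to_rate <- function(lag_s) {
  if (any(!is.finite(lag_s) | lag_s <= 0)) {
    abort("`lag_s` must be positive and finite.", class = "ccrate_domain_error")
  }
  60 / lag_s
}

#' Locate the compression-rate peak of a normalized autocorrelation
#'
#' Searches the closed lag range `[lag_min_s, lag_max_s]` for local maxima of
#' the normalized score and returns the one at the smallest lag whose height
#' reaches `config$threshold`. Taking the smallest qualifying lag selects the
#' fundamental period rather than one of its multiples, so the rate cannot be
#' halved by a peak at twice the period. A lag-grid boundary sample qualifies
#' only if it exceeds its single interior neighbour; on an interior plateau
#' the first sample wins. With `config$require_dip` the score must in
#' addition have dipped below zero at some lag before the candidate, which is
#' always true of genuinely periodic zero-mean fluctuations but not of slow
#' monotone artifacts.
#'
#' During a compression pause the autocorrelation has no prominent maximum in
#' the range and `NULL` is returned; the window is then classified as
#' "no compressions".
#'
#' @param acf A normalized `cc_acf` (see [normalize_autocorrelation()]).
#' @param config A [detector_config()].
#' @return `NULL` if no qualifying peak exists, otherwise a list with
#'   `lag_s` (parabolically refined if `config$interpolate`) and `score` (the
#'   integer-lag peak height, the value the threshold was applied to).
#' @export
find_rate_peak <- function(acf, config = detector_config()) {
  stopifnot(inherits(acf, "cc_acf"))
  if (!isTRUE(attr(acf, "normalized"))) {
    abort("Normalize the autocorrelation first.", class = "ccrate_contract_error")
  }
  if (isTRUE(attr(acf, "null"))) {
    return(NULL)
  }
  fs <- attr(acf, "fs")
  v <- acf$score
  k_min <- ceiling(config$lag_min_s * fs - 1e-9)
  k_max <- floor(config$lag_max_s * fs + 1e-9)
  k_hi <- nrow(acf) - 1L
  if (k_max > k_hi) {
    abort("Autocorrelation does not cover the configured lag range.",
          class = "ccrate_config_error")
  }
  for (k in k_min:k_max) {
    i <- k + 1L
    is_peak <-
      if (k == k_min) {
        v[i] > v[i - 1] && v[i] > v[i + 1]
      } else if (k == k_max) {
        v[i] > v[i - 1]
      } else {
        v[i] > v[i - 1] && v[i] >= v[i + 1]
      }
    if (!is_peak || v[i] < config$threshold) next
    if (config$require_dip && min(v[2:i]) >= 0) next
    lag <- k / fs
    if (config$interpolate && k > k_min && k < k_max) {
      a <- v[i - 1]; b <- v[i]; cc <- v[i + 1]
      den <- a - 2 * b + cc
      if (den < 0) {
        lag <- (k + (a - cc) / (2 * den)) / fs
        lag <- min(max(lag, config$lag_min_s), config$lag_max_s)
      }
    }
    return(list(lag_s = lag, score = v[i]))
  }
  NULL
}
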