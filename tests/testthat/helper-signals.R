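# Shared fixtures: all built in code, no stored data.

# A pure sinusoid of given period, as an impedance signal.
sine_signal <- function(period_s, duration_s = 2, fs = 250, phase = 0,
                        amplitude = 1) {
  n <- round(duration_s * fs)
  impedance_signal(amplitude * sin(2 * pi * (0:(n - 1)) / fs / period_s + phase),
                   fs = fs)
}

# Direct time-domain oracle for the biased autocorrelation estimate:
# r[k] = (1/N) sum_{n=0}^{N-1-k} x[n] x[n+k], straight from the definition.
acf_oracle <- function(x, k_max) {
  n <- length(x)
  vapply(0:k_max, function(k) sum(x[1:(n - k)] * x[(1 + k):n]) / n, numeric(1))
}

# Noiseless, jitter-free scenario at a given rate with continuous compressions.
clean_scenario <- function(rate_cpm, duration_s = 30, seed = 1) {
  episode_scenario(
    duration_s = duration_s, rate_cpm_mean = rate_cpm,
    rate_cpm_jitter_sd = 0, ccf_target = 1,
    ventilation_amp_ohm = 0, drift_amp_ohm = 0, noise_sd_ohm = 0,
    seed = seed
  )
}

# One-lag quantization step of the rate estimate at a given reference rate.
rate_quant_step <- function(rate_cpm, fs = 250) {
  k <- round(60 / rate_cpm * fs)
  60 / (k / fs) - 60 / ((k + 1) / fs)
}

# Evaluated corpus from a benchmark tibble.
run_corpus <- function(bench, config = detector_config()) {
  bench$results <- purrr::map(bench$signal, detect_compressions, config = config)
  bench$references <- purrr::map2(bench$annotation, bench$results, label_windows)
  bench
}
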