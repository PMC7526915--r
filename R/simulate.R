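#' Scenario for a synthetic resuscitation episode
#'
#' Describes the statistical structure of a synthetic transthoracic impedance
#' episode: alternating chest compression series and pauses whose total
#' durations realize a target chest compression fraction (CCF), compression
#' instants following a jittered rate, a quasi-sinusoidal impedance
#' fluctuation per compression with configurable harmonic content, plus slow
#' ventilation and baseline-drift components and additive Gaussian noise.
#'
#' Defaults mirror the central tendencies observed in out-of-hospital AED
#' recordings: mean compression rate 173 cpm, CCF 0.68, fluctuation amplitude
#' 1 ohm against noise of 0.1 ohm SD. Ventilation and drift amplitudes are
#' residuals after the recording device's baseline-suppressing high-pass.
#'
#' @param duration_s Episode length in seconds.
#' @param rate_cpm_mean Mean compression rate in cpm. Must lie inside
#'   `rate_bounds`; the default bounds comfortably cover the 56--294 cpm range
#'   seen in field data.
#' @param rate_cpm_jitter_sd Per-compression rate jitter SD in cpm; applied as
#'   Gaussian jitter on each inter-compression interval, truncated at ±20% of
#'   the nominal period so a window's instantaneous rate stays coherent.
#' @param ccf_target Intended chest compression fraction in `[0, 1]`.
#' @param fluctuation_amp_ohm Peak amplitude of the per-compression impedance
#'   fluctuation (ohms).
#' @param harmonic_weights Relative amplitudes of the 2nd and 3rd harmonics of
#'   the compression fluctuation.
#' @param ventilation_rate_pm,ventilation_amp_ohm Ventilation artifact:
#'   sinusoid rate (per minute) and amplitude (ohms).
#' @param drift_amp_ohm,drift_freq_hz Residual baseline wander: amplitude and
#'   frequency of a slow sinusoid.
#' @param noise_sd_ohm SD of additive white Gaussian noise (ohms).
#' @param series_range_s,pause_range_s Ranges (seconds) from which raw series
#'   and pause durations are drawn uniformly before being rescaled to hit
#'   `ccf_target`.
#' @param fs Sampling frequency of the generated signal (Hz).
#' @param seed RNG seed; identical scenarios generate bit-identical episodes.
#' @param rate_bounds Admissible range for `rate_cpm_mean`.
#'
#' @return An object of class `episode_scenario` (a named list).
#' @examples
#' episode_scenario(duration_s = 60, rate_cpm_mean = 110, seed = 7)
#' @export
episode_scenario <- function(duration_s = 120,
                             rate_cpm_mean = 173,
                             rate_cpm_jitter_sd = 5,
                             ccf_target = 0.68,
                             fluctuation_amp_ohm = 1.0,
                             harmonic_weights = c(0.4, 0.2),
                             ventilation_rate_pm = 8,
                             ventilation_amp_ohm = 0.2,
                             drift_amp_ohm = 0.1,
                             drift_freq_hz = 0.05,
                             noise_sd_ohm = 0.1,
                             series_range_s = c(15, 60),
                             pause_range_s = c(3, 20),
                             fs = 250,
                             seed = 1L,
                             rate_bounds = c(40, 320)) {
  scn <- list(
    duration_s = as.numeric(duration_s),
    rate_cpm_mean = as.numeric(rate_cpm_mean),
    rate_cpm_jitter_sd = as.numeric(rate_cpm_jitter_sd),
    ccf_target = as.numeric(ccf_target),
    fluctuation_amp_ohm = as.numeric(fluctuation_amp_ohm),
    harmonic_weights = as.numeric(harmonic_weights),
    ventilation_rate_pm = as.numeric(ventilation_rate_pm),
    ventilation_amp_ohm = as.numeric(ventilation_amp_ohm),
    drift_amp_ohm = as.numeric(drift_amp_ohm),
    drift_freq_hz = as.numeric(drift_freq_hz),
    noise_sd_ohm = as.numeric(noise_sd_ohm),
    series_range_s = as.numeric(series_range_s),
    pause_range_s = as.numeric(pause_range_s),
    fs = as.numeric(fs),
    seed = as.integer(seed),
    rate_bounds = as.numeric(rate_bounds)
  )
  if (scn$duration_s <= 0) {
    abort("`duration_s` must be positive.", class = "ccrate_scenario_error")
  }
  if (scn$ccf_target < 0 || scn$ccf_target > 1) {
    abort("`ccf_target` must lie in [0, 1].", class = "ccrate_scenario_error")
  }
  if (scn$rate_cpm_mean < scn$rate_bounds[1] ||
      scn$rate_cpm_mean > scn$rate_bounds[2]) {
    abort(sprintf("`rate_cpm_mean` must lie in [%g, %g] cpm.",
                  scn$rate_bounds[1], scn$rate_bounds[2]),
          class = "ccrate_scenario_error")
  }
  amps <- c(scn$fluctuation_amp_ohm, scn$ventilation_amp_ohm,
            scn$drift_amp_ohm, scn$noise_sd_ohm)
  if (any(amps < 0)) {
    abort("Amplitudes and noise SD must be non-negative.",
          class = "ccrate_scenario_error")
  }
  if (scn$ccf_target > 0 &&
      scn$ccf_target * scn$duration_s < 60 / scn$rate_cpm_mean) {
    abort("Infeasible scenario: total compression time (ccf_target * duration_s) is shorter than one compression period.",
          class = "ccrate_scenario_error")
  }
  class(scn) <- "episode_scenario"
  scn
}

#' @export
print.episode_scenario <- function(x, ...) {
  cat(sprintf("<episode_scenario> %.6g s, %.4g cpm (jitter sd %.3g), CCF %.2f, seed %d\n",
              x$duration_s, x$rate_cpm_mean, x$rate_cpm_jitter_sd,
              x$ccf_target, x$seed))
  cat(sprintf("  amplitude %.3g ohm, harmonics (%s), vent %.3g ohm @ %.3g/min, drift %.3g ohm @ %.3g Hz, noise sd %.3g ohm\n",
              x$fluctuation_amp_ohm, paste(x$harmonic_weights, collapse = ", "),
              x$ventilation_amp_ohm, x$ventilation_rate_pm,
              x$drift_amp_ohm, x$drift_freq_hz, x$noise_sd_ohm))
  invisible(x)
}

# Run code with a private RNG stream, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Alternating series/pause skeleton rescaled so compression time equals
# ccf * duration exactly (before clipping at the episode end).
draw_structure <- function(scn) {
  dur <- scn$duration_s
  if (scn$ccf_target >= 1) {
    return(tibble(start_s = 0, end_s = dur))
  }
  if (scn$ccf_target <= 0) {
    return(tibble(start_s = numeric(), end_s = numeric()))
  }
  s <- numeric(); p <- numeric(); tot <- 0
  while (tot < dur) {
    s <- c(s, runif(1, scn$series_range_s[1], scn$series_range_s[2]))
    p <- c(p, runif(1, scn$pause_range_s[1], scn$pause_range_s[2]))
    tot <- sum(s) + sum(p)
  }
  s <- s * (scn$ccf_target * dur) / sum(s)
  p <- p * ((1 - scn$ccf_target) * dur) / sum(p)
  start <- cumsum(c(0, head(s + p, -1)))
  out <- tibble(start_s = start, end_s = pmin(start + s, dur))
  out[out$end_s - out$start_s > 1e-9 & out$start_s < dur, ]
}

#' Generate a synthetic impedance episode with ground truth
#'
#' Builds the compression component as a cosine of a piecewise-linear phase
#' that passes one full cycle between consecutive compression instants, so
#' every annotated instant sits exactly on a crest of the noiseless waveform.
#' Second and third harmonics of the local inter-compression period are added
#' with the scenario's `harmonic_weights`, and each series begins and ends
#' with a half-period raised-cosine amplitude ramp (compressions build up and
#' die out smoothly rather than switching on). Ventilation, drift and white
#' noise are superimposed on the whole episode.
#'
#' @param scenario An [episode_scenario()].
#' @return A list with components `signal` (a [impedance_signal()] at the
#'   scenario's sampling rate) and `annotation` (a [episode_annotation()]
#'   with the series intervals and compression instants actually realized).
#' @examples
#' ep <- generate_episode(episode_scenario(duration_s = 30, seed = 3))
#' ep$annotation
#' @export
generate_episode <- function(scenario) {
  stopifnot(inherits(scenario, "episode_scenario"))
  with_seed(scenario$seed, {
    fs <- scenario$fs
    dur <- scenario$duration_s
    m <- round(dur * fs)
    tt <- (0:(m - 1)) / fs
    series <- draw_structure(scenario)
    x <- numeric(m)
    instants <- numeric()
    period <- 60 / scenario$rate_cpm_mean
    jitter_sd <- scenario$rate_cpm_jitter_sd * 60 / scenario$rate_cpm_mean^2
    h2 <- scenario$harmonic_weights[1]
    h3 <- if (length(scenario$harmonic_weights) > 1) scenario$harmonic_weights[2] else 0
    norm <- 1 + h2 + h3
    keep <- logical(nrow(series))
    for (si in seq_len(nrow(series))) {
      b1 <- series$start_s[si]; b2 <- series$end_s[si]
      ins <- numeric(); t <- b1 + period / 2
      while (t <= b2 - period / 2 + 1e-9) {
        ins <- c(ins, t)
        dt <- period + rnorm(1, 0, jitter_sd)
        dt <- min(max(dt, 0.8 * period), 1.2 * period)
        t <- t + dt
      }
      if (!length(ins)) next
      keep[si] <- TRUE
      instants <- c(instants, ins)
      active_end <- min(ins[length(ins)] + period / 2, b2)
      nodes <- c(b1, ins, active_end)
      phase_nodes <- c(-pi, 2 * pi * (seq_along(ins) - 1),
                       2 * pi * (length(ins) - 1) + pi)
      idx <- which(tt >= b1 & tt < active_end)
      if (!length(idx)) next
      th <- approx(nodes, phase_nodes, xout = tt[idx], rule = 2)$y
      wave <- (cos(th) + h2 * cos(2 * th) + h3 * cos(3 * th)) / norm
      ramp <- period / 2
      u1 <- (tt[idx] - b1) / ramp
      u2 <- (active_end - tt[idx]) / ramp
      env <- ifelse(u1 < 1, (1 - cos(pi * pmax(u1, 0))) / 2, 1) *
             ifelse(u2 < 1, (1 - cos(pi * pmax(u2, 0))) / 2, 1)
      x[idx] <- x[idx] + scenario$fluctuation_amp_ohm * env * wave
    }
    series <- series[keep, ]
    if (scenario$ccf_target > 0 && length(instants) == 0) {
      abort("Infeasible scenario: no series could hold a compression instant.",
            class = "ccrate_scenario_error")
    }
    x <- x +
      scenario$ventilation_amp_ohm *
        sin(2 * pi * (scenario$ventilation_rate_pm / 60) * tt + runif(1, 0, 2 * pi)) +
      scenario$drift_amp_ohm *
        sin(2 * pi * scenario$drift_freq_hz * tt + runif(1, 0, 2 * pi)) +
      rnorm(m, 0, scenario$noise_sd_ohm)
    list(
      signal = impedance_signal(x, fs = fs),
      annotation = episode_annotation(series, instances_s = instants)
    )
  })
}

#' Generate a seeded benchmark collection of episodes
#'
#' Draws per-episode mean compression rates from a truncated normal whose
#' median (173 cpm) and quartiles (about 157--190 cpm) match the distribution
#' observed in field AED recordings, truncated to the detector's design range,
#' and generates one annotated episode per draw. Per-episode seeds are derived
#' deterministically from `master_seed`, so the whole collection is
#' bit-reproducible.
#'
#' @param n_episodes Number of episodes (positive).
#' @param master_seed Integer master seed.
#' @param duration_s Duration of each episode in seconds.
#' @param ccf_target Target chest compression fraction for each episode.
#' @param rate_mean_cpm,rate_sd_cpm Location and spread of the rate
#'   distribution.
#' @param rate_range_cpm Truncation range of the rate distribution.
#' @param ... Further arguments passed to [episode_scenario()] (noise,
#'   ventilation, drift, jitter, ...).
#' @return A tibble with one row per episode: `episode`, `seed`,
#'   `rate_cpm_mean`, and list columns `signal`, `annotation`, `scenario`.
#' @examples
#' bench <- generate_benchmark(3, master_seed = 42, duration_s = 30)
#' bench$rate_cpm_mean
#' @export
generate_benchmark <- function(n_episodes, master_seed = 42L,
                               duration_s = 60,
                               ccf_target = 0.68,
                               rate_mean_cpm = 173,
                               rate_sd_cpm = 24.5,
                               rate_range_cpm = c(60, 250),
                               ...) {
  if (n_episodes < 1) {
    abort("`n_episodes` must be positive.", class = "ccrate_scenario_error")
  }
  rates <- with_seed(master_seed, {
    vapply(seq_len(n_episodes), function(i) {
      repeat {
        r <- rnorm(1, rate_mean_cpm, rate_sd_cpm)
        if (r >= rate_range_cpm[1] && r <= rate_range_cpm[2]) return(r)
      }
    }, numeric(1))
  })
  seeds <- (as.numeric(master_seed) * 7919 + seq_len(n_episodes) * 104729) %%
    2147483647
  eps <- purrr::map(seq_len(n_episodes), function(i) {
    scn <- episode_scenario(duration_s = duration_s,
                            rate_cpm_mean = rates[i],
                            ccf_target = ccf_target,
                            seed = as.integer(seeds[i]), ...)
    c(generate_episode(scn), list(scenario = scn))
  })
  tibble(
    episode = seq_len(n_episodes),
    seed = as.integer(seeds),
    rate_cpm_mean = rates,
    signal = purrr::map(eps, "signal"),
    annotation = purrr::map(eps, "annotation"),
    scenario = purrr::map(eps, "scenario")
  )
}
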