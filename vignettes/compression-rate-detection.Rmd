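---
title: "Detecting chest compressions in the transthoracic impedance: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting chest compressions in the transthoracic impedance: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccrate)
```

## The problem

Automated external defibrillators record the transthoracic impedance (TI)
through their pads. Chest compressions modulate the geometry and blood
distribution of the thorax, so each compression leaves a fluctuation of
roughly sinusoidal shape in the TI, synchronized with the compression. After
the device's high-pass removes the patient's (much larger) baseline
impedance, what remains during compressions is a quasi-periodic signal whose
period is the inter-compression interval, interleaved with pauses in which
the trace carries only noise, ventilation residue, and drift.

`ccrate` turns that observation into a window classifier and rate estimator:
one decision per 2-s window, either a rate in compressions per minute (cpm)
or zero. Two seconds is the shortest window that still contains at least two
compressions at the slowest rate of interest (60 cpm), which is what a
periodicity detector needs.

## Model and detector

Let `x[0..N-1]` be one preprocessed window at `fs = 250` Hz (`N = 500`). The
detector computes the biased autocorrelation estimate

$$r[k] = \frac{1}{N}\sum_{n=0}^{N-1-k} x[n]\,x[n+k], \qquad k = 0 \dots K,$$

implemented with a zero-padded FFT and verified in the test suite against
the direct double-sum definition at relative tolerance $10^{-9}$. Division
by `N` (not `N - k`) keeps `|r[k]| <= r[0]`, so `rho[k] = r[k]/r[0]` is a
bounded, amplitude-free function — the natural object to threshold.

### Why peak search does not run on `rho` directly

The biased estimate carries an `(N-k)/N` taper, and truncating a sinusoid at
the window edges adds a phase-dependent oscillatory term. Both distort the
peak: numerically, the `rho` maximum of a 1-s-period sinusoid in a 2-s
window sits up to 12 lag samples below the true period depending on phase —
a 3 cpm bias at 60 cpm, and `rho` at lag 1.0 s can never exceed 0.5 even for
a perfect periodic signal, which would make a single fixed threshold
meaningless across the rate range. We therefore renormalize each lag by the
energy the two compared segments actually contain,

$$s[k] = \frac{2N\,r[k]}{e_\text{head}[k] + e_\text{tail}[k]},
\qquad e_\text{head}[k] = \sum_{n=0}^{N-1-k} x[n]^2,\quad
e_\text{tail}[k] = \sum_{n=k}^{N-1} x[n]^2,$$

the normalized square-difference score familiar from pitch estimation. For
an exactly periodic window `s` equals 1 at the period for any amplitude and
phase, so the peak position is unbiased, the score is scale-invariant, and a
single threshold works from 60 to 250 cpm. `normalize_autocorrelation()`
returns both `rho` (the classical normalization, kept for inspection and for
its invariants) and `s` (used by the peak search).

### Peak selection rules

`find_rate_peak()` scans the closed lag grid
`ceil(0.24 fs) .. floor(1.0 fs)` (both printed bounds included) and accepts
the **smallest-lag** local maximum of `s` with `s >= threshold`:

* *Smallest lag, not global maximum.* A periodic signal peaks at its period
  and all multiples; the global maximum can land on a multiple and halve
  the reported rate — the clinically dangerous error, since a true 200 cpm
  read as 100 cpm looks compliant. The fundamental is the smallest lag of
  self-similarity.
* *Peak definition.* Strict local maximum (`s[k] > s[k-1]` and
  `s[k] >= s[k+1]`; the first sample of a plateau wins). A lag-range
  boundary sample qualifies only if it exceeds its single interior
  neighbour — necessary so that a period of exactly 0.24 s (250 cpm), whose
  peak sits on the first grid point, is still found.
* *Dip gate.* The score must have taken a negative value at some lag before
  the candidate (`require_dip`). Any zero-mean periodic fluctuation
  anti-correlates near half its period, so genuine compression windows
  always pass. Slow monotone content — a ventilation arc or drift ramp
  seen through a 2-s window — produces a score that decays from 1 without
  ever dipping, yet with noise superimposed it grows spurious
  super-threshold local maxima; the gate removes exactly that failure mode.
  Without it, pause windows containing ventilation residue trigger false
  detections at a high rate; with it they are almost always silent.
* *Sub-sample refinement.* Three-point parabolic interpolation around the
  integer-lag peak (`interpolate`, on by default) reduces the
  lag-quantization rate error (up to ~4 cpm at 250 cpm) to well below 1 cpm
  on clean signals. The threshold decision always uses the integer-lag
  score, so raising the threshold can only remove detections (a monotone
  property the tests check), and the refined lag is clamped to the search
  range so reported rates stay in 60–250 cpm. The switch exists so the
  integer-lag contract remains testable.

The selected lag maps to `rate = 60 / lag`; windows without a qualifying
peak report rate 0. A window with numerically zero energy (`r[0]` below
`1e-30`, e.g. a disconnected pad) is flagged null and treated as a pause
rather than divided through.

### Filtering

The low-pass is a 4th-order Butterworth at 5 Hz applied zero-phase
(forward-backward). Two realization details matter:

* The episode is filtered **once as a whole**, then cut into windows; the
  per-window contract (`preprocess_window()`) is mean removal on already
  filtered content. Filtering each 2-s window separately would put edge
  transients in every window.
* Forward-backward application uses odd-reflection padding with
  steady-state initial conditions. The naive double pass leaves edge
  transients large enough to displace the autocorrelation peak of a
  1-s-period window by one lag sample; with the padded implementation the
  lag-range endpoints map to exactly 60 and 250 cpm, which
  `scripts/acceptance.R` recomputes.

The 5 Hz cutoff passes the fundamental of the fastest detectable rate
(250 cpm ≈ 4.17 Hz) and attenuates harmonics and broadband noise; it is
exposed in `detector_config()`. Mean removal per window is required because
a residual offset inflates `r[0]` and masks the periodicity peak.

### Threshold

The detection threshold (default **0.65**) is a calibrated parameter. It was
fixed once, before freezing the package, by simulation: the upper tail of
the peak-score distribution of filtered-noise windows was compared with the
lowest scores of genuine compression windows across the 60–250 cpm range
(including rate jitter and default noise), and candidate values were swept
on the 50-episode synthetic benchmark. 0.65 sits between the two
populations with the best balanced margin on sensitivity and specificity;
the residual misclassifications are windows genuinely straddling a
series/pause boundary, which no threshold can fix. The value is recorded in
`detector_config()` and can be changed for sensitivity analyses.

## The synthetic episode generator

Real validation data for this problem are proprietary AED recordings, so
the package ships a generator whose defaults emulate the statistical
structure reported for out-of-hospital episodes:

| parameter | default | rationale |
|---|---|---|
| compression rate | 173 cpm mean (benchmark draws N(173, 24.5) truncated to 60–250) | field distributions center near 173 cpm with quartiles ≈ 157–190 |
| rate jitter | 5 cpm SD per interval, truncated ±20% of the period | manual CPR varies by a few cpm between compressions but stays coherent within a window |
| CCF target | 0.68 | observed central chest compression fraction |
| series / pauses | 15–60 s / 3–20 s, rescaled to the CCF target | mimics 30:2 and rhythm-analysis pause structure |
| fluctuation amplitude | 1 ohm, harmonics (0.4, 0.2) | ohm scale is device-dependent; harmonics stress fundamental-vs-multiple peak selection |
| ventilation | 0.2 ohm at 8/min | residual after the device high-pass attenuates the slow ventilation artifact |
| drift | 0.1 ohm at 0.05 Hz | baseline wander residue |
| noise | 0.1 ohm SD white Gaussian | ~20 dB below the compression fluctuation |

The compression component is a cosine of a piecewise-linear phase passing
one cycle between consecutive annotated instants, so every instant lies on
a crest of the noiseless waveform (a tested invariant), with 2nd/3rd
harmonics and half-period raised-cosine amplitude ramps at series
boundaries — compressions build up and die out smoothly, as real traces do;
an earlier sharp-onset variant rang through the low-pass into neighbouring
pause windows. A CCF target of 1 produces a single uninterrupted series.
Everything is driven by one seed and is bit-reproducible; benchmark
episodes derive their seeds deterministically from a master seed.

What the generator does **not** emulate: device-specific noise signatures,
pulse (circulation) artifacts, electrode motion spikes, the interaction of
real ventilation with compressions during continuous CPR, or annotation
noise — real experts disagree at series boundaries, the generator's ground
truth is exact. Passing the synthetic benchmark therefore demonstrates the
algorithm's correctness under the modelled signal structure, not its
clinical field performance.

## Evaluation protocol choices

* **Window labels.** A window counts as a compression window when at least
  50% of it overlaps annotated series (configurable in `label_windows()`).
  The choice is symmetric and parameter-free; windows near boundaries are
  the main source of residual FP/FN either way.
* **Reference rate.** Inverse of the mean spacing of the annotated instants
  inside the window, `60 (n-1) / (t_last - t_first)`, defined only for
  `n >= 2`. True-positive windows with fewer instants count for detection
  metrics but contribute no rate-error sample.
* **Undefined figures of merit.** A zero denominator (e.g. PPV in an
  episode without detections) is reported as `NA` and excluded from
  per-episode averaging — never coerced to 0% or 100%.
* **Confidence intervals.** Normal approximation `mean ± 1.96 sd/sqrt(n)`
  across episodes, matching the symmetric intervals customarily reported
  for per-episode means.
* **Distributions.** Median (IQR) throughout, with type-7
  linear-interpolation quantiles (R's default), so summaries are
  deterministic and reproducible.
* **Out-of-range rates.** Annotated rates above 250 cpm occur in real data;
  the detector cannot report them. Such windows are scored by the plain
  TP/FN definitions (any non-zero output in a compression window is TP) and
  their count is flagged in the report.
* **Excluded intervals.** Annotation masks (shocks, pad disconnections) drop
  the overlapping windows from the grid before any counting.

## Numerical and degenerate-input behaviour

* Autocorrelation via zero-padded FFT; oracle agreement at `1e-9` relative.
* Null-energy windows: floor `1e-30` on `r[0]`; flat episodes yield all-zero
  outputs rather than NaNs.
* Signals shorter than one window produce an empty (not failing) result;
  trailing partial windows are discarded, never padded — a padded window
  would violate the two-compressions-per-window premise.
* Resampling preserves duration to within one output sample, with
  zero-phase anti-alias filtering when downsampling; the identity case is
  exact.
* All randomness (generator, benchmark) flows from explicit seeds through a
  private RNG scope that restores the caller's `.Random.seed`.

## Problem sizes in the test suite

The suite validates the autocorrelation oracle on 1000 random 500-sample
windows, rate recovery at eight noiseless rates over 30-s episodes, the
noisy benchmark on 50 episodes of 60 s (CCF 0.68, default noise) with
sensitivity, specificity, PPV and NPV all required to reach 95%, a
per-episode median rate error within 2 cpm and a median CCF error within 5
points, plus null-input, scale-invariance and oracle-closure properties.
These sizes keep the full suite under a minute on one CPU while leaving the
statistical checks well-powered; all thresholds are design targets of this
package, informed by — but not claims about — performance on clinical
recordings.

## Known limitations

* The 2-s cadence bounds the latency of any feedback built on top; the
  package makes no real-time guarantees.
* Rates outside 60–250 cpm are reported as either silence or an in-range
  rate (typically a sub-multiple); the range is a design decision inherited
  from the feedback use case.
* Windows straddling series boundaries are intrinsically ambiguous under
  any binary label; expect a percent-level floor on FP/FN from them.
* The detector assumes the device has already removed the baseline
  impedance; a raw TI trace with its multi-ohm baseline must be high-pass
  filtered before use.
* ECG is deliberately out of scope: the algorithm uses the impedance
  channel only.
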