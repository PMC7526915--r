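# ccrate

Chest compression detection and rate estimation from the transthoracic
impedance (TI) signal of automated external defibrillators (AEDs).

During cardiopulmonary resuscitation, each chest compression superimposes a
quasi-periodic fluctuation on the impedance measured through the
defibrillation pads. `ccrate` exploits that periodicity to tell, every 2
seconds, whether compressions are being delivered and at what rate — the
information a basic-life-support AED needs to coach a rescuer toward the
guideline rate band (100–120 cpm) and to quantify no-flow time afterwards.
The package is aimed at researchers working on CPR quality monitoring who
need a transparent, fully testable reference implementation together with a
simulation and evaluation harness.

## The algorithm

The TI trace (ohms, baseline-suppressed by the device's high-pass, resampled
to 250 Hz) is processed in consecutive non-overlapping 2-s analysis windows.
For each window the detector:

1. low-pass filters the signal (zero-phase Butterworth, 5 Hz) to enhance the
   fundamental component of the compression fluctuation, and removes the
   window mean;
2. computes the **biased autocorrelation estimate**

   $$r[k] = \frac{1}{N}\sum_{n=0}^{N-1-k} x[n]\,x[n+k],$$

   which guarantees $|r[k]| \le r[0]$;
3. normalizes it into a periodicity score that corrects the estimate's
   $(N-k)/N$ taper by the energy of the two overlapping segments,
   $s[k] = 2N\,r[k] / (e_\text{head}[k] + e_\text{tail}[k])$, so a perfectly
   periodic window scores 1 at its period regardless of amplitude or phase;
4. searches the closed lag range **0.24–1.0 s** for the smallest-lag local
   maximum with score ≥ 0.65 whose score has dipped below zero at a shorter
   lag (which rejects slow ventilation/drift artifacts);
5. reports the rate `60 / lag` in cpm — between 250 and 60 cpm by
   construction — or **0** when no qualifying peak exists (compression
   pause).

Around the detector the package provides a seeded generator of synthetic
resuscitation episodes with ground-truth annotations (compression series,
individual compression instants, ventilation, drift, noise), and the
window-level evaluation protocol: TP/TN/FP/FN counts, sensitivity, positive
predictive value, specificity and negative predictive value (globally and
per episode with 95% CIs), compression-rate error, and chest compression
fraction (CCF) error.

## Worked example

```r
library(ccrate)

scn <- episode_scenario(duration_s = 120, rate_cpm_mean = 110,
                        ccf_target = 0.8, seed = 42)
ep  <- generate_episode(scn)

res <- detect_compressions(ep$signal)
head(res, 5)
#> # A tibble: 5 × 7
#>   window_index start_s end_s detected rate_cpm peak_lag_s peak_score
#>          <int>   <dbl> <dbl> <lgl>       <dbl>      <dbl>      <dbl>
#> 1            0       0     2 TRUE         108.      0.557      0.969
#> 2            1       2     4 TRUE         107.      0.563      0.971
#> 3            2       4     6 TRUE         105.      0.573      0.954
#> 4            3       6     8 TRUE         111.      0.539      0.977
#> 5            4       8    10 TRUE         119.      0.504      0.928
```

Each row is one 2-s window: `detected` says whether compression activity was
found, `rate_cpm` is the estimated compression rate (0 in pauses),
`peak_lag_s` the selected autocorrelation lag (the mean time between
compressions) and `peak_score` the normalized peak height the 0.65 threshold
was applied to. The estimates hover around the scenario's 110 cpm, moving
with the simulated rate jitter.

Scoring the detector against the episode's ground truth:

```r
refs <- label_windows(ep$annotation, res)
rep  <- evaluate_corpus(tibble::tibble(episode = 1, results = list(res),
                                       references = list(refs)))
rep
#> <cc_evaluation> 1 episodes, 60 windows
#>   global: Se 97.9%  PPV 100.0%  Sp 100.0%  NPV 92.3%
#>   rate error (per-episode median |err|): 0.3 (0.3-0.3) cpm
#>   CCF error: 1.7 (1.7-1.7) %
```

Of the 48 windows with annotated compressions, 47 were detected (one
boundary window straddling a pause was missed, hence Se 97.9% and NPV
92.3%); no pause window produced a false alarm. The median unsigned rate
error is 0.3 cpm and the CCF estimate is within 1.7 percentage points of the
annotated fraction. `tidy(rep)` and `glance(rep)` expose the same numbers as
tibbles, and `autoplot(rep)` / `plot_detections(res, refs)` draw them.

A multi-episode benchmark in one call:

```r
bench <- generate_benchmark(50, master_seed = 42, duration_s = 60)
```

## Command line

A thin wrapper around the same functions is installed with the package:

```sh
CCRATE=$(Rscript -e 'cat(system.file("cli", "ccrate", package = "ccrate"))')
$CCRATE simulate  --duration 60 --rate 115 --seed 5 --out-signal ep.csv --out-annotation ep.json
$CCRATE detect    --input ep.csv --output results.csv
$CCRATE evaluate  --results results.csv --annotation ep.json --out report.json
$CCRATE report    --report report.json
$CCRATE benchmark --n 50 --seed 42 --duration 60 --outdir bench/
```

Signals travel as two-column CSV (`time_s,impedance_ohm`), annotations as
JSON (`series` intervals, `instances_s`, optional `excluded` masks); every
run writes a manifest recording command, configuration, seeds and package
version.

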