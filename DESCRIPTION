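Package: ccrate
Title: Chest Compression Detection and Rate Estimation from Transthoracic Impedance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects chest compression activity and estimates compression rate
    from the transthoracic impedance (TI) signal recorded by automated external
    defibrillators during cardiopulmonary resuscitation. The detector computes a
    biased estimate of the autocorrelation of the low-pass filtered TI signal in
    consecutive non-overlapping 2-second windows and locates a periodicity peak
    in the lag range corresponding to 60-250 compressions per minute, reporting
    a rate for each window or zero during pauses. Includes a seeded generator of
    synthetic resuscitation episodes with ground-truth annotations, a full
    window-level evaluation protocol (sensitivity, positive predictive value,
    specificity, negative predictive value, compression-rate error, and chest
    compression fraction error), plotting helpers, and a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
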