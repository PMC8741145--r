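Package: tovaosc
Title: Event-Related Oscillatory EEG Analysis for the TOVA Continuous
    Performance Test
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for event-related EEG analysis of the Test of Variables
    of Attention (TOVA), a Go/NoGo continuous performance test. Provides a
    synthetic TOVA-EEG generator with known oscillatory ground truth (1/f
    noise, ongoing alpha with stimulus-locked phase resetting, evoked
    N2/P3-like transients, theta power modulations), balanced epoch
    extraction with blink and amplitude artifact rejection, RT- and
    phase-sorted ERP images, windowed amplitude group tests, Welch power
    spectral density, per-electrode Morlet time-frequency decomposition
    averaged within regions of interest to yield total (ERSP), evoked and
    induced power, intertrial coherence with permutation significance,
    permutation contrasts of log spectral power, and TOVA behavioral
    scoring with norm-referenced standard scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
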