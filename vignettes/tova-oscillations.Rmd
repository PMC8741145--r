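---
title: "Oscillatory EEG analysis of the TOVA continuous performance test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory EEG analysis of the TOVA continuous performance test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tovaosc)
```

## The problem this package addresses

The Test of Variables of Attention (TOVA) is a Go/NoGo continuous
performance test: a participant presses a button for target stimuli and
withholds responses to nontargets, over two consecutive halves that differ
only in target frequency — H1 presents 72 targets among 252 nontargets,
H2 reverses the counts. Stimuli appear for 100 ms on a strictly periodic
2 s onset-to-onset schedule, so each 324-trial half lasts 10.8 minutes and
the stimulus train itself has a 0.5 Hz periodicity with a 10 Hz
presentation-duration structure.

Because stimulus timing is perfectly predictable, the test is a natural
probe of *temporal attention*: how strongly ongoing cortical rhythms
(notably parietal ~10 Hz alpha and 4–8 Hz theta) entrain to, and are
phase-reset by, each stimulus. `tovaosc` implements the full analysis
chain for this question — behavioral scoring, epoching with artifact
rejection and balanced subsampling, ERP images, Morlet time–frequency
decomposition into total (ERSP), evoked and induced power, intertrial
coherence (ITC), and permutation statistics — together with a synthetic
EEG generator whose ground truth makes every estimator testable without
access to any clinical recordings.

## The synthetic generator

`synthesize_eeg()` composes, per channel and in microvolts:

1. **1/f background noise** — white noise spectrally shaped to
   `1/f^noise_exponent` (default exponent 1), rescaled to
   `noise_scale_uv` RMS (default 3 µV). Each channel draws independent
   noise; mastoids carry attenuated noise and no signal, so mastoid
   re-referencing behaves realistically.
2. **Ongoing alpha with stimulus-locked phase resetting** — a 10 Hz
   oscillation whose phase performs a random walk
   (`phase_jitter` = 0.04 rad/sample, setting the linewidth and the decay
   of post-reset coherence). At each stimulus onset plus
   `reset_latency_s`, the phase is pulled toward a fixed target phase by
   the fraction `phase_reset_strength` ∈ [0, 1] of the circular distance.
   This deterministic fractional pull was chosen over drawing from a von
   Mises distribution because it has a closed-form calibration: for
   initially uniform phases the post-reset dispersion is
   (1 − s)·U(−π, π], so the coherence contributed by the reset is
   sin((1 − s)π)/((1 − s)π) — exactly 1 at s = 1, chance level at s = 0,
   and strictly monotone in between. The ITC acceptance tests exploit all
   three anchors.
3. **Evoked components** — Gaussian-windowed half-sine deflections at each
   stimulus onset (defaults: an N2-like negativity at 200 ms and a
   P3-like positivity at 380 ms), the phase-locked part of the signal.
4. **Theta amplitude modulations** — an 8 Hz oscillation elevated inside
   a prestimulus window (−600 to −100 ms) and a 4 Hz oscillation elevated
   poststimulus (0 to 700 ms), each with an independent random phase per
   trial, i.e. *induced* (non-phase-locked) activity. Base and window
   amplitudes are separate parameters, so a doubling (amplitude ×2 = +6.02
   dB in power) can be injected as spectral ground truth.
5. **Blink artifacts** — raised-cosine deflections on VEOG with
   attenuated frontal spread, at a configurable rate; blink times are
   returned as ground-truth annotations (probabilistic blink *detection*
   is out of scope; a simple VEOG threshold detector is provided as a
   convenience only).

`group_preset("control")` and `group_preset("adhd")` encode the
qualitative contrast under study: controls get stronger/earlier phase
resetting, larger evoked components and stronger theta modulations; the
ADHD preset gets weaker/later resetting, smaller evoked amplitudes,
weaker theta and elevated prestimulus alpha.

What the generator does **not** emulate: volume-conducted scalp
topography (channel gains are flat within a component), non-stationary
artifact families (muscle, drift, electrode pops), heavy-tailed RT
contaminants, or between-participant spectral variability beyond the
preset parameters. Tests passing on this generator therefore validate
*estimator correctness and calibration*, not robustness to every property
of real recordings.

## Protocol constants and preprocessing

The trial period is 2000 ms onset-to-onset with the 100 ms stimulus
contained in it — the only reading consistent with a 10.8 min half of 324
trials. Sampling is fixed at 512 Hz.

Preprocessing follows the standard chain: mastoid-average re-referencing;
a zero-phase windowed-sinc (Hamming) FIR band-pass of 2–45 Hz with a 1 Hz
transition band (the symmetric FIR is applied once and its group delay
removed, which is exactly zero-phase and cheaper than forward–backward
filtering); epochs of [−1.0, +1.0) s around stimulus onset (half-open, so
the t = 0 sample is poststimulus and a 512 Hz epoch has exactly 1024
samples); blink rejection over a −400/+600 ms guard window; amplitude
rejection of epochs exceeding ±80 µV on strictly more than 50% of EEG
channels; and baseline subtraction over (−1, 0) s, or (−1.0, −0.9) s for
analyses of prestimulus phase.

Trials are classified as correct responses, correct inhibitions,
commissions, omissions, or invalid (responses faster than the 150 ms
anticipatory cutoff, which belong to no class). Balanced analysis sets
draw exactly 36 epochs for infrequent cells (responses in H1, inhibitions
in H2) and 72 for frequent cells, per participant and without
replacement; a participant failing a quota is excluded for that cell, and
one retained in both cells of a half contributes 108 epochs.
`sampling_stability()` repeats the draw (11 times by default) and reports
the across-draw variance of a spectral statistic; note that this variance
is zero when the pool equals the quota and *grows* with pool size toward
the usual sampling variance S²/n — the finite-population correction
(1 − n/N) makes draws from a barely-sufficient pool nearly identical.

Early/late splits divide each cell at the median onset time, the extra
trial going to "early" when the count is odd.

## ERP images and windowed tests

An ERP image sorts single-trial ROI waveforms by a covariate (RT or
prestimulus phase) and smooths across trials with a moving Gaussian whose
SD is n/30 trials, truncated at a window of n/5. The smoothing matrix is
Sinkhorn-balanced to be symmetric doubly stochastic: rows summing to one
means identical trials are left untouched, and columns summing to one
means the column means of the image equal the grand ERP exactly — both
properties are asserted to numerical precision in the tests. Plain
row-renormalization at the edges satisfies only the first property.

Phase sorting estimates, per trial, the alpha-band (8–12 Hz) frequency of
maximum power at −80 ms with a 3-cycle Morlet wavelet, discards the 5% of
trials with lowest peak power, and sorts the remainder by phase ascending
from −π (ties by trial index). On generator output with known phases the
recovered order matches ground truth with circular correlation above
0.95.

Group differences in ERP amplitude are tested per time window (N2- and
P3-centred: 150–250 and 330–430 ms target-locked; −170 to −70 and 0–100
ms response-locked) with a two-sample Kolmogorov–Smirnov test on
trial-level window means, Benjamini–Hochberg corrected across windows at
α = 0.05. Trial-level pooling within group is the default observation
unit; per-participant means can be passed instead, since the appropriate
unit is a genuine modelling choice. Note the two-sample KS test is
intrinsically conservative (its statistic is discrete): its realized
type-I error at nominal α = 0.05 is about 0.03–0.04, which the
calibration tests assert as one-sided level control rather than two-sided
equality with 0.05.

## Spectral decomposition

The analysis grid spans 4–30 Hz in 54 log-spaced frequencies. Wavelet
cycles scale linearly in frequency from 3 at 4 Hz to
3 × (30/4) × 0.5 = 11.25 at 30 Hz, trading temporal for spectral
resolution; wavelet support is round(cycles · fs / f) samples. The
wavelets are unit-energy complex exponentials under a Gaussian taper with
SD_t = cycles/(2πf), truncated at ±π·SD (edge amplitude < 1%). Time
centres are 200 points spanning the valid (edge-free) region defined by
the largest wavelet — about ±0.62 s within a ±1 s epoch.

Per-trial, per-electrode power is computed by FFT convolution and
averaged **across electrodes per trial**; averaging power rather than
signals preserves activity whose phase differs between electrodes,
whereas the TFR of the channel average can cancel it entirely (the
two-electrode antiphase case is an exact test).

Three quantities are derived, all expressed in dB against the mean
prestimulus baseline power per frequency (10·log10(P/P_baseline),
divisive baseline):

* **Total power (ERSP)** — the across-trial mean of per-trial TFR power;
* **Evoked power** — the TFR of the across-trial time-domain average;
* **Induced power** — per-trial TFRs after subtracting the grand ERP from
  each epoch in the time domain, then averaged.

These satisfy sharp identities used as tests: with identical noise-free
trials, evoked equals total and induced vanishes; with random-phase
oscillations, evoked/total shrinks like 1/n and induced approaches total
(within 0.5 dB at n = 1000). The three-way decomposition closes only
approximately in general, and the tests report the discrepancy rather
than assume it away.

One numerical caveat matters for recovery experiments: a 3-cycle 4 Hz
wavelet is 0.75 s long, so poststimulus power bleeds into baseline
estimates taken right up to t = 0. Ground-truth recovery therefore
measures against a baseline window ending 200 ms before onset
(−0.6 to −0.2 s); with that convention an injected 2× amplitude step at
4 Hz is recovered within 1 dB of +6.02 dB at 100 trials through the full
pipeline (synthesis → epoching → baseline → ROI TFR → ERSP).

Welch PSDs use the 512-sample (1 s) Hann window with 384-sample overlap
and one-sided density scaling, averaged over trials and channels, with
1 Hz bins over 4–16 Hz; a 1024-sample segment yields exactly 5 averaged
periodograms, and band-integrated power of a unit sinusoid reproduces
A²/2 within 5% (Parseval check). Segments shorter than the window — the
500 ms prestimulus alpha analysis — clip the window to the segment with
75% overlap.

## Intertrial coherence and permutation inference

ITC at frequency f is |mean over trials of unit phase vectors|, computed
per channel and then channel-averaged, evaluated at 10 Hz with the cycle
rule of the main grid. Its calibration anchors: exactly 1 for perfect
locking, 0 for equally spaced phases, and a chance level of
√π/(2√n) ≈ 0.089 at n = 100 uniform phases (the Rayleigh mean), all
asserted by tests. Significance uses a surrogate null built by circularly
time-shifting each trial's phase series (the same shift across channels
within a trial); ITC is significant where it exceeds the per-latency
(1 − α) null quantile.

Group ERSP contrasts use label-permutation tests on the difference of log
mean power per (frequency, time) tile, uncorrected across tiles. Masks
come from two-sided permutation p-values on the absolute null with
add-one correction, p = (1 + #{|null| ≥ |obs|})/(n_perm + 1) — for the
symmetric label-permutation null this is equivalent to the
confidence-interval formulation, calibrates exactly at finite n_perm
(realized false-positive fraction 10/201 ≈ 0.0497 at α = 0.05 with 200
permutations), and makes the strict α = 0.0005 level attainable with 2000
permutations. Both levels are evaluated against one shared null, so the
strict mask is nested in the loose one by construction. The pooled trials
are canonically ordered before permuting, which makes the procedure
exactly symmetric: swapping the group labels negates the observed
difference and preserves the masks bit for bit. Permutation is at the
trial level by default (pooling trials within group); participant-level
permutation can be had by passing per-participant mean power arrays.

## Behavioral scoring

Five measures per test half: mean correct-response RT (ms), RT
variability (SD of correct RTs — the literal "SD of the mean RT" is
degenerate), commission and omission counts, and d′. d′ defaults to
z(hit rate) − z(false-alarm rate) with the log-linear correction
(+0.5/+1) so perfect rates stay finite; a literal hit/false-alarm ratio
is exposed as an alternative mode because the field's shorthand is
ambiguous, without claiming either is the proprietary scoring rule.

Standard scores are 100 + 15·z against a normative cell (age band ×
gender), signed so that *lower always means worse*: RT, RTV and error
counts enter negatively, d′ positively. The normative table shipping with
the package is synthetic (plausible adult values; see
`synthetic_norm_table()`) — it exercises the machinery and carries no
normative authority; `estimate_norms()` builds tables from simulated
cohorts instead. Performance labels ("normal" ≥ 90 ≤ "borderline" < 90,
"not within normal limits" < 80, on the worst score, half-open intervals)
are documented surrogates, not vendor rules.

## Pipeline, problem sizes and determinism

`run_pipeline()` chains everything for a two-group synthetic study and
writes deterministic TSV/JSON artifacts; every stage seed derives from
one master seed, and no artifact contains timestamps, so identical calls
are byte-identical (asserted by test). The default configuration — 3
participants per group, full 324-trial halves, a reduced 27 × 100 TFR
grid, 400 permutations — was chosen to make a complete demonstration run
finish in a few minutes on one core; the full 54 × 200 grid and
2000-permutation contrasts are a configuration change, not a code path
change. The test suite itself runs on deliberately small problem sizes
(tens of trials, reduced grids) with the two large-n calibration checks
(1000-trial decomposition limit, 500-simulation permutation calibration)
kept because they pin down asymptotic behavior.

Continuous recordings are serialized as plain-text TSV matrices with
key=value parameter sidecars, and epoch/TFR/ITC/PSD results as TSV with
header metadata. Binary EEG interchange formats and an HDF5 epoch
container were considered and dropped: no suitable reader/writer package
is available to this package's dependency set, and the text formats
round-trip losslessly at the scales the package targets.

## Known limitations

* The generator's spatial model is deliberately crude (flat gains, no
  forward model); scalp-map analyses are out of scope.
* Wavelet-based recoveries near the epoch edges and within half a wavelet
  of stimulus onset are biased by design (smearing); analyses should use
  the valid region and onset-clear baselines as described above.
* The decomposition total ≈ evoked + induced is approximate for mixed
  signals; the package reports all three rather than enforcing closure.
* Inferential batteries beyond permutation/KS/FDR (mixed ANOVA, Bayesian
  or robust LMMs) are intentionally not re-implemented; the pipeline
  exports tidy tables for external statistical software.
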