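---
title: "Methods: gamma-band EEG power and coherence across behavioral states"
author: "gammacoh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gamma-band EEG power and coherence across behavioral states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammacoh)
```

## The scientific problem

Low-gamma (30-45 Hz) EEG oscillations in carnivore cortex appear as
discrete "bursts" of roughly 200-500 ms and ~25 uV that are strongly
synchronized between distant cortical sites during alert wakefulness,
partially synchronized in quiet wakefulness and NREM sleep, and almost
uncoupled during REM sleep. Sub-anesthetic NMDA-antagonist doses of
ketamine reproduce the REM-like decoupling while leaving gamma *power* at
waking levels -- a functional-disconnection signature of interest as a
pharmacological model of psychosis. Quantifying this requires a chain of
standard but easy-to-misconfigure steps: scored-state window selection,
Welch-block magnitude-squared coherence (MSC), a variance-stabilizing
transform, band summaries, surrogate controls, and repeated-measures
statistics. `gammacoh` packages that chain end to end, together with a
synthetic multichannel EEG generator whose cross-channel coupling is known
exactly, so every stage can be validated against ground truth without
animal recordings.

## The coherence estimator

For each analysis window the two channels are cut into Hann-windowed
blocks of `nfft = 2048` samples. At the canonical sampling rate of
1,024 Hz this gives a frequency resolution of exactly 0.5 Hz, and a 100-s
window with 50% block overlap yields 99 blocks -- the "~100 time-blocks"
configuration. With block spectra $X_b(f)$, $Y_b(f)$,

$$\mathrm{MSC}(f) \;=\;
\frac{\left|\langle X_b(f) Y_b^*(f)\rangle_b\right|^2}
     {\langle |X_b(f)|^2\rangle_b \,\langle |Y_b(f)|^2\rangle_b}
\in [0, 1].$$

The block overlap convention is an interpretation: 100 s of data at a bin
size of 2,048 samples gives 50 non-overlapping blocks, so the historical
"100 time-blocks" description is reconciled by 50% overlap (99 blocks).
Overlap is a parameter; the surrogate stage (below) deliberately uses
non-overlapping blocks.

Coherence magnitudes are variance-stabilized before averaging or testing:

$$z' = \operatorname{atanh}\!\left(\sqrt{\mathrm{MSC}}\right),$$

the Fisher transform of the coherence magnitude. This convention is not
uniquely determined by the published tables; it is the standard choice and
produces the familiar 0-1.2 working range. `zTransform(..., method =
"atanh")` provides the alternative convention. Values at MSC = 1 are
clipped to $1 - 10^{-12}$ with a warning.

Band summaries come in two deliberately distinct flavors:

* `bandMeanZ()` -- the plain mean of $z'(\mathrm{MSC}(f))$ over the grid
  frequencies in the band (inclusive edges; 31 points for 30-45 Hz at
  0.5 Hz). This is the statistic tabulated per window and fed to the
  ANOVAs.
* `bandMsc()` -- the pooled band MSC
  $|\sum_f S_{xy}|^2 / (\sum_f S_{xx} \sum_f S_{yy})$. Pooling before the
  ratio makes the estimate comparable with the lumped-power closed form of
  the synthetic model even when shared and independent components have
  different spectral shapes (a plain mean over the band would be diluted
  by frequencies that carry no power).

Two estimator facts matter when reading small coherences: the MSC
estimator has a positive bias of about $1/L$ for $L$ independent blocks
(so an uncoupled pair at $L = 99$ reads MSC $\approx 0.01$, $z' \approx
0.1$, not zero), and overlapping blocks inflate that floor by a further
~10% because adjacent blocks are correlated. Tests that check the bias law
therefore use non-overlapping blocks, where $1/L$ is exact to first
order.

## The synthetic generator and its closed-form oracle

Each state is generated as

* **background**: band-limited Gaussian components, `data.frame(lo, hi,
  power)` with the stated total power (uV^2) spread uniformly over each
  band, synthesized directly in the frequency domain. The default ladder
  (120/60/40/10/5/5 uV^2 from delta to high gamma) emulates the 1/f-like
  EEG spectrum. Slow waves (NREM, ketamine) and the ketamine beta peak are
  additional bands; the ketamine high-gamma elevation is a gain on the
  45-60 Hz component.
* **bursts**: Poisson streams of Hann-enveloped sinusoids, carrier drawn
  uniformly in 35-40 Hz (the center of the analysis band), duration
  uniform in 200-500 ms, peak amplitude ~18-25 uV with 15% per-burst
  scatter. A fraction `couplingFraction` of the stream is a *shared*
  source copied to every channel; the rest is independent per channel.

With shared in-band power $S$ and independent in-band power $N$ per
channel, the expected band MSC of the pair is

$$\mathrm{MSC} = \frac{S^2}{(S+N)^2},$$

computed by `expectedBandMsc()` from the burst rate, mean duration, Hann
envelope power factor ($3/8 \cdot 1/2$), amplitude (and scatter), coupling
fraction and the in-band background. It is exact at zero jitter and an
upper bound otherwise, and it is the oracle every coherence-recovery test
compares against.

**Jitter semantics.** Perfectly aligned copies would make coherence
trivially 1, so shared bursts receive independent per-channel timing
jitter (uniform, +-10 ms by default). The jitter displaces the burst
*envelope* while the carrier stays phase-locked to the shared source --
physiologically, gamma bursts phase-synchronize across cortices while
their envelopes arrive with small latency scatter. This choice is
load-bearing: shifting the whole waveform by +-10 ms would randomize a
~37 Hz carrier phase by +-133 degrees and multiply the pair's MSC by
~0.008, making coupling unrecoverable at any realistic analysis scale.
`jitterCarrier = TRUE` selects the literal whole-waveform shift for
sensitivity studies.

**Preset parameters.** Burst rates per state are not published anywhere;
they are free parameters fixed once to reproduce the qualitative
contrasts: denser, larger bursts in alert wakefulness; sparse small
bursts in NREM; QW/REM/ketamine at matching in-band power. The coupling
ladder (AW 0.80, QW 0.50, NREM 0.30, REM 0.05; ketamine 0.40/0.20/0.05
for 5/10/15 mg/kg) encodes the published ordering -- the pipeline's job
in the validation suite is to recover that ordering from the raw signal,
not from the labels.

## Window selection

Scoring is in fixed 10-s epochs; analysis windows are 100 s, twelve per
state (1,200 s per state) by default. Windows are placed by tiling each
eligible contiguous same-state run with window-length slots and drawing
the requested number uniformly at random (seeded). Eligibility excludes
annotated artifact intervals and, when `stimulusClear = TRUE`, anything
within 300 s of a sound/visual stimulus event. Windows may abut but never
overlap; the overlap policy of the original hand-selection is unstated,
so non-overlap is enforced as the conservative choice. An amplitude
pre-flagger (`flagArtifacts()`, |x| > 500 uV) is available but off by
default -- artifacts are annotation inputs, not detections.

## Filtering, envelopes, bursts

The 30-45 Hz band-pass is a Hamming windowed-sinc FIR applied
forward-backward (`signal::filtfilt`), i.e. zero-phase -- cross-channel
comparisons tolerate no phase distortion. The design targets +-1 dB over
[lo+2, hi-2] Hz and >=40 dB stopband at lo-10 / hi+10 Hz; the order is
chosen from the transition width (~4 Hz at 1,024 Hz gives order ~846) and
cutoffs sit 1 Hz outside the nominal band so the squared response keeps
the passband flat.

Envelopes are either the analytic-signal magnitude (default) or full-wave
rectification smoothed with a 50-ms moving average. Burst detection --
the published selection was by eye -- uses an explicit stand-in rule:
a burst is a maximal run with envelope above mean + 2 SD lasting >=100 ms;
the trigger is the extremum of the absolute filtered trace within the run
(the peak of the largest wave), and triggered averages align that
extremum with positive polarity before averaging up to 100 randomly
selected bursts in a +-0.25 s window.

## Spectrograms

`multitaperSpectrogram()` averages eigenspectra over Slepian (DPSS)
tapers; defaults are 2-s windows, 0.5-s step, time-bandwidth 3, 5 tapers
(the method, not the parameters, is dictated by precedent -- averaging k
orthogonal tapers cuts estimator variance about k-fold). The tapers come
from the symmetric tridiagonal formulation of the concentration problem,
solved exactly up to length 512 and spline-interpolated (then
re-orthonormalized) above -- the standard low-memory construction.
`morletSpectrogram()` uses unit-energy complex Morlet kernels with 7
cycles per frequency, favoring time localization of individual bursts.

## Surrogate control

`shuffleSurrogate()` permutes the order of one channel's non-overlapping
2-s analysis blocks and recomputes the band z' per permutation. Because
the block-averaged periodogram is a symmetric function of block order,
the shuffled channel's PSD is *exactly* invariant while cross-channel
alignment is destroyed -- separating genuine cross-cortical coupling from
any single-channel spectral artifact. Blocks must equal the Welch bin
size (the alignment precondition is enforced).

## Statistics

Per subject, states are compared with a classical one-way ANOVA
(`stats::oneway.test`, equal-variance form) across per-window band
values, followed by Tamhane's T2 post-hoc: Welch-type pairwise t
statistics with Welch-Satterthwaite df and Sidak-style familywise
adjustment $p_{adj} = 1-(1-p)^m$. T2 is implemented here (no installed
package provides it) and is the variant most plausibly behind legacy
SPSS-era analyses. Across subjects, a one-way repeated-measures ANOVA
(`stats::aov` with an `Error(subject)` stratum) with Bonferroni-adjusted
paired t-tests is used; no sphericity correction is applied by default.
Degrees of freedom are reported as $(c-1),(c-1)(s-1)$; published tables
sometimes print a between-subjects-style error df, so the alternative
$(c-1, N-c)$ convention is echoed in `details$dfAlt` without asserting
either as canonical. The rejection criterion throughout is p < 0.05.

## Problem sizes in the validation suite

The acceptance-level checks run at the published scale where that scale
is what is being checked -- 12 windows x 100 s per state, five states,
five simulated subjects -- and at reduced scale elsewhere: the
coupling-recovery grid uses 600-s records per point (the closed-form
comparison tightens as 1/sqrt(T); 300 s is the floor at which the +-0.05
agreement is reliable), the white-noise bias check uses 20-50 seeds of
200-s pairs, ANOVA calibration uses 2,000-10,000 null draws, and the
burst stage uses 50 injected bursts in 100 s of noise. Unit tests use
20-100 s fixtures throughout.

## What passing tests do and do not show

The generator is stationary within a state, Gaussian apart from the
burst process, artifact-free, and stimulus-free unless events are
injected into the annotation. Real recordings add non-stationary
arousal drift, movement and electrode artifacts, volume conduction and
reference effects -- none of which are modeled. Passing the suite
demonstrates that the estimators and the inferential chain are correct
and well calibrated on signals with known coupling, and that the pipeline
recovers the encoded state ordering from raw samples; it does not certify
artifact robustness on real data. Volume conduction in particular would
inflate MSC at zero lag and is exactly the confound the channel-shuffle
surrogate is designed to expose.

## Known limitations

* High-gamma (50-100 Hz) and HFO (110-160 Hz) bands are out of scope.
* No phase-lag index, imaginary coherence, or directed measures.
* EDF I/O covers the 16-bit uniform-rate subset used here (EDF+
  annotations streams are not parsed); the legacy proprietary acquisition
  format is not read.
* No automatic sleep scoring and no artifact removal: annotations are
  inputs.
* The ketamine presets are parameter sets, not a pharmacokinetic model;
  the dose-response ladder encodes monotone decoupling directly.

## A compact worked example

```{r example, eval = FALSE}
states <- c("AW", "QW", "NREM", "REM", "K15")
res <- runStateComparison(runConfig(
  synthetic = sessionConfig(states, seed = 21),
  states = states, seed = 21))
res$coherenceTable
res$coherenceAnova[["Pf-r:Pp-r"]]@posthoc["K15", "AW"]
```
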