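---
title: "Two-phase sleep spindle detection: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase sleep spindle detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindler)
```

## The detection problem

Sleep spindles are short (0.5–2.0 s) bursts of 11–16 Hz oscillatory activity
during NREM sleep. Automatic detectors typically achieve high sensitivity only
at the cost of a very high false discovery rate, because non-spindle events
vastly outnumber spindles. `spindler` addresses this with two sequential
phases: an **unsupervised sensitivity phase** that keeps almost every
plausible candidate while controlling the pass rate against a non-spindle
null, and a **supervised specificity phase** that uses a small expert scoring
to discard whole classes of candidates with the wrong spectral or topographic
signature.

The detector is deliberately built on *point* events: each event is an
instant `t_max` (a local maximum of the wavelet ridge), not a window. No
start/end estimation is attempted; matching against expert scorings is
point-in-window.

## Signal model and segmentation

The montage `m` (nonnegative weights, unit sum) compresses the channel array
into one virtual channel `s = mᵀS`. Signed montages are rejected: every
montage used operationally is a plain local average, and the normalization
guarantees amplitude comparability. Six presets (`m1`–`m6`) cover prefrontal,
occipital, fronto-centro-parietal, and the three midline single-channel
montages; `m3` is the default.

The continuous wavelet transform uses generalized Morse wavelets
`Ψ(ω) = H(ω) c ω^β e^(−ω^γ)` with `β = 10`, `γ = 20` — a window shape chosen
for its time–frequency trade-off in the spindle band; `β` is the sensitive
parameter (larger values over-smooth in time). Two choices here were
genuinely open:

* **Normalization.** The constant `c` is fixed by *peak normalization*
  (`max Ψ = 1`), so a unit sinusoid has ridge modulus ≈ 1/2 at every analysis
  frequency. This makes ridge amplitudes comparable across the band, which
  matters because the amplitude feature is thresholded globally.
* **Scale mapping.** The scale for analysis frequency `f` is
  `a = ω_p / (2πf/fs)` with `ω_p = (β/γ)^{1/γ}` the window's *peak* angular
  frequency (not its energy frequency); with peak normalization this puts the
  maximum response of a sinusoid exactly on its own grid row.

The transform is evaluated by frequency-domain multiplication on a
zero-padded FFT grid, with negative frequencies and the Nyquist bin zeroed
(analytic wavelet). Long recordings are processed in overlapping blocks
(default 60 s, 5 s overlap); each sample takes its coefficients from the
block where it is most interior, so memory is bounded by one block while the
stitched map is seamless to ~1e-6 (tested). A cone-of-influence margin of two
envelope e-folding times of the largest scale (≈ 0.64 s at 10 Hz, 256 Hz
sampling) is flagged at the record edges; markers inside it are dropped, as
are markers inside a user-supplied artifact mask.

The ridge is `d(t_j) = max_i |w_{i,j}|` over the 10–16 Hz grid (0.1 Hz
resolution, 61 rows; ties toward the lower frequency for determinism). Event
markers are the local maxima of `d`. Discrete ties required a convention: a
plateau of equal values is a single maximum at its first sample, and only
when the plateau is higher than both neighbouring values. No minimum-duration
rule is applied anywhere before evaluation.

## Features

* `amp` — ridge value at the marker (µV-scaled; scales linearly with the
  signal).
* `sigma` — `2·max|W|(10.5–16 Hz) / (mean|W|(4–10 Hz) + mean|W|(20–40 Hz))`
  at the marker, over a 4–40 Hz grid at 0.1 Hz. Band edges are inclusive as
  printed: a 10.0 Hz row feeds the low band while the sigma band starts at
  10.5 Hz (the ridge band 10–16 vs sigma band 10.5–16 asymmetry is
  intentional and preserved). The index is invariant to global scaling and
  penalizes broadband artifacts (20–40 Hz) and slower arousal activity
  (4–10 Hz).
* `freq` — the maximizing grid frequency at the marker, mapped linearly to
  [0, 1] over 10–16 Hz.
* `med` — the channel covariance of a 500 ms window (channels mean-centered,
  no variance normalization — the first PC should pick *variability*, not
  correlation structure) is eigendecomposed; the channel with the largest
  absolute weight in the leading eigenvector represents the event's location,
  and its layout `y + 0.5` (clamped to [0, 1]) is the anterior–posterior
  feature. Absolute weight makes the feature invariant to the eigenvector's
  arbitrary sign. All recorded channels enter this PCA, not only the montage
  channels: topography estimation benefits from the full array, and the
  montage choice should not bias the spatial feature.
* `stage` — hypnogram code at the marker (epochs half-open, 20 s default).
* `expert` — 1 iff the marker lies inside (closed interval) a scored spindle
  window on Fz, Cz or Pz.

The bundled layout is a flat top-view schematic of the 10-5 positions for the
standard 10–20 channel set, compressed along `y` as in flat layout files so
that prefrontal channels map to `med ≈ 0.9` and occipital channels to
`≈ 0.15`. Users may supply their own `name x y` layout file.

## Sensitivity phase

The null sample is the (amp, sigma) of all events in REM epochs, where
spindles are assumed absent (at least 50 REM events are required). Thresholds
are the empirical `(1 − α)` quantiles of the null, per feature, with the
inverse-CDF (type-1) rule: the smallest null value `v` with at least
`⌈(1 − α)n⌉` null values `≤ v`. No interpolation is used — with an empirical
null, interpolation manufactures values that never occurred. Because the
selection rule is `≥` on both features, each *marginal* threshold lets at
most a fraction `α + 1/n` of its own null through (exactly `⌈αn⌉+…/n` pattern
when ties are absent); the *joint* pass proportion — which is what the
detector applies — is far below `α` in practice (≈ 5 % at `α = 0.1` on
simulated 1/f backgrounds, where the two features correlate ≈ 0.8).

Selection tests NREM events (stages 1–4; the tested stage set is
configurable) and requires both features at or above threshold. The expected
false discovery rate obeys `FDr = ακ/P%` with `κ` the unknown fraction of
non-spindles in the tested pool; `κ` is not estimable, so only the upper
bound `α/P%` is reported and `κ` is stored as `NA`.

## Specificity phase

Candidates are clustered on exactly `(freq, med)` — both already in [0, 1],
so no rescaling is applied. Clustering is agglomerative with Euclidean metric
and average linkage (delegated to `stats::hclust`; an independent double-loop
oracle cross-checks the merge heights in the tests). The dendrogram is cut
top-down, splitting one merge at a time in merge order, stopping at the first
partition whose second-largest/largest class-size ratio is ≥ `r = 0.6`; this
favors balanced partitions over one-big-cluster-plus-outlier cuts. Average
linkage can produce height inversions; cutting proceeds in merge order and a
message notes inversions when they occur. The all-singletons partition
trivially satisfies any `r ≤ 1` and is the guarded fallback.

Classes are ordered by descending expert-event count (ties: larger class
first, then lower class id) and the smallest prefix covering ≥ 80 % of expert
events is kept. Candidates with degenerate features (undefined `med`) are
excluded from clustering and counted as rejected. Without annotations the
detector stops after the sensitivity phase — the specificity phase is
inherently supervised.

The partial-scoring bootstrap (`subsample_expert`) re-runs class selection
with random expert subsets of given sizes (500 repetitions by default,
seeded) and reports Se/Sp differentials against exhaustive scoring, which is
how one verifies that a few dozen scored spindles suffice.

## Evaluation

By-event confusion counts always sum to the evaluated pool size. Metrics are
evaluated over the NREM tested pool (wake and REM events are outside the pool
by the same convention as the selection). MCC and Cohen's κ use their
standard definitions from the confusion marginals. Metrics with zero
denominators are `NA`, never 0. The p-value sweep re-thresholds per `α`
(descending) and reports the Se = Sp crossing by linear interpolation between
adjacent grid points. Sleep cycles follow the NREM-period/REM-period rule
with a 15-minute REM-free termination criterion; per-cycle event proportions
are normalized per class over the first four cycles.

## Synthetic data: what it does and does not emulate

`simulate_psg()` generates: per-channel `1/f` Gaussian background
(spectral-shaping of white noise, unit-variance normalized, default sd 15 µV)
with a shared component (30 % of variance) across channels — without it the
window PCA topography would be degenerate; Hann-enveloped sinusoidal bursts
(durations 0.5–2 s, default rate 5 per NREM minute, matching typical NREM2
densities) with Gaussian spatial decay (σ = 0.25 layout units) around a peak
channel; a fast class (13–14 Hz, peak channels Cz/C3/C4/Pz/P3/P4) and a slow
class (10–12 Hz, peak channels F3/F4); an optional ~1 Hz slow-oscillation
amplitude coupling (off by default); and a stage script of repeating NREM2 /
REM blocks. Annotations mimic the expert's channel restriction: exactly the
planted events peaking on Fz, Cz or Pz are scored — so with the default peak
channel sets only fast-class events are ever annotated, reproducing the
expert bias toward fast centro-parietal spindles that the class selection is
designed to exploit.

It does **not** emulate realistic full-night architecture, EMG/EOG/ECG
channels, artifacts, inter-subject variability, alpha intrusions, or spindles
with non-Gaussian topographies. Passing the end-to-end tests therefore shows
that the pipeline recovers events under its own generative assumptions
(correct plumbing, calibrated thresholds, separable classes) — not that it
reproduces performance on clinical recordings, where expert disagreement
alone moves MCC by factors of two.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 300–600 s simulated recordings
(20 channels, 256 Hz) for end-to-end checks, with amplitude 50 µV as the
high-SNR operating point; a 3300 s REM-only single-montage simulation
(≈ 10,500 events) for the null-calibration check; 100 random draws of n ≤ 10
points for the clustering oracle. These sizes keep a full run to a couple of
minutes on one CPU while leaving each check statistically meaningful.

Other conventions: times are seconds from recording start; sample indices are
1-based (R convention); hypnogram epochs are half-open; annotation windows
are closed at both ends; montage weight sums are validated to 1e-9 (1e-6 with
a normalization warning on file load); the clustering tie-break and the
lower-frequency argmax tie-break make every stage deterministic given the
seed.

## Known limitations

* EDF input is not parsed; recordings enter via the documented two-file
  plain/float32 format or in memory.
* Start/end boundaries of spindles are not estimated (by design: point
  events).
* The r-ratio cut can return more than two classes on real, messy feature
  clouds; the published behaviour ("about four classes per night") is an
  empirical observation, not a property of the rule.
* REM-based nulls inherit whatever spindle-like activity REM actually
  contains; the generator makes REM perfectly clean, real recordings do not.
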