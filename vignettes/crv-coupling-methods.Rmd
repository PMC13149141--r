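---
title: "Quantifying cardio-respiratory-vascular coupling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardio-respiratory-vascular coupling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crvcoupling)
```

## The problem

Heart rate, breathing and arterial pressure are not independent rhythms.
Respiration modulates heart period (respiratory sinus arrhythmia, RSA) and
pulse pressure (the respiratory pump); baroreflex loops tie pressure back to
heart period; a ~0.1 Hz Mayer wave rides on both pressure and heart rate.
`crvcoupling` quantifies the joint dynamics of this network from a few
minutes of synchronous single-lead ECG, thoracic-effort respiration and
continuous blood pressure, producing for each recording:

* five pairwise **coupling strengths** — time-averaged phase
  synchronization between respiration (RSP), R-R intervals (RRI), systolic
  (SBP) and diastolic (DBP) pressure series;
* five pairwise **coupling complexities** — multiscale entropy of the
  time-resolved synchronization, capturing how variable the coupling
  itself is;
* two composite totals, `rho_total` and `C_total`; and
* conventional HRV, respiratory-pattern and hemodynamic features for
  context.

## Preprocessing

All channels pass a zero-phase 50 Hz notch (band-stop 48–52 Hz). The ECG is
band-passed 0.5–40 Hz; R peaks come from a derivative–threshold detector
(5–25 Hz band-pass, squared derivative, 150 ms integration window, adaptive
threshold at a quarter of the 99th percentile, 200 ms refractory period),
with each detection refined to the local ECG extremum. The detector is this
package's own; it is validated against the generator's exact beat times
(maximum error below 10 ms at the default 250 Hz sampling) rather than
against any third-party tool.

R-R intervals are cleaned by four rules applied in order against
already-retained intervals: drop intervals above 2000 ms, below 300 ms,
changing by more than 200 ms from the preceding retained interval, or
deviating more than 20% from the mean of the five most recent retained
intervals (the first five retained intervals are exempt from the last
rule, which cannot be evaluated before a local history exists). Evaluating
against retained predecessors makes cleaning idempotent; excluded beats are
removed, and the subsequent spline bridges the gap. If more than 20% of
intervals are removed the record is flagged as a quality concern.

Respiration is resampled to 8 Hz, band-passed 0.01–2 Hz with a first-order
Butterworth filter, differentiated (so that a rising thoracic signal —
inspiration — maps to positive effort), and normalized to (−1, 1) using the
1st–99th percentile range, which keeps a single spike from compressing the
whole scale.

The pressure waveform is band-passed 0.5–12 Hz for landmark detection and
smoothed with a 50 ms moving average for value read-out. Because the
0.5 Hz high-pass removes the absolute pressure baseline, systolic and
diastolic *positions* are found on the filtered waveform but the *values*
are read from the smoothed waveform, which retains mmHg units.

Cleaned RRI, SBP and DBP series are cubic-spline resampled to 8 Hz (4 Hz
for HRV spectra), and all four series are trimmed to their common time span
on one shared grid. Filters are applied forward–backward throughout: the
phase-synchronization index is exactly the quantity a filter's phase
distortion would bias, so zero-phase filtering is non-negotiable here, even
where a single-pass first-order filter might otherwise suffice.

## The coupling engine

**Decomposition.** Each 8 Hz series is decomposed by ensemble empirical
mode decomposition: Gaussian white noise at 0.2 of the signal SD is added,
each of 100 noisy copies is decomposed by EMD, and modes are averaged
slot-wise. Sifting uses a fixed eight iterations per mode — a fixed count,
rather than a data-dependent stopping rule, makes the decomposition
bit-reproducible for a given seed across platforms. At most
`floor(log2(n)) − 1` modes are extracted; envelope splines are natural
cubics through the extrema, with two extrema mirrored beyond each boundary.
Ensemble averaging can split one rhythm across two adjacent mode slots
(the slot index varies between noise realizations), so adjacent averaged
modes whose mean instantaneous frequencies differ by less than a factor of
1.5 are summed back together; genuine neighbouring modes form a dyadic
bank (ratio ≈ 2) and are unaffected.

**Phase.** The analytic signal of each mode gives instantaneous amplitude,
unwrapped phase and frequency (central differences). Mean frequencies are
taken after trimming 5 s from each end, where Hilbert estimates are
unreliable. The highest-energy respiration mode is the reference; for RRI,
SBP and DBP the mode whose mean frequency is closest to the reference is
selected (ties go to the faster mode). This frequency matching isolates
the respiration-driven component of each signal; no n:m locking search is
attempted because matched modes share a band by construction.

**Synchronization.** For each of the five pairs, the 1:1 phase difference
is summarized in 50 s windows stepped by 1 s: the modulus of the windowed
mean unit phasor, a value in [0, 1]. The discrete mean over the closed
sample interval reproduces the continuous-integral definition to
near machine precision, and on a sinusoidal phase difference of amplitude
A it equals |J₀(A)| — the package tests both identities.

**Complexity.** Each synchronization series is reduced by refined
composite multiscale entropy: at scale τ, all τ coarse-graining offsets
are formed and template-match counts are pooled before the logarithm,
which keeps short-series estimates finite and makes scale 1 exactly sample
entropy. Parameters are m = 2, tolerance r = 0.15 of the original series'
SD (frozen across scales), scales 1–3: a 300 s record yields ~250
synchronization points, and N/τ ≥ 80 keeps the scale-3 estimate usable.
The scalar complexity is the mean over scales (the usual area-under-curve
convention divided by the number of scales); scales with no template
matches report an infinite sentinel and are excluded with a warning.

**Composites.** The totals weight the cardio-respiratory pair fully and
average the two respiratory-vascular and the two cardio-vascular pairs:

```
rho_total = rho_RSP-RRI + (rho_RSP-SBP + rho_RSP-DBP)/2
            + (rho_SBP-RRI + rho_DBP-RRI)/2
```

and identically for `C_total`. Published composite group means are only
reproducible under this grouping (applying it to published HA0 pairwise
means gives 1.79–1.81, bracketing the published 1.81; a flat "average
everything in pairs" reading gives ≈ 1.41). The flat reading remains
selectable via `grouping = "naive"` for comparison.

Whether complexity should be computed on the raw or mean-removed
synchronization series is an open choice; the raw series is used, since
sample entropy is translation-invariant and the tolerance is tied to the
series' own SD.

## Feature extraction

HRV: mean R-R and SDNN on the cleaned beat-by-beat intervals; spectra from
a 4 Hz spline resample, linearly detrended, Welch-averaged FFT (150 s Hann
segments, 50% overlap, a tail-anchored final segment; a raw full-length
periodogram is available via `welch = FALSE`). LF is integrated over
[0.04, 0.15) Hz and HF over [0.15, 0.40) Hz; logs are natural. Sample
entropy (m = 2, r = 0.2 SD) is computed on the unresampled beat sequence,
where irregularity lives; records whose breathing rate falls outside the
fixed HF band are flagged, since their vagal modulation would leak out of
HF.

Breaths are segmented from the conditioned effort signal by hysteresis
zero crossing: effort above +0.1 is inhalation, below −0.1 exhalation,
near-zero pauses are absorbed into the preceding phase (so the two duty
cycles partition each breath exactly), and runs shorter than 0.3 s are
merged. Breathing-rate variability is the CV of the per-breath
instantaneous rate (the common toolbox convention; the CV of durations is
the obvious alternative and differs only at second order).

Hemodynamic scalars (SpO2, MAP, CO, PPV) are consumed as device channels —
mean and standard error only; the package does not re-derive them from
waveforms.

## The synthetic generator

Real multi-channel recordings of this kind are not publicly deposited, so
the package carries a generator that produces records with the structural
features the analysis assumes, plus exact ground truth:

* a respiratory phase oscillator whose instantaneous rate wanders
  (Ornstein–Uhlenbeck, correlation half a breath) with per-cycle SD set by
  `resp_jitter`; the emitted thoracic waveform is the integral of effort,
  so the conditioning derivative recovers effort exactly;
* an integrate-and-fire (IPFM) heart: instantaneous R-R modulated by RSA
  (`rsa_gain`), a 0.1 Hz rhythm (`lf_gain`) and broadband variability
  (`hrv_noise_gain`, OU with 0.2 s correlation — effectively white from
  beat to beat); beats fire when the rate integral gains one unit, and the
  ECG is rendered as canonical Q-R-S-T bumps at the exact beat times;
* per-beat pressures: baseline plus respiratory-pump and Mayer-wave
  modulation, rendered as one pulse template per beat whose onset value is
  the diastolic truth and whose peak is the systolic truth;
* a coupling-jitter parameter σ (rad) injecting slow phase noise between
  respiration and the cardiac/vascular modulations — the single dial that
  degrades phase locking without changing any marginal amplitude — and an
  optional regime switch alternating σ between epochs.

Records default to 300 s at 250 Hz. The generator exists to exercise the
pipeline, not to imitate electrophysiology: ECG and pulse morphology are
fixed templates (only landmarks matter downstream), SpO2/CO/PPV are preset
constants plus noise, there is no baroreflex closed loop, no arrhythmia,
no movement artifact, and no measurement drift. Passing the recovery tests
therefore demonstrates that the pipeline measures what it claims on
signals with known structure — not that it is robust to every failure mode
of clinical data.

The five altitude-style presets (HA0–HA4) impose *orderings* — rising heart
rate, falling RSA and broadband HRV, rising breath-timing and coupling
jitter, regime switching only in the top group — chosen so the imposed
gradient is recoverable: total strength strictly decreasing, top-group
complexity exceeding baseline, strength negatively rank-correlated with
breathing variability and positively with heart-period entropy. The preset
means are illustrative, not fits to any human cohort. One known artifact:
the baseline preset's broadband HRV makes its near-flat synchronization
series fluctuate noise-like, so pairwise complexity is not monotone across
the middle presets; only the top-vs-baseline complexity contrast is a
designed (and tested) property.

## Statistics

Group differences use classical one-way ANOVA (explicit sums of squares;
a zero within-group-variance degenerate case reports an infinite F with a
warning) followed by all pairwise two-sample tests — Welch by default,
pooled variance on request — with Bonferroni correction over the full
family of pairs (10 for five groups; correcting over all pairs is
conservative relative to annotating selected pairs). Rank correlations use
average ranks; P values use the t approximation for n > 10 and a seeded
Monte-Carlo permutation (20 000 draws) for small samples, where the
t approximation is poor and exact enumeration under ties is awkward.
Percent changes are reported as `100 · (reference − comparison)/reference`.

## Numerical choices and problem sizes

* EEMD noise is drawn in R under `set.seed` and passed to the C++ core:
  identical seeds give bit-identical decompositions.
* Tie-breaks: dominant-mode and frequency-match ties both resolve to the
  lower (faster) mode index.
* Degenerate inputs fail loudly and early: constant respiration
  (normalization undefined), flatline ECG (no beats), all-zero modes
  (phase undefined), fewer than four spline support points, series shorter
  than one synchronization window.
* Test and validation workloads use 150–300 s records at 250 Hz, cohorts
  of 4–5 records per group over 3 seeds, and 5–10 seeds per Monte-Carlo
  property; these sizes give stable seed-averaged orderings while keeping
  the full suite fast.

## Limitations

Phase synchronization is computed for 1:1 locking only; n:m coordination
regimes are out of scope, as are time-delay-stability, Granger and
transfer-entropy coupling measures. The composite grouping, while the only
reading consistent with published totals, remains a convention. Complexity
is summarized as the mean of three entropy scales; longer records would
support more scales and a richer profile. EDF/WFDB readers are not
included — records enter as per-channel CSV or in-memory objects.
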