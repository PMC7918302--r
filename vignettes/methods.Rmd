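---
title: "Methods: sleep and epileptiform EEG analytics in ptesleep"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep and epileptiform EEG analytics in ptesleep}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ptesleep` re-implements, as a tested pipeline, the EEG analysis battery
used to characterize sleep-wake disturbance and interictal epileptiform
activity in a mouse controlled-cortical-impact (CCI) model of
post-traumatic epilepsy.  This vignette is the package's own account of the
methods: the models and their assumptions, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the design choices made where the method was genuinely underdetermined.

# Preprocessing

Recordings are multichannel EDF (frontal EEG, parietal EEG, nuchal EMG;
natively 1024 Hz).  All analyses run on the frontal channel.  The filter
chain is a Chebyshev type II band-stop at 60 ± 2 Hz (order 4, 40 dB
stop-band) followed by a Chebyshev type I high-pass at 0.5 Hz (order 4,
0.5 dB ripple), each applied forward and backward so the net group delay is
zero.  Orders, ripple and bandwidth are conventions rather than published
constants; they are exposed in `filter_spec()` and the tests assert the
*contract* (stop-band attenuation, DC removal, zero lag) rather than
coefficients.

Numerical choices worth knowing:

* Filtering runs in **cascaded second-order sections**.  Narrow-band
  designs (a 4 Hz notch at a 1024 Hz rate) are catastrophically
  ill-conditioned as single transfer-function polynomials — coefficients
  agree to machine precision yet outputs drift at the 1e-4 level — while
  biquads stay stable.  The SOS design path was validated against an
  independent reference implementation to ~1e-14.
* Edge handling uses odd-reflection padding with steady-state initial
  conditions.  The pad is sized to ~3 time constants of each filter
  (`3·fs/bandwidth`), because a 0.5 Hz high-pass rings for seconds and a
  fixed small pad would leak edge transients into the record.  On 24-h
  records the edge seconds are irrelevant either way; short test signals
  must measure mid-record.
* Epochs are 4 s, 0-based, half-open, trailing partial epoch discarded.
  Zeitgeber time 0 is lights-on at 06:30.

An acquisition-chain caveat: source data were hardware-filtered to 70 Hz
yet the gamma band integrates to 100 Hz; the pipeline applies no 70 Hz
low-pass, so on real data gamma power above the acquisition band may be
attenuated.  Normalized delta is a ratio over the same denominator in all
groups, so comparisons are unaffected.

# High-amplitude events and injury-specificity clustering

An event starts when the deviation of the filtered frontal EEG from its
whole-record mean crosses **5 SD** and ends when it falls back below
**1 SD**.  Thresholding uses `|x − mean|` by default: screw-electrode
epileptiform spikes may be positive- or negative-going, and a one-sided
detector would silently halve sensitivity (a signed mode is available).
The baseline is the whole record (per-hour baselines are a config option);
the detector is proven equal, boundary for boundary, to an independent
sample-scan oracle on a thousand random signals.

*Discrete spikes* are events `< 200 ms` long separated from neighbors by
`> 200 ms` (one-sided at the record ends).  Only discrete spikes enter
clustering — longer or merged discharges are not isolated spike waveforms.

Each spike contributes a 400-ms snippet centered on its peak (largest
absolute deviation), z-scored so that clustering reflects waveform *shape*,
not amplitude.  Snippets are projected onto their first 3 principal
components and clustered with a 9-component full-covariance Gaussian
mixture (k-means++ initialization, 10 restarts, recorded seed; ties in
responsibility break to the lowest cluster index; emptied components are
re-seeded at the worst-fit point).  The per-cluster **injury ratio** is
n_CCI/(n_CCI + n_NC).  Sham animals are assigned to clusters and counted in
rates but excluded from the ratio: the design question the ratio answers is
"does this waveform family distinguish definite injury from definite
no-injury", and the sham arm is by construction ambiguous (craniotomy
itself causes a mild lesion).  Events in clusters with ratio ≥ 0.90 are
*CCI-related*; per-animal rates (events/h, CCI-related events/h) feed Welch
t tests with Bonferroni multiplication by the number of contrasts, capped
at 1 (the uncapped product is retained in the output for fidelity with
sources that print values above 1).

PCA and the mixture are fitted on all events pooled (per-cohort fitting is
available); whether the source analysis pooled across time points is not
stated, and pooling is the variant that makes the ratio estimable with few
animals.

# Sleep architecture

Hypnograms are per-4-s-epoch labels in {WAKE, NREM, REM, ARTIFACT,
SEIZURE}.  Artifact and seizure epochs are excluded from every sleep
metric — numerator *and* denominator — and they **break bouts**: bridging a
bout across an excluded epoch would fabricate continuity (a
`bridge_exclusions` option exists).  Sleep efficiency is defined as
100·(NREM + REM)/(scored minutes); the source never wrote its formula, but
this is the only definition consistent with the ~51–60% daily values it
reports given ~11 h of mouse sleep.  Bouts truncated by record edges are
kept by default (`drop_edge_bouts` to exclude).  Diurnal bins are anchored
at lights-on; each epoch is assigned by its start time (4 s divides every
legal bin width, so no epoch straddles a boundary).

# Spindles

The detector is the cubed-RMS double-threshold algorithm: band-pass the
frontal EEG to 9–15 Hz, slide an RMS window, cube the series (cubing
stretches the dynamic range so burst peaks separate cleanly from
background), and take as candidates the maximal intervals above
`1.5 × baseline` that contain a sample above `3.5 × baseline`.

Decisions inside that sentence:

* **Baseline** = mean of the cubed envelope over NREM samples, per animal
  and recording.  This reproduces the flat horizontal thresholds the
  original algorithm draws, and it is self-normalizing across animals;
  detection is invariant to global amplitude rescaling.  The median variant
  is available but *not* the default: the median ignores the spindles' own
  contribution to the baseline, which sounds attractive, but it drops the
  thresholds so low that background sigma fluctuations constantly cross
  them (precision collapsed from ~1.0 to ~0.4 in simulation).
* **RMS window** = 1.0 s (legal range 0.1–1.0 s).  The window is a free
  smoothing parameter judged by parameter recovery: at 0.75 s the detected
  duration of realistic waxing-waning spindles is biased −0.29 s, at 1.0 s
  the bias is −0.14 s with precision 1.0 and recall 0.98, so the top of the
  legal range is the default.
* **Duration bounds** 0.5–10 s; spindles crossing an NREM boundary are kept
  if ≥ 50% of their samples lie in NREM (strict containment available).
* **Artifact guard**: candidates containing a raw-signal excursion beyond
  5 SD of the record are rejected (when the raw trace is supplied).
  Interictal spikes ring through any 9–15 Hz band-pass and otherwise appear
  as short, high-sigma pseudo-spindles; the guard reuses the event
  detector's own 5 SD convention and mirrors the artifact exclusion that
  manual scoring applies.  Disable with `artifact_sd = Inf`.
* Spindle frequency is the zero-crossing rate of the band-passed snippet;
  power is the mean squared band-passed amplitude (µV²) — the mean, not the
  integral, which is the reading consistent with reported magnitudes of a
  few hundred µV².

Density is spindles per NREM minute, overall, per 6-h bin (bins with no
NREM report missing, not zero), or restricted to lights-on.

A structural caveat the tests quantify rather than hide: a
threshold-crossing duration is only as well defined as the burst envelope
is steep.  For waxing-waning bursts the selection threshold probes ~15–40%
of peak amplitude depending on the burst-to-background ratio, so "duration"
means "extent above a baseline-referenced threshold", and comparisons of
durations across groups are meaningful while absolute durations inherit the
algorithm's convention.

# Normalized NREM delta power

Each 4-s epoch gets a Hann-windowed periodogram (0.25 Hz resolution) with
window power correction, so the integrated PSD equals the windowed-signal
variance (Parseval; checked to 1% analytically and 5% by Monte Carlo).
Band powers are trapezoidal integrals over delta 0.5–4, theta 5–9, sigma
10–14, gamma 25–100 Hz.  The source text carries two band variants (theta
6–9/sigma 10–15 in a figure legend); the Methods-section values are the
default and `band_scheme()` expresses either.  Similarly the denominator of
normalized delta is stated both with and without delta; the default
**includes** delta, making nDelta a bounded fraction in [0, 1] —
scale-invariant, monotone in delta power, and robust to division blowups —
and the flag `include_delta_in_denominator` restores the other reading.
Power in 4–5 Hz and 15–25 Hz is deliberately unused (both text variants
agree on that).  NREM epochs only are profiled into 4-h bins with
normal-approximation 95% CIs.

# Statistics

* `one_way_anova_holm()` — classical one-way F plus pairwise contrasts
  sharing the pooled within-group variance, Holm step-down adjusted.
  Degenerate designs (zero within-group variance) are flagged and given
  limit-case p-values rather than NaNs.
* `mixed_anova()` — the source describes "mixed-model ANOVA, treatment
  fixed, time random".  With one value per animal × bin, the classical
  split-plot decomposition respects the animal as the experimental unit
  exactly: the group effect is tested between animals (equivalently,
  one-way ANOVA on per-animal means), bin and group × bin within animals.
  A REML mixed model with Satterthwaite degrees of freedom was considered
  and rejected: the required machinery is not in the dependency budget, and
  for balanced bins the split-plot test is the same inference.
  Tukey–Kramer pairwise comparisons use the between-animal stratum and
  reduce to Tukey's HSD when groups are balanced (verified against
  `TukeyHSD`).
* `welch_bonferroni()` — unequal-variance t with Welch–Satterthwaite df;
  p multiplied by the number of planned comparisons, capped at 1, uncapped
  value retained.
* `hourly_event_wake_correlation()` — Pearson r, r², p on ≥ 3 paired
  hours; zero-variance series yield an explicit undefined result.
* A descriptive `skewness_report()` is emitted but never gates an
  analysis: the source mentions a skewness screen whose threshold citation
  is irrecoverable, so no arbitrary gate is invented.

All tests are location-scale invariant, and each one's empirical type-I
error is calibrated to [0.03, 0.07] at nominal 0.05 under its own null
(1000 simulations in the acceptance suite).

# The synthetic cohort generator

The generator is the package's test bed: a statistical stand-in with exact
ground truth, not a biophysical EEG model.  Defaults encode the simulated
study's stated world: 24-h days at 1024 Hz, three arms (NC/sham/CCI), and a
seizure-positive subcohort.

* **Hypnogram**: semi-Markov chain over WAKE → NREM → (REM | WAKE) with
  geometric bout lengths; REM is entered only from NREM.  Light phase at
  bout onset selects the parameter set: lights-on favors sleep (wake 120 s,
  NREM 200 s, REM 70 s, p(NREM→REM) = 0.35), lights-off favors wake
  (240/120/50 s, 0.25).  Those values give per-phase sleep fractions of
  ~0.65/0.36 and daily sleep efficiency near 50%, the magnitude reported
  for this kind of cohort; injured arms multiply bout lengths by 0.7 (sham)
  and 0.6 (CCI) to emulate fragmentation.  Explicit bout-length
  distributions (rather than a plain Markov chain) make mean bout length
  directly controllable, which the bout-recovery tests need.
* **EEG**: one-pole-filtered (1/f-ish) background with per-state SD (wake
  20, NREM 25, REM 20 µV) plus a 5 µV broadband floor; NREM adds a
  1.5–3.5 Hz delta oscillation at arm-ordered amplitude (NC 40, sham 55,
  CCI 70 µV); REM adds 6–8 Hz theta at 30 µV.  EMG is white noise with
  state-dependent SD (wake 40, NREM 15, REM atonia 5 µV).
* **Spindles**: Gaussian-windowed 11–13 Hz bursts at 40 µV peak, placed in
  NREM by a refractory renewal process at 2.0/min (lights-on) and 1.0/min
  (lights-off) — the renewal gap is rate-corrected so the delivered density
  matches the configuration.  The nominal duration *d* (drawn N(2.0, 0.4) s,
  clipped to 1–3 s) spans ±2σ of the envelope (σ = d/4), synthesized over
  ±3σ: the logged extent is the part of the burst holding > 13% of peak
  amplitude, which is what a scorer would delimit.  An earlier σ = d/6
  variant put the outer third of the nominal duration below 5% of peak —
  a ground truth no detector (or human) could reproduce, i.e. an ill-posed
  target rather than a detector property — and was redefined once.
* **Spikes**: sharp biphasic template (20 ms spike + 60 ms wave, 400 µV) as
  the injury morphology, blunt 150-ms bump (350 µV) as background; Poisson
  rates per arm (NC 0+10/h, sham 15+10/h, CCI 40+10/h) with 0.5 s
  refractory.  Amplitudes sit at ~8× the record SD so the 5 SD detector is
  exercised well above threshold.
* **Seizures**: with probability 0.25 per CCI animal, one amplitude-ramped
  6 Hz spike-wave train of duration U(20, 160) s; overlapping epochs are
  relabeled SEIZURE and spikes avoid the seizure neighborhood.

What the generator does **not** emulate: real spectral shape beyond the
1/f-ish bed, waveform variability within template families beyond amplitude
jitter, scorer noise in the hypnogram (states are exact), inter-animal
variability beyond the arm parameters, and electrode artifacts with
structure (ARTIFACT labels are placed at random without modifying the
signal).  A green recovery test therefore establishes that an algorithm
recovers known structure under realistic magnitudes and rates — not that it
would survive every pathology of real recordings.

# Pipeline and reproducibility

`run_pipeline()` runs preprocess → events → sleep → spindles → spectral →
stats over a cohort directory with a JSON manifest, isolates stage
failures (a cohort without a CCI arm errors the injury-ratio stage and
completes everything else; a missing hypnogram skips that animal's sleep
stages with an explicit log line), and writes a JSON report whose md5 is
the content hash — the pipeline is a pure function of (fixtures, config,
seed), and the acceptance suite asserts hash stability across reruns.  All
randomness (mixture initialization, generator draws) flows through recorded
seeds, and library code restores the caller's RNG state.

Manifests and reports are JSON rather than YAML: the offline dependency
budget contains a JSON library and no YAML parser, and the sidecar contract
(machine-readable, diffable) is unchanged.

# Known limitations

* Spindle "duration" and "power" are algorithm conventions (threshold
  crossings; mean µV²); cross-study absolute comparisons need the same
  conventions.
* The split-plot ANOVA assumes balanced bins within animal, which the
  pipeline's binning guarantees; severely unbalanced external tables should
  use the one-way path or an external mixed-model fit.
* The EDF writer emits 16-bit, one-second records, symmetric physical
  range — sufficient for round-tripping this pipeline's data, not a general
  EDF+ implementation (no annotations, no discontinuous records).
* Seizure detection is out of scope by design: hypnograms carry SEIZURE
  labels in, and the generator produces them, but no electroclinical
  seizure classifier is provided.
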