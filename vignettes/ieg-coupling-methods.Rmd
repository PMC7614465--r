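---
title: "Methods: coupled analysis of calcium activity and IEG reporter expression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled analysis of calcium activity and IEG reporter expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iegcoupling)
```

## The problem

Chronic two-photon experiments in mouse primary visual cortex can record, in
the same layer 2/3 neurons, a red calcium indicator (a proxy for spiking) and
a GFP-based immediate-early-gene (IEG) reporter (Arc, c-Fos, or EGR1; a proxy
for activity-dependent gene expression). Two experimental designs are
supported:

* **Dark adaptation**: dark-adapted mice are measured every 15 minutes for
  6 hours (25 measurement timepoints), with a single block of moving-grating
  stimulation between the first and second measurement. This design asks
  *when* and *how strongly* expression follows activity.
* **Visuomotor learning**: dark-reared mice are imaged twice daily for six
  days through three conditions — darkness (condition 1), first visual
  exposure in a virtual-reality corridor (condition 2), and a normal
  light/dark cycle, i.e. first normal visuomotor coupling (condition 3).
  Condition-2/3 sessions contain seven ~8-minute recordings (dark,
  closed-loop, two open-loop replays, dark, gratings, dark), with brief (1 s)
  halts of visual flow during closed loop to evoke visuomotor mismatch.
  This design asks *which functional cell types* express which IEG.

The package implements the full analysis chain for both designs, and a
synthetic-data generator with known ground truth so that every stage has a
parameter-recovery test.

## Imaging-derived quantities

* **ROI fluorescence**: the mean pixel value inside each ROI mask per frame
  (`extract_roi_fluorescence()`); IEG snapshots read the mean-fluorescence
  projection of the green channel (`measure_ieg()`).
* **dF/F**: per neuron, `(F - median(F)) / median(F)` with the median taken
  per recording segment (`compute_dff()`). Whether the normalizing median
  should be computed per segment or per session is an open choice; per
  segment is the default because it is robust to slow drift between
  recordings. An optional causal exponentially weighted smoothing filter
  (time constant 0.2 s by default, one parameter, toggleable) stands in for
  the trace filtering customary in this preparation. Negative dF/F is kept.
* **Expression normalization** (`normalize_ieg()`): per mouse, all ROI
  values over all timepoints are shifted by their global minimum and scaled
  by their global median, so the normalized matrix has minimum 0 and
  median 1. The map is idempotent and invariant to positive affine
  transformations of the raw data; all cross-mouse comparisons use
  normalized values.

## The lagged coupling analysis

For each measurement timepoint the activity of each neuron is summarized as
the mean (or maximum) dF/F over the session's dark measurement recordings
(`summarize_activity()`). The grating-stimulation block drives expression but
is not itself a measurement timepoint; a `segments` argument allows
restricting summaries to any segment kind (e.g. stimulation-block activity
for activity-vs-expression scatter analyses).

`lagged_population_correlation()` computes, for every lag `L` on a grid
(default −2 h … +6 h in 15-min steps, matching the measurement cadence), the
Pearson correlation across neurons between the activity population vector at
time `t` and the expression population vector at time `t + L`, averaged over
all timepoint pairs at that lag (unweighted mean; how the original analysis
combined equal-lag pairs is not specified, and the unweighted mean is the
symmetric choice — flagged in the output metadata via `n_pairs`). Lags with
no pairs are missing, never zero.

`peak_statistics()` reports, per mouse, the lag of the maximum (earliest lag
on ties, a deterministic rule) and the value at the maximum. Because the
correlation curve is flat near its top relative to the 15-min grid, it also
reports a sub-grid refined peak: a quadratic fit within ±1 h of the argmax,
vertex clamped to the window. The cohort-level peak lag used in the
summaries is the argmax of the mouse-averaged curve, which pools all
equal-lag pairs of all mice and is considerably more stable than per-mouse
argmaxes.

Group comparisons of peak correlations between reporter lines use a
bootstrapped t-test (`bootstrap_t_compare()`): each group's per-mouse values
are resampled with replacement five times, pooled, and compared with a
two-sample pooled-variance t-test. The resampling unit is the mouse (the
groups are cohorts of four mice); the reported degrees of freedom follow the
pooled-sample t and are printed explicitly.

## Expression dynamics across learning

`build_timecourse()` produces one value per mouse and session: mean dF/F
over all recordings of the session, or mean normalized expression of the
session's last snapshot (the session-to-timepoint convention used
throughout; missing sessions propagate as missing and are excluded
pairwise). `condition_change()` measures a boundary step as (mean of first
two sessions after) − (mean of last two sessions before), with a paired
t-test across mice. `linear_trend()` fits OLS on mouse-timepoint
observations and reports R² with the overall-F p-value, plus the average of
per-mouse fits for plotting. `pattern_similarity()` computes Spearman rank
correlations between expression population vectors of every timepoint pair,
averaged over mice (Kendall available behind a flag). Rank correlation makes
the matrix invariant to monotone transforms, so raw and normalized
expression give identical results.

## Event-triggered functional characterization

Running onsets are upward threshold crossings (default 1 cm/s) after ≥1 s of
quiescence followed by ≥1 s of sustained running; the thresholds are not
prescribed by the experimental literature and are exposed in the
configuration. Mismatch events are the logged closed-loop flow halts, which
the generator only inserts while the animal runs (mismatch presupposes
self-motion). Grating responses are aligned to drifting-grating onsets
(configurable). `event_triggered_response()` subtracts the mean dF/F in
[−500 ms, −100 ms) from the mean over [0, 1.5 s) per event and averages over
events, dropping truncated windows. Responses are pooled over all sessions
of a condition and z-scored over the whole population
(`zscore_over_population()`, population SD), pooled-then-scored.

High-IEG neurons are the top 10 % by mean expression over the first day of
condition 3 (both same-day sessions — sessions 9 and 10 — by default),
with round-half-up counts and ties broken toward the lower neuron id
(`select_high_ieg()`). Open-loop behavior correlations
(`behavior_correlations()`) correlate each neuron's concatenated open-loop
dF/F with the running trace and with the visual-flow trace.
`group_contrast()` compares the high-IEG group against zero and against the
rest of the population with t-tests; no multiple-testing correction is
applied by default (a Holm flag is available via `p.adjust` downstream).

## The synthetic-data generator

The generator (`simulate_cohort()`) produces everything the analyses
consume, with ground truth.

**Cell types.** Neurons are visual, motor, mismatch, or untuned
(default fractions 0.35/0.30/0.15/0.20, a composition in line with
functional surveys of layer 2/3); untuned neurons have all gains zero, and
mismatch neurons carry a smaller motor weight in addition to their mismatch
weight, reflecting their motor-related excitatory input.

**Behavior.** Locomotion is a two-state (rest/run) Markov process with
exponential dwell times (defaults 16 s rest / 4 s run, i.e. a ~20 % running
duty cycle; bout speeds ~12 cm/s). Closed-loop visual flow equals gain ×
running speed except during Poisson-inserted 1-s halts (gated on running,
refractory ≥5 s); open-loop segments replay the preceding closed-loop flow
sample for sample; grating blocks carry the randomized trial list
(8 directions × 10 repetitions, 2 s standing + 3 s drifting).

**Activity.** Per neuron, rate = excitability × (baseline + visual gain ×
flow/grating drive + motor gain × running + mismatch gain × halt-and-running
indicator), rectified; spikes are inhomogeneous Poisson on the 10-Hz trace
grid; fluorescence is the spike train convolved with a 0.5-s exponential
calcium kernel plus white noise. The per-segment lognormal excitability
modulation (sdlog 0.8) makes a neuron's activity fluctuate strongly across
15-min timepoints while time-averaged rates are relatively homogeneous
(baseline sdlog 0.05). This deliberately under-represents the heavy-tailed
stable rate heterogeneity of real cortex: stable rate differences contribute
equally at every lag and only dilute the lag structure, whereas the
timepoint-to-timepoint fluctuations are what make the induction delay
identifiable at these cohort sizes.

**Expression.** Raw expression at snapshot time `t` is

$$E_i(t) = b_i + g \, c_{k(t)} \, d_{i,k(t)} \, S_i(t) + \varepsilon,$$

where `S_i(t)` integrates the per-segment activity summaries
`u_i = (1-w)\,\mathrm{mean} + w\,\mathrm{max}` of dF/F through a
gamma-shaped causal kernel `K(s) = (s/p)^a e^{a(1-s/p)}` with analytic peak
at `p = induction_delay_h` and tail time constant `ieg_decay_h`
(`a = p/decay`; shape `a+1 ≥ 2` at all defaults). The kernel was chosen
because it is smooth, causal, and has a closed-form peak, integral, and
squared integral. Each recording stands in for the epoch it samples (weight
= half-distance to neighboring recordings, capped at the 15-min cadence),
and unmeasured time — before the experiment and between sessions — is
assumed to run at the neuron's *expected* activity with matched variance.
This steady-state closure matters: without it, kernel coverage grows over
the session and the stable component of the correlation curve ramps with
lag, displacing the peak. The fill uses a deterministic function of ground
truth and stimulus (never the measured samples), so it shares no sampling
noise with any measurement.

`c_k` is a per-condition gain and `d_{i,k}` a per-neuron, per-condition
drive that encodes which functional weights expression tracks (uniform,
lognormal random, visual, visual gated by corridor-orientation tuning, or
motor+mismatch). Identical drive-map entries in adjacent conditions share
one draw, so expression patterns re-rank exactly where the map changes.
Expression noise is white with SD = mean level / `snr_ieg`.

**Per-line presets.** The three reporter lines differ in kinetics, drive
maps, condition gains and noise:

* *Arc*: peak 3.5 h, decay 0.35 h, `w = 0.25`; drive uniform in darkness,
  corridor-tuned visual at condition 2, full visual at condition 3;
  condition-3 gain 2.2 (expression steps up).
* *c-Fos*: peak 3.5 h, decay 0.4 h, `w = 0.05`; uniform drive throughout
  (no pattern transitions); condition gains 1.
* *EGR1*: peak 2.5 h, decay 3 h (a broad, earlier kernel, giving the flat
  positive correlation window), `w = 0.6`; drive switches to motor+mismatch
  at condition 3 with gain 0.55 (expression steps down).

The coupling gain and `snr_ieg` of each line were calibrated once, against
the lagged-correlation pipeline itself run at the reference cohort size
(4 mice × 300 neurons), so that the recovered mouse-averaged peak
correlations reproduce the reference ordering and magnitudes (c-Fos highest
at ≈0.37–0.39, Arc intermediate ≈0.31, EGR1 lowest ≈0.16) with the peak at
the configured delay; they were then frozen. The short effective decay of
the Arc/c-Fos kernels is an *effective* choice — it reflects the width of
the empirical activity-expression cross-correlation rather than the
literature half-life of either protein, and it is what keeps the peak lag
identifiable against the ±6 h lag-grid edges, where single timepoint pairs
dominate the curve.

**Rendering.** `render_frames()` paints activity and expression into
dual-channel pixel stacks (additive where masks overlap, constant
background, optional white noise) so the extraction code can be tested by
round trip; `write_stack_tiff()` stores stacks as 32-bit multi-page TIFF.
Default frame geometry is 400 × 750 pixels; the four-plane scheme of the
microscope is metadata only and rendering uses one plane.

## Statistical kernels

`t_test_one_sample()`, `t_test_two_sample()` (pooled variance by default —
the compared groups are small and similar-sized — Welch behind a flag),
`t_test_paired()` and `regression_f_test()` wrap the classical procedures
and return a uniform `TestResult` (statistic, two-sided p, df, n, method,
seed) that is serialized into every summary table. Two-sided p-values are
used throughout. Zero-variance inputs yield flagged degenerate results
rather than errors; the bootstrap comparison reports p = 1 with a warning in
that case.

## Problem sizes, tolerances and determinism

* All simulation outputs are bit-identical under a fixed seed; sub-seeds for
  truth/behavior/activity/expression derive from the mouse seed via a Lehmer
  step, so stages are independently reproducible.
* The dark-adaptation recovery analyses use 4 mice × 300 neurons with 60-s
  measurement recordings (the per-measurement recording duration is not
  fixed by the experimental design beyond the 15-min cadence; 60 s is a
  realistic brief activity snapshot) and 20 replicate cohorts.
* Learning-protocol analyses in the test suite run at reduced scale —
  120–200 neurons, 60–120 s recordings, 3 grating repetitions, and a halt
  rate of 0.2 Hz so the shortened closed-loop recordings still contain
  mismatch events; the session structure is never altered.
* Floating-point contracts (normalization post-conditions, oracle
  equivalences against brute-force reimplementations) are tested at 1e-9 to
  1e-12; statistical recoveries at the 2·SE / ≥90%-of-seeds level stated in
  each test.

## What passing tests do and do not show

The generator reproduces the *structure* of the experiments: measurement
cadences, closed/open-loop coupling, mismatch statistics, delayed
line-specific induction, and the functional-type composition of layer 2/3.
It does not model neuropil contamination, image registration errors, eye
movements, orientation-tuning development, heavy-tailed stable rate
distributions, or reporter-protein maturation chains; the closed-loop
corridor is a fixed scalar gain, not a geometric virtual environment.
Parameter recovery on this generator therefore validates the analysis
implementation and its statistical behavior — not the biological claims, and
not robustness to imaging artifacts that the generator does not emulate.
One known side effect of the uniform c-Fos drive is that high-c-Fos neurons
coincide with the most active (often motor-driven) neurons, giving them a
positive running-onset contrast that the real data do not show.
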