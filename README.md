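# iegcoupling

Analysis pipeline for chronic two-photon experiments that record neuronal
calcium activity together with GFP-based immediate-early-gene (IEG) reporter
expression (Arc, c-Fos, EGR1) in mouse visual cortex, plus a synthetic-data
generator with ground truth that makes every analysis stage testable by
parameter recovery.

## What it computes

For populations of layer 2/3 neurons imaged across sessions, the package
implements:

* **Imaging quantities** — ROI fluorescence (mean mask pixel value per
  frame), median-normalized dF/F
  (`ΔF/F = (F − median F) / median F`, per neuron and segment), IEG snapshot
  intensities from mean projections, and the per-mouse min/median expression
  normalization `(ROI − min) / (median − min)` (minimum 0, median 1 over all
  ROIs and timepoints).
* **Activity–expression coupling** — the time-lagged population-vector
  correlation: for lag `L`, the Pearson correlation across neurons between
  the activity population vector at time `t` and the expression vector at
  `t + L`, averaged over all timepoint pairs at that lag (grid −2…+6 h in
  15-min steps); per-mouse peak lags and peak correlations; bootstrapped
  (5× resampling of mice) t-tests between reporter lines; and the
  mean- vs max-activity coupling contrast.
* **Expression dynamics across visuomotor learning** — per-mouse
  timecourses, condition-boundary change statistics (last two sessions
  before vs first two after), OLS linear trends with R²/F-tests, and
  rank-order (Spearman) expression-pattern similarity matrices.
* **Functional characterization of high-IEG neurons** — top-10 % selection
  by expression at the first day of normal visuomotor coupling
  (round-half-up: 197 of 1969 neurons, 121 of 1213, …), event-triggered
  responses (baseline −500…−100 ms, response window 1.5 s) to running
  onsets, drifting gratings and visuomotor mismatch, population z-scores,
  open-loop running/visual-flow correlations, and high-vs-rest group
  contrasts.
* **Synthetic experiments** — Markov locomotion with closed-loop /
  open-loop / grating visual flow and 1-s mismatch halts; Poisson spiking →
  exponential calcium kernel → noisy fluorescence; and delayed IEG induction
  through a gamma-shaped kernel `K(s) = (s/p)^a e^{a(1−s/p)}` peaking
  `p` hours (default 3.5) after activity, with per-line coupling mode
  (mean/max mixture), per-condition expression drives, and steady-state
  closure for unmeasured time.

See `vignettes/ieg-coupling-methods.Rmd` for the full model description and
design rationale.

## Worked example

Simulate a dark-adaptation cohort (4 mice × 300 neurons, measurements every
15 min for 6 h) for the Arc reporter line and recover the induction delay:

```r
library(iegcoupling)

cfg <- generator_config(ieg_line = "Arc")      # documented per-line defaults
coh <- simulate_cohort(cfg, "dark_adapt_fig1", seed = 42, keep_fluor = FALSE)
cp  <- coupling_pipeline(coh)                  # lags -2..+6 h, 15-min steps

cp$peak_lag_mean_curve_h   # 3.5   <- argmax of the mouse-averaged curve (h)
cp$peaks$mean_r            # 0.324 <- mean per-mouse peak correlation
cp$peaks$sem_r             # 0.028
```

The recovered peak lag equals the generator's configured induction delay
(3.5 h); the peak correlation is the strength of the activity→expression
coupling under the Arc preset. The numbered drivers under `analysis/` run
the full workflow (simulate → coupling → dynamics → responses → report) and
write tidy CSV/JSON tables under `results/`; stage 2, for example, prints
per line:

```
Arc: peak lag 3.50 h (mean-curve argmax), peak r 0.315 +/- 0.012 (mean +/- SEM over 4 mice)
cFos: peak lag 3.50 h (mean-curve argmax), peak r 0.374 +/- 0.018 (mean +/- SEM over 4 mice)
EGR1: peak lag 6.00 h (mean-curve argmax), peak r 0.159 +/- 0.010 (mean +/- SEM over 4 mice)
```

i.e. the c-Fos line couples most strongly, Arc is intermediate, and the
broad EGR1 kernel yields a weak, flat correlation curve without a sharp
peak.

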