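---
title: "Methods: taut-string ECG features and SVM+ for qSOFA deterioration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taut-string ECG features and SVM+ for qSOFA deterioration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The prediction task

`sepsislupi` implements a prognostic pipeline for short-horizon sepsis
deterioration. An instance is anchored at a time `t0` at which a
patient's quick-SOFA score equals exactly 1 (one of: GCS ≤ 13, systolic
blood pressure ≤ 100 mmHg, respiratory rate ≥ 22/min — all boundaries
inclusive). The binary outcome is whether the qSOFA score reaches 2 or 3
at `t6 = t0 + 6 h` (positive class, `+1`) or stays below 2 (negative,
`-1`).

Two information regimes are distinguished:

* **Regular space** — everything available at or before `t0`: the 10
  minutes of lead-II ECG ending at `t0`, and EHR observations at the
  five lookback times `t-16, t-12, t-8, t-4, t0` (hours).
* **Privileged space** — the 10 minutes of data ending at `t6`.
  Privileged features exist only for training instances (the data are
  retrospective); at prediction time only regular features are seen.
  This is the *learning using privileged information* (LUPI) paradigm.

# Taut-string signal approximation

For a discrete signal `f = (f_0, …, f_n)` and a tube half-width
`ε > 0`, the taut-string estimate is the unique `g` with
`max_i |f_i − g_i| ≤ ε` minimising `Σ_i (g_{i+1} − g_i)²`. Geometrically
`g` is a string pulled tight through the corridor of vertical gates
`[f_i − ε, f_i + ε]`; it is piecewise linear, bending only where it
touches a gate boundary, and `r = f − g` acts as a noise estimate.

## Algorithm and numerical choices

The estimate is computed by a funnel (shortest-path) walk over the gate
corridor in `O(n)` — a quadratic-programming formulation would be
infeasible for the 72,000-sample 5-minute windows the pipeline
processes. Because the shortest path minimises *every* convex function
of the successive differences simultaneously, the same solution
minimises the squared-difference objective and the total variation,
which is why the denoised total variation is non-increasing in `ε`
(tested as an invariant).

Endpoints are free inside their gates (nothing in the definition pins
them). They are located by convex line search on the pinned-endpoint
subproblem, using the optimality condition `g_0 = clip(g_1, f_0 ± ε)`:

* on long signals each endpoint only influences the string up to its
  first few gate contacts, so the search runs on a prefix/suffix
  anchored twelve knots deep;
* long signals with very few contacts (wide tubes) instead iterate a
  knot-compressed box QP (variables = string values at contact columns,
  weights = inter-contact distances) to a fixed point of the endpoint
  optimality conditions.

All three paths were validated against independent quadratic-programming
oracles (projected SOR, and `scipy`'s bounded least squares during
development) to below `1e-12` relative objective error on roughly a
thousand random signals from 2 to 8,000 samples; the shipped test suite
re-checks 100 random signals against a projected-SOR oracle at the
`1e-6` tolerance. When a horizontal line fits inside the whole tube the
forced constant estimate is returned, with the tie broken towards the
middle of the feasible band.

## The six features and their conventions

From each estimate the pipeline computes: number of line segments,
number of inflection segments, total variation (`Σ|Δx|`) of noise and
of the denoised signal, and power of the denoised signal and of the
noise. Two of these are stated loosely in the literature this design
follows, so the package fixes explicit conventions:

* **Power** is the mean squared amplitude `mean(x²)` (not summed
  energy, not variance).
* **Inflection segments** are interior slope-change points where the
  slope *sign* flips (rising→falling or falling→rising). Slopes are
  compared with a tolerance of `1e-9` (in slope units) so that
  numerically collinear pieces merge; slopes within the tolerance of
  zero carry no sign and do not create inflections.

The schedule `ε ∈ {0.0100, 0.1575, 0.3050, 0.4525, 0.6000}` (signal
units, here millivolts) is the default; each 10-minute regular segment
is split into two 5-minute windows, giving the 2 × 5 × 6 feature tensor,
flattened window-major, then `ε`, then feature. The privileged ECG
features are the same bank on the *unwindowed* 10-minute `t6` segment
(30 values) plus seven statistical features.

# ECG preprocessing

Segments are filtered with a second-order Butterworth band-pass
(0.5–40 Hz) applied forward and backward (`signal::filtfilt`). The
zero-phase choice is deliberate: a causal single pass would delay and
skew QRS morphology, which the taut-string features react to; the cost
is a doubled effective filter order, which only strengthens stop-band
attenuation. Filtering is linear, so feature extraction commutes with
amplitude scaling of artefact-free inputs.

Statistical features fix these conventions (tested): variance with
`1/n` normalisation; skewness and kurtosis as standardised third and
fourth moments (Pearson; a Gaussian has kurtosis 3); Shannon entropy of
a 64-bin equal-width histogram in nats with empty bins contributing 0;
`mean_abs_fft` as the mean modulus of the unnormalised DFT. A
zero-variance window defines skewness, kurtosis and entropy as 0.

Segment quality is screened by `noise_fraction()`: 10-second subwindows
are flagged when flat (peak-to-peak < `1e-4` mV), clipped against an
amplitude rail (> 5% of samples at the subwindow extreme), or out of
physiologic range (|x| > 6 mV). Instances with ≥ 50% flagged subwindows
are rejected with a reason code. The 50% rule is part of the protocol;
the detector itself is a configurable heuristic because no canonical
definition exists.

# EHR features

Each observation block contributes 23 values: five vitals (temperature,
SpO2, heart rate, mean arterial pressure, respiratory rate), hourly
urine output, ten labs as ordinal severities 0–4, and seven
cardiovascular infusions as ordinal severities 0–3 (0 always means
"nothing logged"). The regular space concatenates the five lookback
blocks in time order (115 values); the privileged space is the single
`t6` block (23 values).

Ordinal thresholds live in a YAML configuration
(`inst/extdata/ehr_encoding_default.yaml`). The shipped defaults are
clinically plausible synthetic cut points assembled from common
critical-care reference ranges — they are explicitly *not* a canonical
published encoding, and sites should substitute their own. Missing
numeric vitals/urine are filled by last observation carried forward
across lookbacks, then by configured population defaults; ordinal
features never carry forward, since absence itself is the "0" state.

# The classifiers

## Baseline SVM

The baseline is a standard soft-margin Gaussian-kernel SVM: the dual
`min ½ aᵀ(K ∘ yyᵀ)a − 1ᵀa` with `0 ≤ a ≤ C`, `yᵀa = 0`, solved by a
deterministic maximal-violating-pair SMO with an explicit bias recovered
from the free support vectors.

## SVM+

SVM+ replaces the slack variables by a linear model in the privileged
space, so that hard training instances (as judged at `t6`) relax the
margin where the regular features alone cannot explain the difficulty.
With features augmented by a constant 1 (absorbing the bias; on the
kernel side this adds +1 to every kernel value), the dual reduces to

```
min ½ αᵀ(H + G)α,   H = (K + 1) ∘ yyᵀ,   G = K*(γI + C K*)⁻¹
```

where `K` and `K*` are the regular and privileged kernel matrices. `G`
is computed in the kernelised form via the push-through identity
`Pᵀ(γI + C P Pᵀ)⁻¹P = K*(γI + C K*)⁻¹`, so nonlinear privileged kernels
are supported; for explicit linear privileged features the two forms
agree to `1e-10` (tested). The coefficients come from the one-class-SVM
dual: `min ½ αᵀQα` subject to `Σα = νn`, `0 ≤ α ≤ 1`, solved by a
pairwise SMO that always picks the first maximal violator, making fits
bit-reproducible.

Numerical choices made here:

* The working-set solver stops at KKT violation ≤ `1e-8` or 200,000
  pair updates. The looser `1e-5` that would suffice for classification
  alone leaves a duality gap orders of magnitude above the `1e-6`
  objective agreement the oracle tests demand, so the tighter default
  was adopted; both are arguments.
* `ν = 0.5` and `γ = 1` by default. The one-class level `ν` only
  rescales the coefficient mass and leaves the score *ranking*
  unchanged, which is why it is not part of the hyperparameter grid;
  `γ` controls how strongly privileged information shapes the fit
  (`γ → ∞` recovers the correction-free solution, a tested limit).
* The privileged kernel defaults to Gaussian with scale `sqrt(d*)`;
  a linear privileged kernel is available and is what the algebraic
  cross-checks use.
* Class predictions threshold the raw score at 0; AUROC/AUPRC use raw
  scores. Whether a tuned threshold would be preferable is left open
  deliberately — 0 is the canonical choice and keeps F1/sensitivity/
  specificity comparable across arms.

# Evaluation protocol

Each of the (default 100, configurable) iterations: split patients —
never instances — 80/20 into training and test, reserve 20% of the
training patients as validation, standardise every design matrix by
training-set statistics, grid-search the box constraint
(`{0.1, 1, 10, 100}`) and kernel scale (`{0.5, 1, 2, 4}·√d`) on
validation AUROC with deterministic tie-breaks (smaller `C`, then
smaller scale), refit on train + validation with the selected values,
and compute test F1, sensitivity, specificity, AUROC and AUPRC. Reports
give mean (sd) over iterations, one row per privileged-information arm
(`none` = baseline SVM; `ts_ecg`, `sf_ecg`, `ehr` = SVM+).

Design choices worth stating:

* **Standardisation** is applied even though protocols of this kind
  often leave it unstated: Gaussian kernels on features with mixed
  units (mV-scale total variation next to counts in the tens of
  thousands) would otherwise be dominated by a handful of columns.
* **Refit on train + validation** after the grid search uses all
  non-test data for the final model; the selection itself never sees
  test rows (leakage is asserted by a test that perturbs test-set
  features and checks the selected hyperparameters do not move).
* Splits are redrawn deterministically until all three sets contain
  both classes — AUROC is undefined otherwise at these cohort sizes.
* A failed iteration aborts the run rather than being skipped, so
  reported means are never silently biased.
* γ and ν stay fixed during the grid search (only box constraint and
  kernel scale are searched); an extended grid can be passed
  explicitly.

# The synthetic cohort generator

The real cohorts this design targets are controlled-access, so the
package ships a generator that emulates their *structure*: 10-minute
240 Hz lead-II-like segments at `t0` and `t6`, EHR observations at the
five lookbacks plus `t6`, qSOFA-consistent anchoring (every instance
has qSOFA exactly 1 at `t0`), and labels that are always produced by
scoring the generated `t6` physiology through the labeling module —
never assigned directly. Default shapes mirror the two study cohorts
(106 instances with 59 positives; 453 with 144).

The ECG model is a Gaussian-bump QRS/T pulse train with beat-interval
jitter, 0.25 Hz baseline wander and white noise — a morphology-level
emulation, not a physiological ECG simulator. The class signal is
planted in beat-interval variability and noise amplitude (plausible
physiology: decompensation degrades heart-rate variability and signal
quality), scaled by `ecg_effect` and stronger in the `t6` window.
Patients carry individual lognormal factors (sd 0.35 for noise, 0.25
for jitter) so classes overlap realistically; without that spread any
nonzero effect would be trivially separable. Defaults chosen once:
`ecg_effect = ehr_effect = 0.3` (moderate separability, baseline ECG
AUROC around 0.65–0.75 at the default cohort size),
`pi_informativeness = 1` (the `t6` physiology defines the outcome, as
in the real task), `noise_sd = 0.05` mV.

What passing tests on this cohort do **not** show: performance on real
ECG (no arrhythmias, electrode artefacts, or nonstationary rhythms are
modelled), robustness to real missingness patterns, or the actual
clinical effect sizes — the generator's effects are knobs, not claims.
They do show that every pipeline stage is wired correctly, that the
solvers reach their optima, that the protocol is leakage-free and
deterministic, and that the end-to-end system recovers planted signal
(null configurations score near chance; strong configurations score
near 1).

# Problem sizes used in the shipped checks

The test suite and acceptance script run cohorts of between 24 and 200
patients with 3 to 20 iterations over the default 4×4 grid or reduced
3×3/2×2 grids — sizes chosen so the whole battery exercises the full
10-minute, 240 Hz pipeline end to end while staying comfortable on a
single CPU. The protocol itself defaults to 100 iterations.

# Interfaces

The package's interface is its functions (plus CSV writers
`write_ts_features_csv()` and `write_metrics_report()`); no shell entry
point is shipped, as every workflow here is an R analysis. A worked
example lives in the README; `scripts/acceptance.R` reruns the
pipeline's headline computations and writes them as JSON.

# Known limitations

* The shipped EHR ordinal thresholds are synthetic stand-ins.
* The ECG generator does not model arrhythmia, ectopy or electrode
  artefacts; the noise screen's detector is a heuristic.
* GCS is taken as recorded (never derived from sub-scores), and
  observation-to-lookback matching assumes one observation per offset.
* With `pi_informativeness < 1` the generated prevalence drifts from
  `positive_fraction` towards 0.5, by construction.
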