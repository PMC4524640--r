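---
title: "Forecasting seizures from chronic iEEG: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting seizures from chronic iEEG: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(preictal)
```

## The forecasting problem

Chronic ambulatory intracranial EEG devices record months of multichannel
field potentials from subjects with focal epilepsy. A seizure warning
system must decide, minute by minute, whether the brain is in a *preictal*
(seizure-prone) state. `preictal` implements one complete forecasting
pipeline and — just as importantly — the statistical machinery needed to
say whether its warnings beat chance:

1. band-limited inter-electrode correlation features (plus univariate
   power-in-band features for comparison) in one-minute bins;
2. epoch labeling: lead-seizure identification, preictal windows,
   interictal exclusion zones, gap and burn-in handling;
3. a class-weighted linear soft-margin SVM over the labeled bins;
4. an overlapping-window rule turning bin calls into warning intervals;
5. blocked five-fold cross-validation and evaluation against a
   time-matched Poisson chance predictor.

Because real chronic canine/human recordings cannot ship with a package,
a synthetic-data module generates recordings with *known* preictal
structure; validation is by recovery of injected structure and by the
statistical calibration of the full pipeline.

## Features

Signals are bandpass filtered into eleven contiguous, non-overlapping
bands from 0.61 to 184.1 Hz (`default_band_edges()`), using linear-phase
windowed-sinc FIR filters with a Bartlett–Hanning window. Frequencies
above 184.1 Hz are avoided: near-Nyquist content of a 400 Hz device is
dominated by sampling artifact, which also rules out ripple-band analysis.
The filter length defaults to about eight seconds of impulse response
(`8*fs + 1` taps). Year-scale offline analyses can afford vastly longer
filters; at the record lengths this package targets, the design contract
is functional, not a tap count: a pure tone at each band's center must
pass its own band with at least ten times the energy leaked into any
other band, which the shipped design satisfies and the tests assert.

For each physically adjacent within-strip contact pair (12 pairs on the
default 16-contact, four-strip bilateral montage) and each band, the
Pearson correlation coefficient is computed on consecutive one-second
blocks and the 60 block coefficients are summed per minute, giving
12 × 11 = 132 correlation features. Summing presupposes sub-minute
computation; the one-second block is a declared convention, configurable
through `block_len`. It is a compromise: blocks much shorter than the
lowest band's period estimate correlation poorly, while minute-long
blocks would average away transient synchrony. Per-block normalization
makes the features invariant to channel-wise amplitude rescaling.
Power-in-band features are the mean squared band-filtered signal per
channel per minute over five conventional bands (0.1–4, 8–12, 12–30,
30–70, 70–180 Hz — the list deliberately has no 4–8 Hz band and is
configurable). Bins overlapping segment boundaries or gaps are dropped,
not zero-padded.

## Labeling

All intervals are half-open `[start, end)` at one-minute resolution,
aligned to the recording start. The rules, with defaults:

* **Lead seizures** — a seizure counts for scoring only when preceded by
  at least 4 h (`lead_min_sep`) of *recorded*, seizure-free time.
  Recording gaps longer than 1 h (`gap_event_threshold`) are treated as
  potential unobserved seizures: they reset the clock. Shorter gaps merely
  do not count as recorded time. This is deliberately conservative with
  respect to seizures that may have occurred while the device was down.
* **Preictal** — 90 min (`preictal_len`) ending 5 min (`preictal_offset`)
  before each lead-seizure onset.
* **Excluded** — the first 70 days after implantation
  (`post_implant_excl`; post-surgical non-stationarity), ictal bins, bins
  without data, and everything within one week (`interictal_excl`) of any
  seizure or qualifying gap boundary that is not preictal. The exclusion
  is applied symmetrically on both sides; sidedness is configurable
  because the convention is genuinely open — symmetric is the stricter
  choice.
* **Interictal** — everything else. Non-lead seizures contribute no
  preictal windows but still exclude their neighborhoods: they are real
  seizures.

The three labels partition every bin; the tests assert the partition and
compare lead identification against a brute-force oracle.

## Classifier

A C-SVC with linear kernel (`e1071`, the R binding of libSVM) on z-scored
features, with class weights inversely proportional to class sample
counts. Standardization uses training-fold statistics only; it matters
because raw correlation sums and band powers differ by orders of
magnitude and would otherwise dominate a linear margin. The kernel
`gamma` is accepted and ignored (inert for a linear kernel); only the
cost is tuned, by grid search on the first contiguous 10% of the training
fold so no later (test-adjacent) time is touched. The fitted hyperplane
is stored explicitly as a weight vector and bias so that a dot-product
oracle can reproduce every prediction — a reproducibility contract the
tests enforce exactly. The optimizer's termination tolerance defaults to
0.01: bin decisions feed a 90-minute warning aggregation, so margin
precision beyond that cannot change the forecaster's output, and looser
termination materially speeds up fits on weakly separable data.

## Warnings

The number of preictal calls among the trailing `window_len` minutes
(equal to the preictal window) is evaluated at every bin; at or above an
integer threshold, a warning of length `window_len` starts at that bin.
"Exceeds a threshold" is implemented as `>=` so that
`threshold = window_len` remains attainable. The window is causal — a
prospective system cannot condition on future bins. Warnings re-arm while
the condition persists and merge when overlapping or abutting; whether
the original system re-armed or suppressed during an active warning is
unstated, so re-arming is the package's choice, isolated behind the
aggregation function. Warnings are truncated at gap starts; monitored
time bookkeeping lives in the evaluation layer.

## Evaluation and the chance predictor

* **Sensitivity**: fraction of lead-seizure onsets inside a warning.
* **TIW** (time in warning): warned fraction of monitored time
  (recording minus gaps minus burn-in) — the complement of specificity.
* **FP/day**: merged warnings containing no seizure onset per monitored
  day. **DWW**: complete 24 h blocks, anchored at recording start, that
  intersect no warning.
* **ROC/AUC**: the operating point is swept over the integer warning
  threshold; AUC is trapezoidal with (0,0) and (1,1) appended.
* **Threshold tuning**: the smallest threshold whose TIW does not exceed
  the 30% target — the point of maximum sensitivity under the TIW cap
  (TIW is non-increasing in the threshold, an asserted property). If no
  threshold attains the target, the minimum-TIW point is used and logged.

The significance benchmark is a chance forecaster issuing
`window_len`-minute warnings at Poisson times, rate-matched so that its
long-run TIW equals the algorithm's. Under that construction each lead
seizure is hit independently with probability `P = 1 − exp(−λW) = TIW`,
so the p-value is the binomial upper tail of the observed hit count. The
matched-rate identity `P = TIW` is forced by the construction, not an
approximation; the tests verify the analytic tail against a Monte-Carlo
simulation of the Poisson-triggered predictor itself. The benchmark
inherits the known limitation of Poisson nulls: real seizures cluster
beyond the 4-hour lead separation, and no clustering-aware null is
implemented.

Cross-validation is blocked: five contiguous equal-length time blocks,
each held out in turn, out-of-fold calls assembled in time order, and the
warning engine plus metrics run once on the assembled sequence. A fold
boundary bisecting a preictal window would leak: preictal bins whose
seizure onset lies in the test block are dropped from training.

## The synthetic-data generator

`generate_recording()` emulates the statistical regime the analysis
assumes, not seizure electrophysiology: background channels are
band-limited Gaussian noise with a per-strip shared component giving a
baseline inter-channel correlation of 0.2 — real adjacent contacts are
neither independent nor duplicated, and the correlation features need a
baseline that is neither 0 nor 1. Seizure onsets follow a homogeneous
Poisson process (default 2/day) thinned by a 4 h refractory interval,
matching the Poisson benchmark framing while respecting the lead
definition. Gaps have Poisson starts (0.5/day) and uniform 5–120 min
lengths, so some exceed the one-hour qualifying threshold and exercise
the gap rules; gaps never swallow a seizure onset or its signature
window. During a preictal signature window (default 90 min ending 5 min
before onset, aligned with the labeling convention) a common component
band-limited to the signature band is added to both contacts of each
designated pair, scaled by `signature_strength` — the single effect-size
dial, expressed as a fractional increase (0 = null; default 0.3, a
moderate, detectable change chosen once as a plausible effect size).

`generate_feature_level()` is the fast path: it emits the one-minute
feature matrix directly, drawing each correlation column Gaussian around
a column baseline (mean 15–35 summed correlation per minute, i.e. mean
per-block coefficients of 0.25–0.6) and shifting the signature columns'
mean by the same fractional `signature_strength` in preictal bins. Bin
noise is independent by default; `bin_ar` optionally makes it a
stationary AR(1) process, reflecting the slow minute-to-minute drift of
real synchrony features. Autocorrelation matters for one experiment in
particular: with independent bins, even a 30-minute training window
supplies enough effective samples to saturate the classifier, so the
training-window-length experiment is degenerate; with `bin_ar` around
0.8 the effective sample count per window shrinks by an order of
magnitude and short windows become genuinely data-poor. The two modes
agree qualitatively — features extracted from raw-signal mode show the
injected shift in the designated band and pair — and this agreement is
a tested invariant.

What the generator does **not** emulate: ictal waveform morphology,
diurnal rhythms and sleep–wake structure, battery-charging artifact,
seizure clustering, or slow non-stationarity. Passing tests therefore
demonstrate that the pipeline recovers the structure it is designed to
detect and that its statistics are calibrated — not that real canine or
human recordings carry such structure.

## Problem sizes used by the validation suites

Raw-signal synthesis is memory- and CPU-bound (`fs × duration ×
channels` doubles plus one filtering pass per band), so the package's
validation runs use hours-scale records at reduced sampling rate
(64–100 Hz, band edges scaled below Nyquist) for raw-signal checks, and
feature-level datasets for pipeline-statistics checks:

* type-I calibration: 100 null replicates of 36 h records at 3
  seizures/day with a 6-band bank (72 correlation columns); with few
  lead seizures per short record the discrete binomial null makes the
  pipeline conservative, so observed rejection rates sit at or below the
  nominal level;
* power: 20 replicates of 72 h records at 3 seizures/day, signature
  strength 0.3 (the generator default); band- and bilateral-pair
  recovery: 20 replicates of 48 h records at the same strength;
  window-length recovery: 20 replicates of 48 h records at strength 0.2
  with `bin_ar = 0.8`. Replicates must contain at least five lead
  seizures — the same eligibility rule chronic-recording studies apply
  to their subjects;
* the warning-engine and Poisson-null oracles run at the sizes stated in
  their tests (10^4-bin instances; 10^4-replicate Monte-Carlo cells).

The window-length experiment deserves a caveat. Its premise is that
training windows longer than the physiological signature dilute the
preictal class while shorter ones starve it of data. The dilution side
is robust in simulation: windows well beyond the injected 90 minutes
lose sensitivity. The starvation side is real at the classifier level
(held-out bin AUC drops markedly for 30-minute training windows under
autocorrelated noise) but is largely masked at the warning level,
because at a fixed time-in-warning budget shorter warning windows are
cheaper per false trigger. Consequently the sensitivity-vs-length curve
attains its maximum at the injected length but typically in a tie with
shorter windows rather than as a strict unimodal peak, and the shipped
validation asserts exactly that pair of properties (maximum attained
within one grid step of the injected length; strict loss beyond it).

Larger records, the full 11-band bank and 400 Hz sampling are supported
by configuration; the defaults of `sim_config()` describe the simulated
study conditions, and the reduced sizes above are the package's choices
for its shipped validation suites.

## Numerical choices and degenerate inputs

* Correlation of a zero-variance block is undefined; it contributes 0
  and logs a warning.
* Z-scoring passes constant columns through unscaled; training fails
  explicitly if *all* columns are constant, or if either class is empty
  (naming the labeling stage, where such failures originate).
* Cost-grid ties resolve to the smallest cost; threshold-tuning ties to
  the largest admissible TIW.
* `tiw = 0` with observed hits has a chance probability of zero and is
  handled explicitly.
* DWW counts only complete 24 h blocks.
* The seizure-count model and every other stochastic component run off a
  single integer seed; generators save and restore the global RNG state,
  so they are pure functions of their configuration.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(duration_hours = 72, seizure_rate = 3,
                  signature_strength = 0.5, seed = 42)
ds <- generate_feature_level(cfg)
lab_cfg <- labeling_config(post_implant_excl = 0, interictal_excl = 2)
res <- crossval_forecast(ds$features, ds$seizures, ds$gaps,
                         c(0, 72 * 3600), lab_cfg)
res
```

On this dataset the forecaster recovers all injected preictal windows
(sensitivity 1.0 at 30% TIW) with a chance-predictor p-value well below
0.05; with `signature_strength = 0` the same pipeline stays at chance.

## Known limitations

* The Poisson chance predictor ignores seizure clustering; significance
  against it is necessary, not sufficient, evidence of forecastability.
* The correlation estimator convention (one-second Pearson blocks,
  summed) is one defensible reading of per-minute synchrony binning;
  alternatives (overlapping blocks, Fisher-z averaging) are not
  implemented.
* Feature-level synthesis draws bins independently; real features are
  autocorrelated, which inflates the effective evidence per preictal
  window relative to real data.
* No HDF5 container support: signals travel as EDF (a minimal 16-bit
  writer/reader ships with the package), features and annotations as
  CSV/JSON.
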