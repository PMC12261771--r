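---
title: "Self-controlled shock prediction from ICU waveforms: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-controlled shock prediction from ICU waveforms: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Circulatory shock kills quickly, and intervention inside the first hour
changes outcomes. Most early-warning scores lean on laboratory values that
cannot be redrawn every hour. `shockcast` implements an alternative: predict
an impending shock event one hour ahead using only the four waveforms a
monitored ICU patient already produces continuously — arterial blood
pressure (ABP), electrocardiogram (ECG), respiration (RESP) and pulse
oximetry (SpO2).

Two ideas carry the design:

* **Self-controlled sampling.** The negative class is not other patients but
  the *same* patient at a shock-remote time. Each case contributes one
  30-minute *observation* window ending one hour before the event (the
  intervening hour is a prediction blackout) and one 30-minute *control*
  window separated from the event by a washout — at least 24 hours before
  the onset (scenario 1) or 7 days after it (scenario 2). Comparing a
  patient with their own baseline removes between-patient nuisance
  variation.
* **Physiology-guided feature engineering.** Instead of thousands of
  opaque descriptors, a fixed catalog of 299 named features spans the four
  modalities: 90 ABP features (nine beat-level hemodynamic parameters
  crossed with ten summary statistics), 89 heart-rate-variability indices,
  112 respiratory features (nine breath-cycle parameters crossed with the
  same ten statistics, plus 22 breath-to-breath variability indices) and 8
  SpO2 features.

## Event definition and labeling

A shock event is a hypotensive episode — beat-averaged mean arterial
pressure (MAP) at or below 65 mmHg sustained strictly longer than one
minute — coupled with a serum lactate of at least 2 mmol/L measured within
12 hours of the episode onset. Only the first qualifying event per patient
is used. The MAP series is built by detecting pulse onsets on the ABP
waveform, averaging the pressure over each beat, and interpolating to a
regular 1 Hz grid; episode detection is a run-length scan on that grid
(`NA` gaps break runs). Two boundary choices are deliberately exposed:

* the lactate comparison defaults to `>= 2` mmol/L (the headline
  definition) with `> 2` available via `lactate_op` for sensitivity
  analysis;
* "more than 1 minute" is strict: a run of exactly 60 one-second samples
  does not qualify, 61 does.

Cohort exclusions mirror routine practice for archived ICU waveforms:
patients missing any of the four channels, with less than 90 minutes of
pre-onset data, with more than 50% invalid samples in any used
window/channel, or with no feasible control window are excluded, each with
a logged reason. The missingness rule is applied per used window and
channel (the strictest defensible reading; a record-level reading would
pass almost anything because archived records contain long gaps between
monitored spells).

## Preprocessing

* **ECG** is band-passed 3–45 Hz with a zero-phase (forward–backward)
  Butterworth filter — zero phase because phase distortion would bias
  interval measurements. R peaks come from an amplitude-threshold local
  maximum detector with a 200 ms refractory period. R-R intervals outside
  the open interval (400, 1500) ms — heart rates above 150 or below 40
  bpm — are replaced by linear interpolation from valid neighbours; the
  operation is idempotent and leaves valid intervals bit-identical.
* **ABP** passes a signal-quality mask with a 0.5 s check window: a window
  is invalid if any sample leaves [20, 300] mmHg, the window is flat, or
  the slew rate exceeds 2500 mmHg/s. Beat onsets are slope-triggered local
  minima; beats with implausible durations (outside 0.3–2 s) are discarded
  as detector or gap artifacts.
* **RESP** cycles are found by prominence-gated alternating trough/peak
  detection with a 1.5 s minimum cycle.
* Interior gaps shorter than 2 s in any raw signal are bridged by linear
  interpolation before fiducial detection; longer gaps stay invalid.
* **Imputation.** Chained-equation imputation is applied to the
  *feature table*, not the raw waveforms: iterating conditional linear
  regressions over sample-level waveform values is ill-posed (millions of
  cells, no meaningful conditional model), whereas the per-sub-window
  feature table is exactly the kind of moderate-dimension numeric matrix
  the technique was designed for. The implementation initializes missing
  cells at column means and runs ten deterministic predictive-mean sweeps,
  each column regressed on its ten most-correlated peers; observed cells
  are never altered.

## The feature catalog

Every 30-minute window is tiled into five 10-minute sub-windows with a
5-minute hop; each sub-window is one row of the feature table. Fiducial
detection runs once per window and sub-windows subset the detected
beats/cycles by time.

The ten-statistic battery (minimum, mean, maximum, median, SD, skewness,
kurtosis, Hurst exponent, largest Lyapunov exponent, sample entropy) is
applied to nine ABP beat-parameter series — systolic and diastolic
pressure, pulse pressure, waveform-average pressure between adjacent
onsets (MeanAP), the formulaic MAP (DBP + PP/3, kept distinct from
MeanAP), heart rate, the systolic-peak-to-next-diastolic interval
(TimeSBP2DBP), and the absolute differences between consecutive systolic
(AmplitudeSBP) and diastolic (AmplitudeDBP) values — and to nine breath
cycle-parameter series (cycle amplitude, width = rise interval,
peak-to-peak and trough-to-trough intervals, peak amplitude, cycle rate,
respiratory volume per time, peak-trough amplitude symmetry, rise-decay
symmetry as the fraction of the period spent rising).

The 89-member HRV set and the 22-member breath-to-breath (RRV) set are
fixed, versioned lists (`shock_catalog()` is the single source of truth;
its per-modality cardinalities 90/89/112/8 are asserted in the test
suite). The HRV list covers time-domain deviation and difference measures
(SDNN, SDANN, RMSSD, pNN50, MCVNN, ...), Welch band powers (ULF, VLF, LF,
HF, VHF plus logs, ratios, normalized and relative powers and peak
frequencies), short-time Fourier and Haar-wavelet band summaries,
Poincaré geometry (SD1, SD2 and derived indices), heart-rate
fragmentation, and nonlinear measures (ApEn, SampEn, multiscale entropy
by scale, detrended fluctuation exponents, a multifractal singularity
peak, correlation dimension, Hurst, Lyapunov, Lempel-Ziv complexity,
central tendency measure and friends). The RRV set spans time-domain
statistics, LF/HF band powers via Burg, Welch and Lomb–Scargle spectra,
sample entropy, Poincaré widths, a wavelet LF/HF ratio and the
multifractal peak.

Frequency-domain caveat: ULF and SDANN are, strictly, ill-defined on a
10-minute segment; they are computed numerically on the sub-window (band
integration of the Welch spectrum; SD over 5-minute segment means) and
fall back to missing-markers where undefined, rather than silently
changing the window length.

### Complexity metrics

All nonlinear measures are implemented in the package (compiled kernels
for the quadratic-cost template counts) and cross-checked in the test
suite against independent brute-force oracles to 1e-9 on seeded series.
Conventions, all configurable through `metric_params()`:

* SampEn/ApEn: embedding `m = 2`, tolerance `r = 0.2` times the
  sub-window's own SD (scale invariance); multiscale entropy fixes `r`
  from the original series so scale 1 equals SampEn exactly.
* Lempel-Ziv: LZ76 phrase count of the median-binarized sequence,
  normalized by `n / log2(n)` — the median split is parameter-free.
* Central tendency measure: radius `0.1` SD by default.
* Hurst via rescaled-range regression, DFA-1 over a dyadic scale spread,
  correlation dimension via Grassberger–Procaccia, largest Lyapunov via
  the Rosenstein divergence slope (a declared convention — per-window
  "Lyapunov exponent" admits many estimators), multifractal DFA peak as
  the mode of the singularity spectrum.
* Degenerate inputs return documented constants (zero-variance: SampEn 0,
  CTM 1, Hurst/DFA 0.5, Lyapunov/CD 0) or `NA` missing-markers (too
  short), never exceptions, so one bad sub-window cannot abort a cohort
  extraction.
* The pairwise-template estimators (SampEn, ApEn, fuzzy entropy,
  Lyapunov, correlation dimension) operate on at most the first
  `max_len_embedding = 256` points of a series; beat series in a
  10-minute window run to ~800 beats, and capping the quadratic-cost
  estimators at a few hundred points is the usual accuracy/cost
  compromise for windowed monitoring features.

## Modeling

Features are ranked by a deterministic plug-in mutual-information
estimator (equal-frequency binning for continuous features, ties broken
by catalog order) against the window label, computed on training rows
only; the default selection keeps the top 65 (a sweep helper evaluates
k = 30..100 on the validation set). Patients — never rows — are shuffled
into 60/20/20 train/validation/test sets, so the five sub-window rows of
a window can never straddle sets.

The bench fits five seeded base learners: a depth-wise gradient-boosted
tree model (logistic objective, L2 regularization, maximum depth 6), a
leaf-wise histogram gradient-boosted tree model (31 leaves), a random
forest (100 trees, Gini), extremely randomized trees (100 trees) and an
L2-regularized logistic baseline. A weighted ensemble is built by greedy
forward selection with replacement over base-model probabilities,
maximizing validation AUC from the best single model, so its validation
AUC can never fall below the best base learner's; weights are nonnegative
and sum to one.

Evaluation reports accuracy, AUC, sensitivity and specificity at a 0.5
probability threshold (configurable), with 95% percentile bootstrap
intervals formed by resampling *patients* with replacement — rows of one
patient are correlated, so row-level resampling would understate the
intervals. Importance uses tree-SHAP contributions (mean absolute value)
for the boosted models and permutation importance otherwise; the additive
identity (contributions + bias = margin) is asserted in tests. Each
selected feature is finally re-examined by simple logistic regression and
by a multivariable model adjusted for age, sex, body-mass index and neck
and waist circumference, reporting odds ratios per unit with Wald 95%
intervals; quasi-separation is flagged, not silently dropped.

## The synthetic cohort

Credentialed clinical waveforms cannot ship with a package, so
`sim_config()`/`simulate_cohort()` generate the study conditions:

* Per-patient baselines are drawn once (systolic 120 ± 10, diastolic
  70 ± 6 mmHg, heart rate 80 ± 8 bpm, respiratory rate 16 ± 1.5 /min,
  SpO2 97 ± 0.8%); covariates (age, sex, BMI, neck, waist) come from
  plausible population distributions solely to exercise the adjusted
  regression.
* ABP is a beat train: half-cosine upstroke from the diastolic onset to
  the systolic peak, exponential-style decay to the next onset. The
  analytic waveform mean (DBP + 0.37 PP for the default morphology) lets
  the generator place the MAP trajectory exactly: baseline until a
  10-minute ramp inside the blackout, a switch to MAP 55 mmHg at the true
  onset sustained for five minutes, then recovery. The rule-triggering
  crossing therefore happens once, at the onset, and labeling recovers it
  to within one MAP sample.
* ECG is generated at the R-R level (AR(1) slow component plus white
  jitter) and rendered as a spike train — sufficient because every ECG
  feature in the catalog is R-R-derived. Respiration is an
  asymmetric-cosine cycle signal; SpO2 a clipped AR(1) percentage. All
  AR streams are initialized in their stationary regime (a burn-in would
  make early windows systematically calmer than late ones and break the
  self-controlled design's exchangeability).
* Lactate panels are sparse and irregular; shock patients receive one
  qualifying value (2.5–5 mmol/L) one to six hours after onset, others
  stay near 1 mmol/L.
* Records emulate segmented waveform archives: samples are rendered in an
  active region around the control window and a continuous peri-event
  region `[onset - 2 h, onset + 30 min)`, with invalid-masked spans in
  between and ~2% random short gaps inside active regions. This keeps a
  200-patient cohort tractable on one core without changing anything a
  window-level analysis sees. The generator hosts scenario-1 controls by
  default; scenario-2 geometry is exercised in tests on hand-built
  records because rendering 7-day spans buys no additional coverage.
* `shock_fraction` defaults to 1: the emulated cohort is the *included*
  population of a self-controlled design, in which every patient met the
  shock criteria. Lower fractions exist for null and detection tests.

### Injected pre-shock drift

The cohort-level ground truth is a set of physiological shifts active only
inside `[onset - 90 min, onset)`, targeting five headline feature
families with these directions: higher pNN50, higher TimeSBP2DBP sample
entropy, lower AmplitudeDBP median, lower breath width, lower respiratory
rate. Literature reports directions, not magnitudes, so the defaults are
the package's own choice, made once: R-R white jitter 12 to 35 ms,
systolic-timing white jitter 3 to 28 ms, diastolic beat jitter 2.5 to
1.0 mmHg, respiratory rate −3 /min, relative breath width −25%. They are
sized as *markedly* abnormal but physiologically plausible pre-shock
changes, large enough that recovery tests are informative rather than
coin flips.

Two implementation details matter for validity:

* The timing jitter that drives TimeSBP2DBP entropy is split into a
  smooth autocorrelated part (baseline) and a white part (drift target):
  sample entropy responds to *irregularity relative to the series' own
  scale*, so inflating an already-white jitter would barely move it.
* The width shift is parameterized relative to the baseline rise
  interval and applied on top of the rate change; a naive rise-fraction
  shift would be cancelled by the longer cycles the rate drop produces.

Drift is realized by switching generative parameters per beat/cycle at
the drift boundary inside one continuous peri-event stream: no phase
discontinuity enters the observation window, samples outside the window
are bit-identical under injection, and `inject_preshock_drift()` with a
zero effect vector reproduces the record exactly.

### What passing tests do and do not show

The generator produces clean, stationary-by-construction physiology with
known ground truth. Tests against it demonstrate that the pipeline's
machinery is correct: the labeling rule fires exactly where the MAP
trajectory says it should, injected effects of known direction are
recovered, a zero-drift cohort is classified at chance, and windows from
the same patient are exchangeable absent drift. They do not demonstrate
clinical performance: real ICU waveforms carry artifacts, arrhythmias,
therapy-driven non-stationarity and label noise that no fixed generator
reproduces, and reported headline metrics on real cohorts cannot be
reproduced from synthetic data.

## Numerical and design choices worth knowing

* Time is half-open everywhere: `[start, end)` in seconds from record
  start; sample `i` of a channel covers `[i/fs, (i+1)/fs)`. Channels keep
  native rates; nothing is globally resampled.
* Scenario preference when both controls fit: scenario 1 (it precedes any
  shock physiology); the control sits flush against the washout boundary
  for determinism. Patients with no feasible control are excluded — a
  self-controlled design needs a within-patient negative.
* pNN thresholds are compared with a 1e-6 ms slack: detector output is
  quantized to the sampling grid, and a strict comparison at a grid point
  would be decided by floating-point rounding of timestamps.
* The problem sizes used by the automated checks — two 200-patient
  cohorts for the discrimination and null criteria, 100-series oracle
  sweeps, 1000-case episode fuzzing — were chosen as the smallest sizes
  at which the binomial/Monte-Carlo error of each criterion is far from
  its decision boundary.
* Known limitations: single-lead spike-train ECG (no morphology beyond
  R peaks), no arrhythmia or ventilator simulation, no treatment-aware
  censoring, first event only, and a deliberately simple two-regime
  hemodynamic trajectory.
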