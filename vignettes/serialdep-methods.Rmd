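---
title: "Measuring serial dependence in orientation working memory: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring serial dependence in orientation working memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serialdep)
```

# The problem

In delayed-estimation working-memory tasks, the orientation a participant
reports is systematically biased by recently encountered orientations:
attracted toward the target they reported on the previous trial, and
sometimes repelled from another grating shown earlier in the same trial.
`serialdep` measures these biases twice over — in the reports themselves,
and in the multivariate neural representation of the current target while
it is being recalled — so that the two levels can be compared within the
same analysis framework.

# Conventions

Everything downstream depends on one set of circular conventions, fixed
once:

* Orientations live on the half-open interval **[0°, 180°)** (gratings are
  180°-periodic).
* Relative orientations are wrapped to **(−90°, 90°]**; the boundary case
  of exactly 90° maps to +90°. Positive differences are counterclockwise,
  negative clockwise.
* Time is in seconds, zero at the lock event; sample *i* covers the
  half-open interval `[times[i], times[i] + 1/sfreq)`.
* In every bias quantity, **positive = attraction toward the inducer**.
  This works out automatically: a clockwise inducer that attracts the
  representation shifts it clockwise, which is a positive asymmetry index,
  and the bias index is defined as clockwise-group minus
  counterclockwise-group asymmetry.

Missing values are explicit `NA`s; nothing is imputed.

# Behavioral serial-bias index

For a chosen inducer (previous-trial target, sample 1, or — as a control —
the participant's own report), each trial contributes its signed report
error and the inducer's relative orientation δ. The index is

mean(error | δ ∈ (0°, 45°]) − mean(error | δ ∈ [−45°, 0°)).

Two boundary decisions are deliberate. Trials with δ exactly 0 are
excluded from both sides: the two closed 45° intervals would otherwise
both claim them, and a δ = 0 trial carries no directional information
anyway. Trials at exactly ±45° belong to their side (half-open at zero
only). Either side being empty is an error naming the side, not a silent
`NA`.

The overlapping-bin smoother (`smoothBiasCurve`, 64 centers, each
averaging the 25 % of trials circularly closest to it) exists for
plotting only and never feeds inference.

**Stimulus-dependent bias correction.** Reports are also biased away from
cardinal and oblique axes regardless of history. Before report-sorted
analyses, a sum of three sinusoids of the target orientation is fitted to
each participant's errors and subtracted. Because "three sinusoids of
possibly varying frequency" is under-determined, the fit searches all
triples of integer harmonics (1–8 cycles per 180°) and solves each
candidate by closed-form least squares in the sine/cosine
parameterization, keeping the lowest residual sum of squares. This is
exhaustive on its grid, strictly deterministic (no starting values, no
convergence failures), and its RSS can never exceed the zero-model's.
With fewer than 7 usable trials the correction degrades to identity with
a warning.

# The decoder

At each time point the decoder works on a trailing window of
`windowSamples` samples ending at that point, concatenated across all
sensors (the default 37 samples corresponds to 148 ms at a 250 Hz
sampling rate; worked examples at 100 Hz use 15 samples ≈ 150 ms to keep
the same temporal extent). PCA retains the smallest number of components
reaching 90 % explained variance; the transform is reusable on held-out
rows.

Decoding is leave-one-trial-out. For each held-out trial, training trials
are binned by their orientation relative to the held-out trial's into ten
half-open 18° bins ([−90°, −72°), …, [72°, 90°], the top bin also taking
+90°), and the Mahalanobis distance from the held-out pattern to each
bin's mean pattern is computed. The ten distances are negated and
mean-centered, giving a tuning curve that sums to zero by construction.
If any bin is empty the trial's curve is marked missing at that time
point — never imputed.

Three design choices deserve explanation:

* **Doubled-angle cosine projection.** The decoding evidence weights each
  bin by cos(2·center). Orientation is 180°-periodic, so the natural
  angle for tuning arithmetic is the doubled angle; literal cosines of
  the bin centers would be all-positive weights that cannot distinguish
  tuned from flat curves (they would not even sum to zero). This is the
  central interpretive decision of the decoding module; with it, a
  perfect cos(2θ) tuning curve scores exactly 0.5 and its antiphase
  counterpart −0.5.

* **Covariance estimation.** The Mahalanobis metric uses a
  shrinkage-regularized covariance (off-diagonal shrinkage with the
  analytic intensity of Schäfer & Strimmer) — standard practice when the
  feature count approaches the trial count. By default one covariance is
  estimated per time point from the residuals of regressing the patterns
  on `[1, cos 2θ, sin 2θ]` across all trials, so it reflects noise rather
  than orientation signal; re-estimating it inside every leave-one-out
  fold changes it by O(1/n) while multiplying cost by n.
  `tuningCurveLoo(..., cov = "shrinkage")` provides the strict per-fold
  variant, and `covEstimator = "identity"` reduces the whole decoder to a
  Euclidean nearest-bin-mean rule, which is how it is validated against
  an independently written oracle (tolerance 1e-8; the distance itself is
  checked against direct quadratic-form evaluation at 1e-10).

* **PCA scope and window alignment.** The PCA is fitted once per time
  point on all trials jointly — faithful to the procedure the pipeline
  reimplements, though not leakage-free; `pcaFoldwise = TRUE` refits it
  inside every fold for users who want the conservative variant. The
  sliding window trails (ends at) the evaluated time point so that
  response-locked analyses never consume post-response samples.

Response locking re-epochs each trial so that zero is the moment the
report was completed, excluding trials with missing RTs or RTs outside
0.65–11.85 s (too little analyzable data at the epoch edges), with every
exclusion counted and reported. Variable per-trial windows (e.g.
probe-onset-to-rotation-start) average within each trial first, over
samples strictly before that trial's rotation-start time, then across
trials.

# Asymmetry and neural bias

The asymmetry index is the mean similarity in the three clockwise
flanking bins (centers −63°, −45°, −27°) minus the three counterclockwise
ones (+27°, +45°, +63°); the central pair is blind to small shifts and
the extreme pair is dominated by the wrap-around, so both are excluded by
default (configurable in `analysisConfig`, with validity checks enforcing
disjoint, mirror-symmetric bin sets). The index is exactly invariant to
adding a constant to the curve, so per-participant mean-centering for
display cannot change it.

Trials are sorted by the sign of the inducer's relative orientation;
exact 0° and ±90° cases are excluded with logged counts (the two closed
half-circles would otherwise double-count them). Asymmetries are averaged
within group per time point and then differenced — group-then-average,
not trial-wise differencing.

# Inference

`clusterPermutationTest` is a one-sample, two-tailed cluster-based
sign-flip permutation test: sample-level t statistics thresholded at the
two-tailed 5 % point, contiguous same-sign excursions summed into cluster
masses, and a max-|mass| null built by randomly flipping the sign of
whole participant time courses. The +1-corrected p-value
`(1 + #null ≥ observed) / (1 + nPerm)` can never be zero, and its floor
`1/(nPerm+1)` is part of the class validity. Sign-flipping (rather than
label shuffling) is the exchangeability argument for per-participant
differences against zero; paired designs enter as differences. Samples
with zero variance across participants get a clamped, effectively
infinite t (sign of the mean) rather than NaN. The default is 100,000
iterations; tests and desk-scale runs use 1,000–10,000, which changes
only the resolution of small p-values. Where cluster tests are
underpowered, windowed one-sample t-tests on participant means
(`windowTtest`) are the fallback.

# The synthetic-data generator

The generator exists so that every downstream stage has a ground truth.
It emulates:

* **Task structure.** The two-grating retro-cue design: 400 trials per
  participant — 200 with both gratings (100 cued to each), 100
  first-only, 100 second-only — randomly interleaved. The block count is
  not dictated by the design, so the generator uses 8 blocks of 50
  trials; previous-target links never cross block boundaries. The cued
  recall design: 2 sessions × 6 blocks × 84 trials (1,008), both
  gratings always shown, cue balanced within block. All orientations are
  i.i.d. uniform on [0°, 180°).

* **Reports.** Signed errors built additively from a
  derivative-of-Gaussian (DoG) kernel of the previous-target delta, a DoG
  of the sample-1 delta on sample-2-cued trials, a sinusoidal
  stimulus-dependent term, and circular Gaussian noise, plus occasional
  swap errors (reporting the uncued item). The DoG is parameterized as
  a·(δ/w)·exp(½ − δ²/2w²) so the amplitude *a* **is** the peak shift in
  degrees and the peak sits exactly at |δ| = w — interpretable recovery
  targets. Defaults (+2° attraction toward the previous target at
  w = 20°; −1.5° repulsion from sample 1 at w = 25°; 2° cardinal bias
  with 2 cycles/180°; 8° report noise; 2 % swaps; log-normal RTs around
  2 s) are of the magnitude routinely reported for this class of task.
  The rotation-start time is a uniform 0.3–0.7 fraction of the RT.

* **Epochs.** Each sensor has a preferred orientation; preferred
  orientations tile [0°, 180°). Within the signal window, sensor *s*
  carries gain·cos(2(θ_repr − φ_s)) plus noise (a `tuningWidth`
  parameter morphs this into a narrower von-Mises-shaped profile; the
  default 45° zero-crossing *is* the pure cosine). The represented
  orientation θ_repr equals the target plus any scheduled shifts, each
  applied along the sign of the inducer's relative orientation (positive
  shift = toward the inducer) and constant within its window with 50 ms
  cosine ramps to avoid step artifacts. Noise is Gaussian with an
  exponentially decaying spatial covariance over a planar sensor grid in
  the unit disc (correlation length 0.5 by default, so Mahalanobis
  whitening genuinely matters; a diagonal option exists for oracle
  tests) and AR(1) temporal correlation (0.7), normalized to a marginal
  s.d. of 1.5 against a tuning gain of 1 — an SNR at which
  single-participant decoding evidence is reliably positive, comparable
  to a clean recording.

What it does **not** emulate: biophysical forward models or realistic
sensor geometries (the grid stands in for a helmet array), artifacts
(blinks, cardiac), non-stationary noise, the visual transients of probes
and masks, or any generative cognitive model of *why* the biases arise.
Passing recovery tests therefore shows the estimator chain is correct and
well-calibrated under these idealized conditions — not that real
recordings will show the effects.

# Validation strategy and problem sizes

The test suite validates each stage against an independent route:
closed-form cases and brute-force oracles for distances, tuning curves,
indices and window averages; analytic values for the cosine projection;
null calibration (label-shuffled decoding unbiased at every time point
across 200 simulations; cluster-test family-wise error ≤ 7.5 % at
α = 0.05 across 200 null experiments of 20 participants × 40 samples with
1,000 permutations); and parameter recovery (±8° representational shifts
recovered with the correct sign in-window, null out-of-window and in the
report-sorted control, across 20 replicate experiments of 20 simulated
participants × 400 trials; 2° behavioral DoG attraction recovered within
a factor of two of its numerically integrated expectation). Recovery
simulations run at 100 Hz with 16 sensors and decode at a handful of
time points inside and outside the injection window — sizes chosen to
keep the full suite in the minutes range while leaving every estimator
at realistic trial counts.

# Known limitations

* The per-time-point pooled covariance and the all-trials PCA are shared
  with the procedure this package operationalizes, but both are mildly
  optimistic relative to strictly fold-wise variants; the switches exist,
  at a factor-n cost.
* The asymmetry index is a fixed contrast, not an estimate of the shift
  in degrees; its units are similarity differences. Parameter recovery
  tests check sign and reliability, not degree-scale calibration.
* `smoothBiasCurve` bins overlap by construction; adjacent points are
  strongly correlated and must not be treated as independent samples.
* The cluster test controls family-wise error across time within one
  analysis; nothing corrects across the many analyses a full study runs.
* Epoch containers use R-native serialization; they are not a
  cross-language interchange format.
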