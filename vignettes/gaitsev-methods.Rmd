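---
title: "Severity grading of parkinsonian gait from plantar VGRF: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Severity grading of parkinsonian gait from plantar VGRF: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitsev)
```

## The problem

Parkinson's disease alters gait in ways that plantar pressure sensors
capture directly: longer relative stance (high-pressure) phases, growing
left/right asymmetry, and larger cycle-to-cycle variability. Public gait
archives record vertical ground reaction force (VGRF) from 8 in-sole
sensors per foot at 100 Hz during roughly two-minute walks, together with
two per-foot total-force channels (18 channels in all) and a Hoehn–Yahr
(H&Y) stage per subject. `gaitsev` grades walks into four classes —
Healthy, stage 2, stage 2.5, stage 3 — and, because labelled cohorts of
this kind are small, puts its emphasis on *data augmentation*: seven
label-preserving stochastic transforms plus a linear-prediction-residual
(LPR) preprocessing family, evaluated under subject-independent
cross-validation with two small sequence classifiers.

## Data model and loading

A `walk_record` is a T×18 force matrix (newtons; columns `L1..L8`,
`R1..R8`, `TotalL`, `TotalR`) with a 100 Hz time vector and subject
metadata. Loader invariants: strictly increasing time at 0.01 s ± 1e-6,
and totals equal to the sum of their 8 sensors. The totals check is a
**warning**, not an error (tolerance 1 N by default): real archive files
print rounded values. Stages outside {healthy, 2, 2.5, 3} are retained at
load but flagged unknown and excluded from the four-class task. Records
shorter than one 100-step window are kept at load and dropped only at
segmentation, with a message. The time column is used for validation
only; all downstream indexing is sample-based.

## The synthetic cohort generator

Every downstream stage is testable without any download because
`simulate_cohort()` generates labelled cohorts with exactly the
statistical structure the classifiers exploit. Each foot produces
quasi-periodic stance bursts (cadence 1 stride/s, feet in antiphase);
each burst is a double-peak "M" profile built from two overlapping
raised-cosine lobes (heel-strike and toe-off peaks at 25% and 75% of
stance, width 0.35 of stance) scaled by a per-sensor amplitude profile.
Severity acts on exactly three knobs, so class-recovery tests stay
interpretable:

* `stance_fraction` (0.55, 0.64, 0.73, 0.82 by class) — the fraction of
  the stride spent loaded, strictly increasing with severity (the
  longer-high-pressure-duration signature);
* `asymmetry` (1.00, 0.92, 0.84, 0.76) — right/left amplitude ratio;
* `cycle_jitter_sd` (5, 15, 25, 35 ms) — stance-onset timing noise,
  non-decreasing with severity.

Gaussian sensor noise (SD 3 N) is added to the 16 sensor channels and
clipped at zero *before* the totals are computed, so `TotalL`/`TotalR`
remain exact sums. Per-subject random effects (log-amplitude SD 0.08,
stance-fraction SD 0.012) are drawn once per subject, making a subject's
walks correlated — the property that subject-independent validation is
designed to respect. The defaults were chosen once to give a clear but
not trivial class separation at two-minute walks; tests use shorter walks
only to bound runtime. A planted-signal mode (`informative_sensors`)
restricts all class-dependent knobs to chosen sensor indices while the
stride schedule and remaining sensors follow healthy parameters; it
exists to validate the sensor-ablation ranking against a known ground
truth.

What the generator does **not** emulate: biomechanical coupling between
sensors, freezing-of-gait episodes, drift, dual-task effects, or realistic
between-subject covariate structure. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the class structure it
is pointed at — not clinical performance on real recordings.

## Augmentation operators

Seven composable operators act on full-length T×18 walks, before
windowing (defaults in parentheses):

* **jitter** — i.i.d. Gaussian noise, mean 0, `sigma` (2 N) per element;
* **scale** — one multiplicative factor per **channel**, N(1, 0.1²). The
  alternative reading "one factor per time step" would be
  indistinguishable from magnitude warping with white noise, so the
  per-channel interpretation is adopted and documented;
* **rotate** — consecutive channel triples form feature groups; each
  triple's time-mean vector, normalised, is the rotation axis; a uniform
  angle in (−π, π] and Rodrigues' formula give the rotation. Per-sample
  triple norms are preserved. A zero-mean group falls back to a fixed
  unit axis with a warning;
* **magnitude_warp** — per channel, a cubic spline through `knot + 2 = 6`
  control values ~ N(1, sigma²) (sigma 0.2) multiplies the signal;
* **permute** — the walk is cut into `n_perm = 4` contiguous blocks, each
  at least `min_seg_length = 100` samples, and the blocks are shuffled;
  all channels share one block order. Because the minimum block length
  equals the window length, permutation is only defined on full walks —
  one reason augmentation precedes windowing;
* **time_warp** — per channel, a spline rate curve through 6 control
  values ~ N(1, 0.2²), clipped below at 1e-3 (guaranteeing a strictly
  increasing warped axis), cumulated, rescaled to span the original
  support, and used to re-interpolate the signal;
* **random_sample** — per channel, `n_sample` (1000) sorted random
  indices with forced endpoints; linear re-interpolation back onto the
  full grid. Linear ramps are reproduced exactly.

`aug_compose()` applies any ordered subset reproducibly. In
cross-validation, augmented copies are **appended to** (never substituted
for) the training walks, and validation walks are never augmented —
augmentation is a training-set property, and the comparisons between
recipes must hold the validation data fixed.

## Linear-prediction residuals

Per channel: centered moving-average smoothing (window 3), min–max
normalization to [0, 1] (constant channels map to zero), keep-every-k-th
decimation at rate 1, 2 or 4 (tags `lp_100`, `lp_50`, `lp_25` for the
effective 100/50/25 Hz series), then an order-`p` linear predictor
`x(n) ≈ Σ a_k x(n−k)` fitted by least squares per channel per walk, whose
residual replaces the signal. The smoothing window and normalization
flavour are package choices (the upstream description names only "mean
filtering" and "normalization"); so is the predictor order `p = 10`,
which no table fixes — the three published variants differ in decimation
rate, not order, so the rate is the exposed axis. Warmup samples are
zero-filled rather than dropped to preserve alignment for windowing.
Rank-deficient designs (constant or zero channels) fall back to a ridge
solve with a warning. The estimator is verified against a
normal-equations oracle and recovers noise-free AR coefficients to 1e-6.

## Windowing, folds, majority voting

Walks are segmented into 100-step windows with 50% overlap (stride 50);
the count obeys `floor((T − 100)/50) + 1` for T ≥ 100, verified against
brute-force enumeration. Folds are built at the **subject** level:
controls and PD subjects are shuffled separately and split into k
near-equal chunks, so each validation fold holds ≈ 1/k of each group and
every record of a subject stays on one side. Leakage is asserted
programmatically on every training call. A walk's class is the majority
vote over its segment predictions; ties break to the **lowest class
index** — a deterministic rule that under-calls severity, which is the
conservative direction clinically. Walk-level voting is the reporting
unit (the segmenting is defined per walk); subject-level aggregation can
be layered on by the caller.

## The classifiers

Both models are implemented in the package itself (vectorized R with the
convolution inner loops in C++), with analytic gradients checked against
finite differences in the test suite.

**Per-channel 1D ConvNet.** Each of the 18 channels passes through its
own branch — conv(8 filters, kernel 3) → conv(16, 3) → maxpool 2 →
conv(16, 3) → conv(1, 3) → maxpool 2 → flatten → dense(50) — with SELU
activations throughout (λ ≈ 1.05070, α ≈ 1.67326); the 18 embeddings are
concatenated and fused by dense(100) → dense(20) with dropout 0.1 after
each, then a 4-class softmax. Branches default to separate weights (a
shared-weights switch exists). Default learning rate 0.01 and batch 200.

**Time–spatial transformer.** Each channel's 100 samples are embedded to
`d_model = 16` and passed through a shared time-encoder block: layer-norm
→ 2-head self-attention (key dim 100) → dropout 0.3 → residual →
layer-norm → position-wise feed-forward (width 2×`d_model`) → residual.
Temporal mean pooling gives one embedding per channel; the 18 embeddings
plus a sinusoidal positional encoding on the *sensor index* enter an
identical spatial encoder block. Mean pooling over the 18 tokens (rather
than flattening) feeds two dense layers and the softmax: with positional
encoding off the whole classifier is then exactly invariant to sensor
order, which makes the role of the positional encoding testable as a
contract rather than a tendency.

**Training.** Nadam (β₁ = 0.9, β₂ = 0.999) on categorical cross-entropy;
early stopping monitors validation loss with `min_delta = 1e-4` and
patience 10 by default, restoring best-epoch weights; everything is
seeded, and NaN loss aborts with a diagnostic. Two learning rates
circulate for the ConvNet in its source material (0.0002 as a training
detail, 0.01 in the architecture grid); the package keys the model config
to 0.01 and leaves 0.0002 available via `train_config(learning_rate=)`.
Inputs are z-scored per channel with statistics fitted on the training
batch and stored on the model — raw newton-scale inputs are otherwise
poorly conditioned at these learning rates. Class weighting is off by
default, with inverse-frequency weights available behind a flag.

## Evaluation harness

`classification_metrics()` computes one-vs-rest TP/FP/FN/TN per class,
precision, recall, F1 and accuracy, with zero-denominator metrics defined
as 0 (warned). `cross_validate()` reports majority-voted walk-level
metrics (segment-level counts are attached for transparency).
`compare_augmentations()` evaluates recipes under bit-identical fold
manifests — asserted via a manifest hash — so recipe differences are
never confounded with fold differences. The augmentation-effect t-test is
Welch's unequal-variance test on per-walk correctness indicators pooled
over folds (the sample unit is a package choice; per-fold accuracies can
be passed instead); identical constant samples return p = 1, and no
multiple-testing correction is applied across recipes by default.
`sensor_ablation()` drops symmetric sensor pairs (18 → 16 channels),
reruns the CV, and ranks pair importance by ascending accuracy.

## Problem sizes used in validation

The shipped validation suite runs on deliberately scaled-down cohorts,
chosen as the smallest sizes at which each property is informative: class
recovery uses 10 subjects per class with 20 s walks and 3 folds
(≥ 90% majority-vote accuracy expected under the default separation); the
augmentation-benefit comparison subsamples training walks to 20%
(stratified, ≥ 1 walk per class) and averages 5 seeds over 2 folds; the
ablation check uses 5 subjects per class, 12 s walks, a planted signal on
sensor pair 2, and 2 folds. Short training schedules (6–15 epochs with
early stopping) suffice at these separations. Headline accuracies
published for the real archive (~90% at 10-fold scale) are not
reproducible from synthetic desk-scale runs and are not asserted.

## Numerical and design notes

* Decimation is plain keep-every-k-th subsampling by construction (no
  anti-alias filter): the published variants are defined by their
  extraction factor, and the smoothing step precedes it.
* Tie-breaks, warmup zero-filling, rate-curve clipping (1e-3) and the
  dropout placement (after each fusion dense layer) are documented above
  rather than left implicit.
* The rotation operator's feature groups are consecutive triples; nothing
  in the source fixes the grouping, and triples are the standard choice
  for tri-axial sensor augmentation. Whole-18-dim rotation was rejected
  as physically meaningless for this channel layout.
* Determinism: single-threaded by default; identical seeds give
  bit-identical training histories, fold manifests and reports.

## Known limitations

Synthetic validation bounds what the green suite proves about real data
(see the generator section). The transformer is substantially more
expensive per epoch than the ConvNet at its published key dimension and
is exercised at reduced width in the routine suite. UPDRS-style
regression scoring, GAN-based augmentation and frequency-domain
augmentation are out of scope.
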