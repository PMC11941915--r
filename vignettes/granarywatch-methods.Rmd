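---
title: "Methods: models, simulator, and design choices in granarywatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, simulator, and design choices in granarywatch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the models and
their assumptions, what the synthetic granary emulates (and does not), the
numerical choices, and the places where the design was genuinely open. It
states no empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## 1. The monitored object and its data model

A flat grain warehouse holds an `M x N x H` lattice of temperature sensors
(x, y horizontal; z vertical with `z = H` the pile surface). The raw record
is long-format: one row per `(date, x, y, z)` with a temperature in degC,
plus an irregular grain-moisture track (percent, sampled manually and
forward-filled between samplings) and the grain variety. Internally a day is
a `temperature_grid` (values + missing-value mask) and a granary is a
`granary_series`. File coordinates are 1-based to match sensor identifiers;
internal array indexing is R's native 1-based as well, so no translation
layer is needed beyond the x-fastest memory layout used by the compute
kernels.

## 2. Preprocessing chain

Order is fixed: **clean → impute → resize → standardize**; each stage's
output satisfies the next stage's preconditions.

* **Cleaning.** Sensor firmware emits exact sentinel values on failure
  (default 888, -85, 85 degC, matched after rounding to 0.1 degC since the
  codes are exact), plus a physical-plausibility range [-40, 60] degC. A
  second pass removes pooled Z-score outliers: `Z = (X - mu) / sigma` with
  `mu`, `sigma` the mean and *population* standard deviation over all
  surviving values of the series, removing `|Z| > 3`. Choices made here:
  sigma is population (the convention the toy standardization example
  forces); pooling is within one series (cross-granary pooling would let one
  hot granary mask another's outliers); the Z pass runs once, not
  iteratively. With `sigma = 0` (constant series) no Z-removals occur and
  the report flags degenerate dispersion. Cleaning is idempotent only in the
  practically relevant regime (the second pass finds nothing new on typical
  data); the test suite checks the property on representative series.
* **Imputation.** A missing voxel-day takes the unweighted mean of the
  nearest previous and next observation of that voxel (leading/trailing gaps
  copy the single nearest value). This is deliberately *not* linear
  interpolation — the convention is the simple adjacent-mean rule, and the
  tests pin the distinction (`[10, NA, NA, 22] -> 16, 16`).
* **Resizing.** Separable interpolation per axis on a normalized [0, 1]
  lattice onto the unified `10 x 6 x 4` model grid: natural cubic splines
  where the axis has >= 4 samples, linear for 2-3. Because interpolation is
  linear in the data, the per-axis operators are precomputed as matrices
  (built once by evaluating the spline on unit basis vectors and cached), which
  makes resizing exact for constants, exactly commuting with adding a
  constant, and fast.
* **Standardization.** Global per channel (not per voxel): the classifier
  must compare absolute temperature patterns across granaries. Statistics
  come from the *training partition only* and are stored with each model;
  `classify()` and `forecast()` reapply them. For this reason the dataset
  builders return raw-degC grids and standardization happens inside
  training — a deliberate deviation from treating standardized grids as the
  sample type, since dataset construction precedes the split.

## 3. Synthetic granary

The simulator is a stated world, not a tuning dial; its defaults were fixed
once, before any model experiment:

* **Heat transport**: each voxel moves a fraction `diffusivity = 0.35` per
  day toward the mean of its 6-neighborhood, with out-of-domain neighbors
  replaced by ambient. This is a discrete relaxation, not a PDE solver —
  adequate for daily-resolution signatures, and it produces the two features
  that matter: boundary voxels track ambient, interior voxels lag with depth
  (about 19 days at the bottom layer under the default geometry).
* **Forcing**: `A(t) = 7 - 16 cos(2 pi t / 365) + N(0, 1)` degC — series
  start at the midwinter trough (the natural start for storage campaigns),
  annual amplitude 16 degC as in a temperate continental storage region.
  With these choices a default 540-day pile has pooled mean ~5 degC, sd
  ~9.7 degC, |skewness| < 0.2 and excess kurtosis ~ -1.4, i.e. the same
  regime as published granary statistics (mean 7.27, sd 11.41, skewness
  0.17, kurtosis -0.98). The cosine phase matters: a sine-phase 540-day
  window cuts the seasonal cycle asymmetrically and shifts the pooled mean
  by ~+3 degC.
* **Observation model**: sensor noise sd 0.2 degC, sentinel error codes at
  rate 1e-3, dropouts at 1e-2.
* **Moisture**: slow AR(1) around a variety mean (wheat 12.5 %, corn 14 %),
  recorded weekly; mildew events nudge it upward.

**Event injectors** encode one defining, label-recoverable inequality each:

| state | signature | defining check |
| --- | --- | --- |
| mildew | localized exothermic ramp `(onset + rate*t) * exp(-d^2 / 2 r(t)^2)`, onset 2 degC, rate 1 degC/day, growing radius | center excess >= rate per day |
| condensation | core boosted / surface depressed until the extra core-minus-surface gradient reaches `gradient` (default 14 degC); the injector adds `max(0, -baseline)` so the target is met regardless of season | max core-surface gap >= gradient |
| aeration | rising ventilation cooling front: layers below the front sit near `ambient - chill` (chill 4 degC), the front climbs but never covers the surface; mild pile-wide pull elsewhere | cold-bottom two-zone profile |
| new_grain | +6 degC step in the upper half layers | top-bottom step |
| empty | all voxels = ambient + N(0, 0.2) | spatial sd < 0.5 degC |

Two injector choices deviate from the most literal reading of their
descriptions and are worth recording. A *pull-toward-ambient-only* aeration
converges to a spatially flat grid — byte-for-byte the `empty` signature —
making the two states indistinguishable from a single grid; the cooling
front is the standard physical picture of duct aeration and keeps the
classes separable. And mildew events in the classification dataset last 10
days (other states 30): a 30-day ramp at 1 degC/day ends at +30 degC, which
is not a mildew observation but a smoldering pile, and those extreme grids
dominate any class summary.

**What a green test does and does not establish.** The synthetic world has
exactly one anomaly per series, noise-limited flat fields for `empty`, and
event signatures that are by construction recoverable from a single grid.
Passing the synthetic recovery criteria shows the pipeline is implemented
correctly and has adequate capacity — it does not certify field accuracy on
operational granaries, where states co-occur, sensors fail in correlated
ways, and signatures are weaker.

## 4. Absolute water potential

`E_jg = 8.31 (T_g + 273) ln(exp(u) * 133.3) / 18` with
`u = (D^2/22 (e^{(B1-M)/A1} - e^{(B2-M)/A2}) + 0.9854)(1737.1 -
474242/(273+T_g)) + D (1 - e^{(B1-M)/A1}) - 68.578/7.72`.

The published typesetting of this expression is ambiguous ("D222",
"474242273+Tg", "68.5787.72"); the grouping above is this package's
documented reconstruction, isolated in `awp_inner()` so an alternative can
be swapped without touching callers. The outer logarithm is composed as
`u + ln 133.3`, which is exact and cannot overflow. The per-variety
coefficient sets shipped are **synthetic placeholders** (the original fits
are not publicly printed): chosen so the feature is finite, smooth and
strictly increasing in temperature over the storage range — the properties
the tests assert, via a frozen 50-digit independent evaluation and a
monotonicity scan, never via magic constants. Supply fitted coefficients for
production use; units follow the conventional kJ/kg label without
dimensional reconciliation.

## 5. The networks and their numerics

Both models run on an in-package neural core: explicit forward/backward
passes over BLAS matrices, Adam, and compiled im2col 3D-convolution kernels.
Every layer's gradient is checked against central finite differences in the
test suite, and the production convolution/LSTM are checked against
brute-force reference implementations (`conv3d_reference`,
`lstm_cell_reference`).

* **Classifier** (3D DenseNet): stem 3x3x3 conv (32 channels) → 3 dense
  blocks of 4 BN-ReLU-conv layers, growth 32 (growth defaults to
  `base_channels`; the tuned table names no growth rate) → transitions with
  1x1x1 conv (compression 0.5) + 2x2x2 average pooling (ceil mode:
  10x6x4 → 5x3x2 → 3x2x1) → BN-ReLU → global average pool → dropout 0.3 →
  softmax-6. Training: Adam lr 1e-3, batch 64, weighted cross-entropy,
  stratified 70/15/15 split (stratification protects the rare-class test
  cells), early stopping on validation loss (patience 10, max 200 epochs by
  default) with best-weight restore. The restore snapshot includes the
  BatchNorm *running statistics* — restoring weights without their matching
  running stats skews evaluation, which the test suite guards.
* **Forecaster** (3DCNN-LSTM): per-frame conv (16 kernels 3x3x3, padding
  preserves dims) → 2x2x2 max-pool → flatten → FC embedding 256 → 3-layer
  LSTM hidden 128, dropout 0.5 between layers → FC head mapping the final
  hidden state to all `P x 240` values at once (direct multi-step, not
  autoregressive). The head is *residual on a persistence-plus-drift
  anchor*: horizon day p is `last_frame + p * drift + correction`, with the
  per-voxel drift measured over the last `trend_window = 10` input days and
  the head (initialized near zero) supplying the learned correction. This
  is the standard drift-baseline decomposition from the forecasting
  literature: the network starts at a sane baseline and spends its capacity
  on what the baseline gets wrong, which matters at single-CPU training
  budgets — an unanchored head must first learn the absolute temperature
  field and converges orders of magnitude more slowly. The anchor also
  extrapolates local event ramps (mildew heating) that the learned part
  alone systematically under-predicts. Loss is MSE on standardized targets; windows are
  chronological per series (70/15/15 at day boundaries; windows whose target
  days cross a boundary stay unassigned, so no test target day can appear in
  a training input — asserted by date-set intersection in the tests). The
  single-channel variant (`channels = 1`) is the ablation configuration.
* **GAN** (per minority state): generator FC → 5x3x2 map → nearest-neighbor
  x2 upsample → three conv stages → 10x6x4; an exact chain of strided
  transpose convolutions cannot reach 10x6x4 from an integer seed resolution
  without cropping, so upsample+conv stands in for each
  transpose-conv/upsampling stage. Discriminator: two conv layers with
  ReLU/dropout/max-pool, FC, sigmoid. Non-saturating adversarial loss, Adam
  with beta1 = 0.5. GAN training operates on standardized grids and
  generated samples are destandardized on the way out.
* **Precision.** The fused convolution kernels dispatch on workload: below
  1e7 multiply-adds (every oracle and gradient-check instance) they run in
  exact double precision; above (training scale) in single precision, whose
  ~1e-7 relative rounding is far below the 0.2 degC sensor noise and which
  roughly doubles single-CPU throughput. Everything outside the convolutions
  is double precision.
* **Determinism.** Every stochastic stage takes a seed; sub-seeds derive by
  a fixed affine map mod 2^31 - 1. Same seed, same platform → bit-identical
  training histories (asserted in the tests).

## 6. Risk-alert chain

`run_alert()` forecasts `P = 10` grids, classifies each, and alerts on the
first day classified `condensation` or `mildew` — operational states
(aeration, new grain, empty) are reported but never alerted, since a warning
system that pages the operator for the operator's own fan schedule is
useless. Lead time is counted from the forecast issue date (the last
observed day): horizon day k has lead time k. When a ground-truth event date
is known downstream scoring uses it; the convention "alert before the event
date" is evaluated strictly.

Hotspot localization is a package addition (operators otherwise localize by
inspecting cloud maps): mildew hotspots are voxels whose predicted warming
over the horizon exceeds 0.5 degC/day; condensation hotspots are surface
voxels more than 8 degC below the predicted core mean. Raising either
threshold can only shrink the voxel set (asserted as a monotonicity
property).

## 7. Scaling of the acceptance experiments

The acceptance criteria fix dataset sizes (600 training samples per class;
35-day windows; 5 seeded alert runs) and thresholds (accuracy >= 0.90,
recall >= 0.75, MAE <= 0.5 degC, 4/5 alerts). On one CPU the full suite
must also fit a 25-minute budget, so the *epoch counts* are scaled down:
classifier 2 epochs (the synthetic classes are strongly separable and
training converges within the first epoch), forecaster <= 8 epochs, and the
alert experiment shares one trained classifier/forecaster pair across its
five seeded event runs. Dataset sizes, seeds and thresholds are exactly as
stated; nothing was tuned after observing a failing threshold.

## 8. Known limitations

* The simulator has no humidity field, no CFD, no microbial growth model;
  condensation/mildew are temperature signatures only.
* The water-potential coefficients are placeholders; absolute `E_jg` values
  are not physically calibrated (the feature enters the forecaster after
  standardization, so only its shape matters in-package).
* The forecaster is direct multi-step; it cannot be rolled forward beyond
  `P` days without retraining.
* Real granaries exhibit correlated sensor failures (whole cables dropping
  out); the simulator's dropouts are independent.
* The GAN is a capacity-limited sample synthesizer; no fidelity metric is
  computed, and `rebalance()` prefers flips, filling only the remainder
  with GAN output.
* The pooled `|Z| > 3` outlier filter cannot distinguish sensor faults from
  genuine extremes: a mature mildew hotspot more than three pooled standard
  deviations above the series mean is removed and imputed away, capping the
  anomaly signal that reaches the classifier. This is inherent to
  Z-score cleaning; operationally it argues for alerting *before* hotspots
  reach that magnitude, which is exactly the forecasting chain's purpose.
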