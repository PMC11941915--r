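# granarywatch

Monitoring bulk-grain storage from 3D granary temperature grids: storage-state
classification, temperature-field forecasting, and early warning of
condensation and mildew risk.

## The problem

Flat grain warehouses are instrumented with temperature-sensing cables that
form an `M x N x H` lattice of sensors inside the grain pile, read daily.
Operators traditionally judge the state of the pile by eyeballing temperature
cloud maps. Two things go wrong with that: current anomalies (mildew hotspots,
"cold skin, hot core" condensation gradients, unlogged grain movements) are
noticed late, and nothing anticipates risks that are still days away.

`granarywatch` implements an integrated pipeline for both tasks:

1. **Storage-state classification.** Each day's 3D grid — cleaned, imputed,
   spline-resized to a unified `10 x 6 x 4` lattice and standardized — is
   classified by a compact **3D DenseNet** (initial 3x3x3 convolution, dense
   blocks with concatenative skip connections, 1x1x1 compressing transitions
   with average pooling, global average pooling, softmax over six states:
   `normal`, `empty`, `aeration`, `new_grain`, `condensation`, `mildew`).
   Class imbalance is handled by axis-flip augmentation (x4), a small 3D GAN
   per minority state, and weighted cross-entropy
   `w_c = N / (6 n_c)` (normalized to mean 1).
2. **Temperature-field forecasting.** A sliding window of `T = 35` daily
   grids with two channels — temperature and **absolute water potential**
   `E_jg(T_g, M)` (a thermodynamic feature of grain temperature, moisture
   content `M` and variety-specific sorption coefficients) — feeds a
   **3DCNN-LSTM**: per-frame 3D convolution + max-pooling + fully connected
   embedding, a 3-layer LSTM (hidden 128), and a linear head emitting all
   `P = 10` future grids in one shot.
3. **Risk alert.** Forecast grids are pushed through the classifier; the
   first horizon day classified `condensation` or `mildew` raises an alert
   with its lead time and a hotspot voxel list (warming-rate rule for
   mildew, surface-deficit rule for condensation).

Because operational granary data are proprietary, the package ships a
**granary simulator**: a daily heat-relaxation pile driven by seasonal
ambient forcing, with sensor noise, sentinel error codes (888 / -85 / 85),
dropouts, and injectable state events. Every model in the package trains
and tests against it; all tests and the acceptance report are fully
self-contained.

## Worked example

```r
library(granarywatch)

# simulate 200 days of a 12x8x6 granary and inject a mildew event
cfg <- sim_config(n_days = 200, seed = 7)
ser <- simulate_series(cfg)
inj <- inject_state(ser, event_spec("mildew", start_day = 170, duration = 20,
                                    center = c(6, 4, 3)))

# preprocessing chain: error codes / Z-score outliers -> impute -> resize
pp <- preprocess_series(inj$series)
series_dims(pp)
#> [1] 10  6  4

# classify today's grid with a trained model (see vignette for training)
samp <- build_classification_dataset(
  c(normal = 60, empty = 60, aeration = 60, new_grain = 60,
    condensation = 60, mildew = 60), seed = 1)
fit <- train_classifier(samp, densenet_config(max_epochs = 2, seed = 1))
classify(fit$model, pp$grids[[165]])$state   # five days before the event
#> [1] "normal"
classify(fit$model, pp$grids[[180]])$state   # day 11 of the event
#> [1] "mildew"
```

The printed state is the argmax of the six-way softmax; `classify()` also
returns the full probability vector. The early-warning chain
(`run_alert()`) does the same on *forecast* grids and reports
`alert_day`, `lead_time_days` and the hotspot voxels (1-based sensor
coordinates, z = H is the pile surface).

## Package layout

| area | contents |
| --- | --- |
| `grid_core` | `temperature_grid`, `granary_series`, CSV/JSON readers and writers, `summarize_dataset` |
| `granary_sim` | `sim_config`, `simulate_series`, `event_spec`, `inject_state`, dataset builders |
| `preprocess` | `clean_series` (sentinels + pooled Z-score), `impute_missing`, `resize_spline`, standardization |
| `water_potential` | `awp`, `awp_field`, `grain_coefficients` (placeholder sorption sets) |
| `augment` | `flip_augment`, `train_gan`, `gan_generate`, `rebalance` |
| `state_classifier` | `densenet_config`, `build_classifier`, `split_dataset`, `class_weights`, `train_classifier`, `classify` |
| `temp_forecaster` | `forecast_config`, `make_windows`, `build_forecaster`, `train_forecaster`, `forecast`, reference oracles |
| `risk_alert` | `hotspot_rule`, `run_alert`, `evaluate_alert` |
| `metrics` | `classification_metrics`, `regression_metrics`, `series_diagnostics` (ACF/PACF), `relative_improvement`, `channel_ablation` |
| `cli` | `run_config`, `run_pipeline`, `inst/cli/granarywatch.R` |
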