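Package: granarywatch
Title: Grain Storage Monitoring, Temperature-Field Forecasting, and Risk Alerts
Version: 0.1.0
Authors@R:
    person("Granarywatch", "Developers", email = "granarywatch@example.org",
           role = c("aut", "cre"))
Description: An integrated toolkit for monitoring the storage state of bulk
    grain from 3D granary temperature-sensor grids.  Provides readers and
    writers for long-format granary temperature records, a cleaning /
    imputation / spline-resizing / standardization preprocessing chain, an
    absolute-water-potential feature derived from grain temperature and
    moisture, minority-class augmentation by axis flips and a small 3D GAN,
    a 3D DenseNet six-way storage-state classifier, a two-channel
    3DCNN-LSTM temperature-field forecaster, and a forecast-then-classify
    early-warning chain for condensation and mildew risk.  A heat-relaxation
    granary simulator with injectable storage-state events makes every stage
    trainable and testable without access to operational granary data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
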