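gw <- asNamespace("granarywatch")

# a small preprocessed series on the model lattice for window tests
make_model_series <- function(days, seed = 1) {
  cfg <- sim_config(dims = c(10, 6, 4), n_days = days, sensor_noise_sd = 0,
                    error_code_rate = 0, dropout_rate = 0, seed = seed)
  simulate_series(cfg)
}

small_fcfg <- function(...) {
  forecast_config(lstm_hidden = 16, lstm_layers = 2, conv_channels = 4,
                  embed_dim = 24, batch_size = 8, max_epochs = 2,
                  patience = 2, dropout = 0.2, ...)
}

test_that("conv3d_reference satisfies its closed-form examples", {
  # 1x1x1 kernel, weight 1, bias 0 -> identity
  x <- array(rnorm(24), c(4, 3, 2))
  expect_equal(conv3d_reference(x, array(1, c(1, 1, 1))), x)
  # all-ones 2x2x2 kernel on all-ones 3x3x3 input -> every output 8
  out <- conv3d_reference(array(1, c(3, 3, 3)), array(1, c(2, 2, 2)))
  expect_equal(out, array(8, c(2, 2, 2)))
  expect_error(conv3d_reference(array(1, c(2, 2, 2)), array(1, c(3, 3, 3))),
               "larger")
})

test_that("production convolution agrees with the reference oracle (seed 5)", {
  set.seed(5)
  for (i in 1:10) {
    x <- array(rnorm(4 * 3 * 3), c(4, 3, 3))
    W <- array(rnorm(8), c(2, 2, 2))
    b <- rnorm(1)
    ref <- conv3d_reference(x, W, b)
    l <- gw$nn_conv3d(1, 1, kernel = c(2, 2, 2), pad = c(0, 0, 0))
    l$params$W <- matrix(as.vector(W), 1)
    l$params$b <- b
    got <- l$fwd(gw$st_new(matrix(as.vector(x), 1), dim(x), 1))
    expect_lt(max(abs(got$v - as.vector(ref))), 1e-6)
  }
})

test_that("lstm_cell_reference satisfies its gating limit cases", {
  H <- 3
  zp <- function() matrix(0, H, H)
  params <- list(Wf = zp(), Uf = zp(), bf = rep(0, H),
                 Wi = zp(), Ui = zp(), bi = rep(0, H),
                 Wo = zp(), Uo = zp(), bo = rep(0, H),
                 Wc = zp(), Uc = zp(), bc = rep(0, H))
  C_prev <- matrix(c(1, -2, 0.5), H)
  r <- lstm_cell_reference(matrix(0, H), matrix(0, H), C_prev, params)
  expect_equal(as.vector(r$gates$F), rep(0.5, H))
  expect_equal(as.vector(r$gates$I), rep(0.5, H))
  expect_equal(as.vector(r$gates$O), rep(0.5, H))
  expect_equal(r$C, 0.5 * C_prev)
  expect_equal(r$H, 0.5 * tanh(0.5 * C_prev))
  # saturated forget gate, closed input gate: cell state passes through
  params$bf <- rep(30, H); params$bi <- rep(-30, H)
  r2 <- lstm_cell_reference(matrix(0, H), matrix(0, H), C_prev, params)
  expect_equal(r2$C, C_prev, tolerance = 1e-6)
})

test_that("make_windows enumerates stride-1 windows with contiguity", {
  s45 <- make_model_series(45, seed = 31)
  w <- make_windows(s45, forecast_config(channels = 1), preprocessed = TRUE)
  expect_length(w, 1)   # L = T + P
  s50 <- make_model_series(50, seed = 32)
  w50 <- make_windows(s50, forecast_config(channels = 1), preprocessed = TRUE)
  expect_length(w50, 6) # L - T - P + 1
  for (wi in w50) {
    expect_identical(dim(wi$input), c(35L, 10L, 6L, 4L, 1L))
    expect_identical(dim(wi$target), c(10L, 10L, 6L, 4L))
    # last input day + 1 = first target day
    arr <- series_array(s50)
    expect_equal(wi$input[35, , , , 1], arr[, , , wi$start + 34])
    expect_equal(wi$target[1, , , ], arr[, , , wi$start + 35])
  }
  expect_error(make_windows(make_model_series(30, seed = 33),
                            forecast_config(channels = 1),
                            preprocessed = TRUE), "at least")
})

test_that("no test-window target day can leak into a training input window", {
  s <- make_model_series(160, seed = 34)
  w <- make_windows(s, forecast_config(channels = 1), preprocessed = TRUE)
  span_days <- function(wi) wi$start:(wi$start + 44)
  target_days <- function(wi) (wi$start + 35):(wi$start + 44)
  train_days <- unlist(lapply(Filter(function(x) isTRUE(x$split == "train"), w),
                              span_days))
  test_targets <- unlist(lapply(Filter(function(x) isTRUE(x$split == "test"), w),
                                target_days))
  expect_length(intersect(train_days, test_targets), 0)
  # val targets never cross the train boundary either
  val_targets <- unlist(lapply(Filter(function(x) isTRUE(x$split == "val"), w),
                               target_days))
  expect_length(intersect(train_days, val_targets), 0)
})

test_that("build_forecaster shapes: forward pass, ablation input, head size", {
  cfg <- small_fcfg()
  m <- build_forecaster(cfg)
  m$stats <- standardization_stats(list(rnorm(100, 10, 5), rnorm(100, 5000, 500)))
  s <- make_model_series(35, seed = 35)
  pred <- forecast(m, s, preprocessed = TRUE)
  expect_identical(dim(pred), c(10L, 10L, 6L, 4L))
  expect_true(all(is.finite(pred)))
  # deterministic given model + input
  expect_equal(forecast(m, s, preprocessed = TRUE), pred)
  # head parameter count: hidden x P*240 + P*240
  expect_equal(length(m$layers$head$params$W) + length(m$layers$head$params$b),
               cfg$lstm_hidden * 10 * 240 + 10 * 240)
  # single-channel ablation config accepts (T,10,6,4,1) input
  m1 <- build_forecaster(small_fcfg(channels = 1))
  m1$stats <- standardization_stats(rnorm(100, 10, 5))
  s1 <- make_model_series(40, seed = 36)
  pred1 <- forecast(m1, s1, preprocessed = TRUE)
  expect_identical(dim(pred1), c(10L, 10L, 6L, 4L))
  expect_error(forecast(m1, make_model_series(20, seed = 37),
                        preprocessed = TRUE), "needs")
})

test_that("train_forecaster reproduces its history and learns the field", {
  s <- make_model_series(150, seed = 38)
  cfg <- small_fcfg(channels = 1, seed = 6)
  w <- make_windows(s, cfg, preprocessed = TRUE)
  f1 <- train_forecaster(w, cfg)
  f2 <- train_forecaster(w, cfg)
  expect_equal(f1$history, f2$history)
  expect_true(all(is.finite(f1$history$train_loss)))
  # forecast errors from the metrics module match hand arithmetic on a toy
  truth <- array(0, c(2, 10, 6, 4)); pred <- truth + 1
  rm_ <- regression_metrics(truth, pred)
  expect_equal(rm_$mae, 1); expect_equal(rm_$rmse, 1)
})

test_that("channel ablation requires two channels and scores each channel", {
  s <- make_model_series(150, seed = 39)
  cfg1 <- small_fcfg(channels = 1, seed = 7)
  w1 <- make_windows(s, cfg1, preprocessed = TRUE)
  m1 <- train_forecaster(w1, cfg1)$model
  expect_error(channel_ablation(m1, w1), "two-channel")

  cfg2 <- small_fcfg(channels = 2, seed = 7)
  w2 <- make_windows(s, cfg2, preprocessed = TRUE)
  fit2 <- train_forecaster(w2, cfg2)
  ab <- channel_ablation(fit2$model, fit2$test)
  expect_identical(ab$channel, c("none", "temperature", "water_potential"))
  expect_equal(ab$delta[1], 0)
  expect_true(all(is.finite(ab$mae)))
  # ablation cannot systematically help beyond noise (soft expectation)
  expect_true(all(ab$delta >= -0.5))
})
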