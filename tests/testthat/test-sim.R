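test_that("simulate_series is deterministic under a fixed seed", {
  cfg <- sim_config(dims = c(5, 4, 3), n_days = 40, seed = 9)
  a <- simulate_series(cfg)
  b <- simulate_series(cfg)
  expect_equal(series_array(a), series_array(b))
  expect_equal(a$moisture, b$moisture)
})

test_that("with no forcing variation every voxel converges to the ambient mean", {
  cfg <- sim_config(dims = c(6, 5, 4), n_days = 200, ambient_amplitude = 0,
                    daily_noise_sd = 0, sensor_noise_sd = 0, diffusivity = 0.1,
                    error_code_rate = 0, dropout_rate = 0, seed = 1)
  s <- simulate_series(cfg)
  expect_lt(max(abs(s$grids[[200]]$values - cfg$ambient_mean)), 0.01)
})

test_that("deep layers lag the ambient annual cycle (seed 42)", {
  cfg <- sim_config(dims = c(10, 6, 4), n_days = 730, ambient_mean = 7,
                    ambient_amplitude = 14, daily_noise_sd = 1.0, seed = 42)
  s <- simulate_series(cfg)
  phys <- attr(s, "physical")
  amb <- attr(s, "ambient")
  bottom <- apply(phys[, , 1, ], 3, mean)
  cc <- vapply(0:40, function(L) {
    stats::cor(amb[1:(730 - L)], bottom[(1 + L):730])
  }, 0)
  expect_gte(which.max(cc) - 1, 5)
})

test_that("default 540-day simulation is calibrated to realistic pooled statistics", {
  s <- simulate_series(sim_config(seed = 7))
  cleaned <- clean_series(s)$series
  d <- series_diagnostics(cleaned, max_lag = 40)
  expect_gte(d$mean, 3);  expect_lte(d$mean, 11)
  expect_gte(d$sd, 8);    expect_lte(d$sd, 15)
  expect_lte(abs(d$skewness), 0.6)
  expect_gte(d$kurtosis, -1.5); expect_lte(d$kurtosis, 0.2)
})

test_that("mildew injection produces the advertised hotspot ramp", {
  cfg <- sim_config(n_days = 70, seed = 5)
  s <- simulate_series(cfg)
  ev <- event_spec("mildew", 51, 10, center = c(6, 4, 3),
                   intensity = list(rate = 1, onset = 0))
  inj <- inject_state(s, ev)
  base <- attr(s, "physical")[6, 4, 3, 50]
  final <- inj$series$grids[[60]]$values[6, 4, 3]
  expect_gte(final - base, 8)  # 10 days at 1 degC/day, minus drift/noise
  expect_identical(inj$labels[51:60], rep("mildew", 10))
  expect_identical(inj$labels[50], "normal")
})

test_that("condensation injection reaches the requested vertical gradient (seed 7)", {
  cfg <- sim_config(n_days = 70, seed = 7)
  s <- simulate_series(cfg)
  inj <- inject_state(s, event_spec("condensation", 51, 10,
                                    intensity = list(gradient = 12)))
  arr <- series_array(inj$series)
  d <- dim(arr)
  core_minus_surf <- vapply(51:60, function(t) {
    mean(arr[, , seq_len(ceiling(d[3] / 2)), t], na.rm = TRUE) -
      mean(arr[, , d[3], t], na.rm = TRUE)
  }, 0)
  expect_gte(max(core_minus_surf), 12 - 1e-9)
})

test_that("empty injection collapses spatial variance", {
  cfg <- sim_config(n_days = 60, seed = 13)
  s <- simulate_series(cfg)
  inj <- inject_state(s, event_spec("empty", 41, 10))
  arr <- series_array(inj$series)
  sds <- vapply(41:50, function(t) stats::sd(arr[, , , t], na.rm = TRUE), 0)
  expect_lt(max(sds), 0.5)
})

test_that("overlapping events are rejected and labels track event days", {
  cfg <- sim_config(n_days = 60, seed = 2)
  s <- simulate_series(cfg)
  a <- inject_state(s, event_spec("aeration", 20, 10))
  expect_error(inject_state(a$series, event_spec("mildew", 25, 5), a$labels),
               "overlap")
  b <- inject_state(a$series, event_spec("new_grain", 40, 5), a$labels)
  expect_identical(sum(b$labels == "aeration"), 10L)
  expect_identical(sum(b$labels == "new_grain"), 5L)
  expect_error(inject_state(s, event_spec("mildew", 58, 10)), "fit")
})

test_that("build_classification_dataset delivers exact counts, dims and no NAs", {
  samp <- build_classification_dataset(c(normal = 10, mildew = 5), seed = 1)
  labs <- vapply(samp, function(s) s$label, "")
  expect_identical(sum(labs == "normal"), 10L)
  expect_identical(sum(labs == "mildew"), 5L)
  for (s in samp) {
    expect_identical(dim(s$grid), c(10L, 6L, 4L))
    expect_false(anyNA(s$grid))
  }
  # determinism
  samp2 <- build_classification_dataset(c(normal = 10, mildew = 5), seed = 1)
  expect_equal(samp[[1]]$grid, samp2[[1]]$grid)
})

test_that("empty and mildew are separable by a nearest-centroid baseline (seed 1)", {
  samp <- build_classification_dataset(c(empty = 100, mildew = 100), seed = 1)
  expect_gte(nearest_centroid_accuracy(samp, samp), 0.9)
})

test_that("build_forecast_dataset honors the length contract and determinism", {
  cfg <- sim_config(dims = c(6, 5, 4), n_days = 30, seed = 3)
  sers <- build_forecast_dataset(cfg, seed = 3, n_granaries = 2,
                                 window = 35, horizon = 10)
  expect_length(sers, 2)
  for (s in sers) {
    expect_gte(length(s$days), 35 + 10 + 100)
    expect_true(any(!is.na(s$moisture)))
    expect_identical(attr(s, "labels"), rep("normal", length(s$days)))
  }
  sers2 <- build_forecast_dataset(cfg, seed = 3, n_granaries = 2,
                                  window = 35, horizon = 10)
  expect_equal(series_array(sers[[2]]), series_array(sers2[[2]]))
  # with an injected event the label track and center are returned
  ev <- list(event_spec("mildew", 100, 10))
  sers3 <- build_forecast_dataset(cfg, events = ev, seed = 3, n_granaries = 1)
  expect_identical(sum(attr(sers3[[1]], "labels") == "mildew"), 10L)
  expect_length(attr(sers3[[1]], "event_centers"), 1)
})
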