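test_that("clean_series removes sentinel codes and range violations", {
  s <- make_tiny_series(3, dims = c(2, 2, 2))
  arr <- series_array(s)
  arr[1, 1, 1, 2] <- 888
  arr[2, 2, 2, 1] <- -60   # outside physical range
  s <- series_with_values(s, arr)
  r <- clean_series(s)
  expect_true(r$series$grids[[2]]$mask[1, 1, 1])
  expect_true(r$series$grids[[1]]$mask[2, 2, 2])
  expect_identical(r$report$n_code_removed, 2L)
})

test_that("constant series has degenerate dispersion and zero Z-removals", {
  s <- make_tiny_series(3)
  arr <- series_array(s) * 0 + 15
  r <- clean_series(series_with_values(s, arr))
  expect_true(r$report$degenerate)
  expect_identical(r$report$n_z_removed, 0L)
  expect_false(any(series_array(r$series) |> is.na()))
})

test_that("Z-scores and removal match a hand-computed oracle ({999 zeros, one 100-like})", {
  # 999 values at 0 and one at 50 (inside physical range): mu = 0.05005...,
  # sigma = population sd, Z of the outlier > 3 -> removed
  n <- 1000
  dims <- c(10, 10, 1)
  days <- 10
  vals <- array(0, c(dims, days))
  vals[5, 5, 1, 3] <- 50
  s <- make_tiny_series(days, dims = dims)
  s <- series_with_values(s, vals)
  r <- clean_series(s)
  mu <- 50 / n
  sigma <- sqrt(mean((c(rep(0, n - 1), 50) - mu)^2))
  z <- (50 - mu) / sigma
  expect_equal(r$report$mu, mu)
  expect_equal(r$report$sigma, sigma)
  expect_equal(r$report$z[5, 5, 1, 3], z)
  expect_true(z > 3)
  expect_true(r$series$grids[[3]]$mask[5, 5, 1])
  expect_identical(r$report$n_z_removed, 1L)
})

test_that("cleaning is idempotent", {
  s <- make_random_series(days = 6, dims = c(3, 3, 2), seed = 11)
  arr <- series_array(s)
  arr[1, 1, 1, 1] <- 888
  arr[3, 3, 2, 6] <- 40  # a tail value the Z-filter may remove
  s <- series_with_values(s, arr)
  once <- clean_series(s)$series
  twice <- clean_series(once)$series
  expect_equal(series_array(once), series_array(twice))
})

test_that("impute_missing uses adjacent-day means and edge rules", {
  s <- make_tiny_series(3, dims = c(1, 1, 1))
  s <- series_with_values(s, array(c(10, NA, 20), c(1, 1, 1, 3)))
  expect_equal(as.vector(series_array(impute_missing(s))), c(10, 15, 20))
  s2 <- series_with_values(s, array(c(NA, 8, 9), c(1, 1, 1, 3)))
  expect_equal(as.vector(series_array(impute_missing(s2))), c(8, 8, 9))
  s3 <- series_with_values(s, array(c(7, 8, NA), c(1, 1, 1, 3)))
  expect_equal(as.vector(series_array(impute_missing(s3))), c(7, 8, 8))
  # interior gap takes mean of nearest neighbors, not linear interpolation
  s4 <- make_tiny_series(4, dims = c(1, 1, 1))
  s4 <- series_with_values(s4, array(c(10, NA, NA, 22), c(1, 1, 1, 4)))
  expect_equal(as.vector(series_array(impute_missing(s4))), c(10, 16, 16, 22))
})

test_that("impute_missing property: no missing left, observed untouched (seed 3)", {
  s <- make_random_series(days = 8, dims = c(4, 3, 2), miss_rate = 0.1,
                          seed = 3)
  before <- series_array(s)
  out <- impute_missing(s)
  after <- series_array(out)
  expect_false(anyNA(after))
  obs <- !is.na(before)
  expect_equal(after[obs], before[obs])
})

test_that("impute_missing errors when a voxel is never observed", {
  s <- make_tiny_series(3, dims = c(2, 1, 1))
  arr <- series_array(s)
  arr[2, 1, 1, ] <- NA
  expect_error(impute_missing(series_with_values(s, arr)), "voxel \\(2,1,1\\)")
})

test_that("resize_spline reproduces constants and the identity at target dims", {
  g <- array(20, c(7, 5, 3))
  out <- resize_spline(g)
  expect_identical(dim(out), c(10L, 6L, 4L))
  expect_equal(out, array(20, c(10, 6, 4)), tolerance = 1e-12)
  # nodes coincide: output equals input
  h <- array(rnorm(240), c(10, 6, 4))
  expect_equal(resize_spline(h), h, tolerance = 1e-9)
})

test_that("resize_spline preserves linear fields and endpoints", {
  # grid linear in x: interpolation must stay linear in x within 1e-6
  x <- seq(0, 1, length.out = 8)
  g <- array(rep(2 + 3 * x, times = 15), c(8, 5, 3))
  out <- resize_spline(g)
  xo <- seq(0, 1, length.out = 10)
  expect_equal(out[, 3, 2], 2 + 3 * xo, tolerance = 1e-6)
  expect_equal(out[1, 1, 1], 2, tolerance = 1e-9)
  expect_equal(out[10, 5, 3], 5, tolerance = 1e-9)
})

test_that("resize_spline commutes with adding a constant", {
  set.seed(9)
  g <- array(rnorm(8 * 5 * 3, 10, 4), c(8, 5, 3))
  expect_equal(resize_spline(g + 7.5), resize_spline(g) + 7.5,
               tolerance = 1e-9)
})

test_that("resize_spline refuses missing values", {
  g <- array(1, c(5, 5, 3)); g[1] <- NA
  expect_error(resize_spline(g), "impute")
})

test_that("standardize/destandardize are exact inverses with train-partition stats", {
  set.seed(2)
  x <- rnorm(500, 12, 6)
  st <- standardization_stats(x)
  z <- standardize(x, st)
  expect_equal(mean(z), 0, tolerance = 1e-6)
  expect_equal(sqrt(mean(z^2)), 1, tolerance = 1e-6)
  expect_equal(destandardize(z, st), x, tolerance = 1e-9)
  # fixed toy set: population stats (5, 5) and standardized {-1, 1}
  st2 <- standardization_stats(c(0, 10))
  expect_equal(unname(st2$mean), 5)
  expect_equal(unname(st2$sd), 5)
  expect_equal(standardize(c(0, 10), st2), c(-1, 1))
  expect_error(standardization_stats(rep(3, 5)), "positive")
})

test_that("the full chain output satisfies downstream preconditions", {
  cfg <- sim_config(dims = c(8, 6, 5), n_days = 30, seed = 21,
                    error_code_rate = 0.01, dropout_rate = 0.05)
  s <- simulate_series(cfg)
  pp <- preprocess_series(s)
  expect_identical(series_dims(pp), c(10L, 6L, 4L))
  arr <- series_array(pp)
  expect_false(anyNA(arr))
  expect_true(all(arr > -40 & arr < 60))
})
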