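# shared fixture builders (everything generated in code; no stored data)

# a small fully-observed series with deterministic values
make_tiny_series <- function(days = 3, dims = c(2, 2, 2), base = 10,
                             moisture = NULL) {
  dts <- as.Date("2023-01-01") + seq_len(days) - 1
  grids <- lapply(seq_len(days), function(t) {
    temperature_grid(array(base + t + seq_len(prod(dims)) / 10, dims),
                     date = dts[t])
  })
  granary_series("tiny", "wheat", dts, grids, moisture, region = "test")
}

# a random series with a given missingness rate, seeded
make_random_series <- function(days = 5, dims = c(3, 3, 2), miss_rate = 0,
                               seed = 1) {
  set.seed(seed)
  dts <- as.Date("2023-06-01") + seq_len(days) - 1
  grids <- lapply(seq_len(days), function(t) {
    v <- array(rnorm(prod(dims), 15, 5), dims)
    if (miss_rate > 0) {
      v[runif(length(v)) < miss_rate] <- NA_real_
    }
    temperature_grid(v, date = dts[t])
  })
  moist <- rep(NA_real_, days)
  moist[1] <- 12.5
  granary_series("rand", "corn", dts, grids, moist, region = "test")
}

# random class samples on the model lattice
make_random_samples <- function(n, label = "normal", seed = 1,
                                dims = c(10, 6, 4)) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    class_sample(array(rnorm(prod(dims), 12, 4), dims), label)
  })
}

# finite-difference gradient check helper: returns max abs deviation over a
# few random parameter entries
fd_param_check <- function(layer, pname, loss_fn, n = 4, eps = 1e-6) {
  g <- layer$grads[[pname]]
  p <- layer$params[[pname]]
  idx <- sample(length(p), min(n, length(p)))
  num <- vapply(idx, function(j) {
    layer$params[[pname]][j] <- p[j] + eps
    lp <- loss_fn()
    layer$params[[pname]][j] <- p[j] - eps
    lm <- loss_fn()
    layer$params[[pname]][j] <- p[j]
    (lp - lm) / (2 * eps)
  }, 0)
  max(abs(num - g[idx]))
}

# the printed regional storage-state counts shipped with the package
regional_counts <- function() {
  utils::read.csv(system.file("extdata", "regional_state_counts.csv",
                              package = "granarywatch"),
                  stringsAsFactors = FALSE)
}
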