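gw <- asNamespace("granarywatch")

m_with_stats <- function(m) {
  m$stats <- standardization_stats(c(0, 1))
  m
}

# six artificial, linearly separable classes on the model lattice
make_sep_dataset <- function(n_per_class = 12, seed = 1, sd = 1) {
  set.seed(seed)
  out <- list()
  for (i in seq_along(storage_states())) {
    mu <- (i - 3.5) * 4
    for (j in seq_len(n_per_class)) {
      out[[length(out) + 1]] <- class_sample(
        array(rnorm(240, mu, sd), c(10, 6, 4)), storage_states()[i])
    }
  }
  out
}

test_that("build_classifier emits normalized probabilities and logged shapes", {
  cfg <- densenet_config(base_channels = 8, growth_rate = 8,
                         num_dense_blocks = 2, layers_per_block = 2, seed = 3)
  m <- build_classifier(cfg)
  r <- classify(m_with_stats(m), array(0, c(10, 6, 4)))
  expect_length(r$prob, 6)
  expect_equal(sum(r$prob), 1, tolerance = 1e-6)
  expect_identical(names(which.max(r$prob)), r$state)
  # shapes log: transition halves dims (ceil) and compresses channels
  expect_identical(m$shapes$transition1$dims, c(5L, 3L, 2L))
  expect_identical(m$shapes$transition1$channels, 12L)  # floor(24 * 0.5)
})

test_that("compression 1.0 keeps the channel count across a transition", {
  tr <- gw$nn_transition(10, 1.0)
  expect_identical(tr$c_out, 10L)
  tr2 <- gw$nn_transition(10, 0.5)
  expect_identical(tr2$c_out, 5L)
})

test_that("parameter count equals an independent shape-walk computation", {
  cfg <- densenet_config(base_channels = 16, growth_rate = 16,
                         num_dense_blocks = 3, layers_per_block = 4,
                         compression = 0.5, seed = 1)
  m <- build_classifier(cfg)
  expected <- local({
    g <- cfg$growth_rate
    tot <- cfg$base_channels * 27 + cfg$base_channels  # stem conv, C_in = 1
    ch <- cfg$base_channels
    for (b in seq_len(cfg$num_dense_blocks)) {
      for (k in seq_len(cfg$layers_per_block)) {
        ck <- ch + (k - 1) * g
        tot <- tot + 2 * ck            # BN gamma/beta
        tot <- tot + g * ck * 27 + g   # 3x3x3 conv + bias
      }
      ch <- ch + cfg$layers_per_block * g
      if (b < cfg$num_dense_blocks) {
        co <- floor(ch * cfg$compression)
        tot <- tot + 2 * ch            # transition BN
        tot <- tot + co * ch + co      # 1x1x1 conv
        ch <- co
      }
    }
    tot <- tot + 2 * ch                # final BN
    tot + 6 * ch + 6                   # head
  })
  expect_identical(count_parameters(m), as.integer(expected))
})

test_that("a config that collapses the lattice is rejected with the stage named", {
  cfg <- densenet_config(num_dense_blocks = 6, layers_per_block = 1,
                         base_channels = 4, growth_rate = 4)
  expect_error(build_classifier(cfg, input_dims = c(4, 4, 4)), "transition")
})

test_that("split_dataset is stratified with largest-remainder rounding", {
  samp <- make_random_samples(100, "normal", seed = 1)
  sp <- split_dataset(samp, seed = 2)
  expect_length(sp$train, 70)
  expect_length(sp$val, 15)
  expect_length(sp$test, 15)
  # disjoint and covering
  expect_identical(sort(unlist(lapply(1:3, function(i) which(sp$index == i)))),
                   1:100)
  # multiclass proportions within one sample of target
  mixed <- c(make_random_samples(37, "normal", seed = 3),
             make_random_samples(11, "mildew", seed = 4),
             make_random_samples(7, "empty", seed = 5))
  spm <- split_dataset(mixed, seed = 6)
  for (cl in c("normal", "mildew", "empty")) {
    n <- sum(vapply(mixed, function(s) s$label, "") == cl)
    got <- sum(vapply(spm$train, function(s) s$label, "") == cl)
    expect_lte(abs(got - 0.7 * n), 1)
  }
  expect_error(split_dataset(make_random_samples(2, "empty"), seed = 1),
               "fewer than 3")
  # seeded determinism
  sp2 <- split_dataset(samp, seed = 2)
  expect_identical(sp$index, sp2$index)
})

test_that("class weights are inverse-frequency, mean 1, monotone in rarity", {
  bal <- rep(storage_states(), each = 10)
  expect_equal(unname(class_weights(bal)), rep(1, 6))
  labs <- rep(storage_states(), times = c(60, 30, 10, 10, 10, 10))
  w <- class_weights(labs)
  n_c <- c(60, 30, 10, 10, 10, 10)
  raw <- 130 / (6 * n_c)
  expect_equal(unname(w), raw / mean(raw))
  expect_equal(mean(w), 1)
  # rarer class never gets a smaller weight
  expect_true(all(diff(w[order(-n_c)]) >= 0))
  expect_error(class_weights(rep("normal", 5)), "empty class")
})

test_that("training reduces loss, stops early, restores best weights, reproduces", {
  samp <- make_sep_dataset(24, seed = 7)
  cfg <- densenet_config(learning_rate = 0.01, base_channels = 6,
                         growth_rate = 6, num_dense_blocks = 2,
                         layers_per_block = 2, batch_size = 16,
                         max_epochs = 10, patience = 4, seed = 5)
  f1 <- train_classifier(samp, cfg)
  expect_lte(f1$history$train_loss[f1$best_epoch], f1$history$train_loss[1])
  expect_lte(f1$best_epoch, f1$stopped_epoch)
  f2 <- train_classifier(samp, cfg)
  expect_equal(f1$history, f2$history)
  # the restored model classifies its own training data well
  pred <- classify(f1$model, lapply(f1$split$train, function(s) s$grid))
  acc <- mean(pred$state == vapply(f1$split$train, function(s) s$label, ""))
  expect_gte(acc, 0.9)
})

test_that("classify validates dims and is batch/single consistent", {
  samp <- make_sep_dataset(3, seed = 8)
  cfg <- densenet_config(base_channels = 4, growth_rate = 4,
                         num_dense_blocks = 1, layers_per_block = 1,
                         batch_size = 18, max_epochs = 1, patience = 1, seed = 2)
  fit <- train_classifier(samp, cfg)
  m <- fit$model
  expect_error(classify(m, array(0, c(5, 5, 5))), "dims")
  grids <- lapply(samp[1:4], function(s) s$grid)
  batch <- classify(m, grids)
  for (i in 1:4) {
    single <- classify(m, grids[[i]])
    expect_identical(single$state, batch$state[i])
    expect_equal(unname(single$prob), unname(attr(batch, "prob")[i, ]),
                 tolerance = 1e-9)
  }
  expect_equal(rowSums(attr(batch, "prob")), rep(1, 4), tolerance = 1e-6)
})

test_that("permuting the head permutes class probabilities identically", {
  samp <- make_sep_dataset(3, seed = 9)
  cfg <- densenet_config(base_channels = 4, growth_rate = 4,
                         num_dense_blocks = 1, layers_per_block = 1,
                         batch_size = 18, max_epochs = 1, patience = 1, seed = 4)
  m <- train_classifier(samp, cfg)$model
  g <- samp[[5]]$grid
  p0 <- classify(m, g)$prob
  perm <- c(3, 1, 6, 2, 5, 4)
  m$layers$head$params$W <- m$layers$head$params$W[perm, ]
  m$layers$head$params$b <- m$layers$head$params$b[perm]
  p1 <- classify(m, g)$prob
  expect_equal(unname(p1), unname(p0[perm]), tolerance = 1e-9)
})
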