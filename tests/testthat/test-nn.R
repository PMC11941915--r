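# gradient and bookkeeping checks for the network core (all layers small,
# all on the double-precision kernel path, checked against central finite
# differences)

gw <- asNamespace("granarywatch")

test_that("conv3d forward/backward gradients match finite differences", {
  set.seed(5)
  l <- gw$nn_conv3d(2, 3, kernel = c(3, 3, 3))
  xs <- gw$st_new(matrix(rnorm(2 * 60 * 4), 2), c(5, 4, 3), 4)
  tgt <- matrix(rnorm(3 * 60 * 4), 3)
  loss <- function() { y <- l$fwd(xs); sum((y$v - tgt)^2) }
  y <- l$fwd(xs)
  dx <- l$bwd(gw$st_new(2 * (y$v - tgt), y$d, y$B))
  expect_lt(fd_param_check(l, "W", loss), 1e-5)
  expect_lt(fd_param_check(l, "b", loss), 1e-5)
  idx <- sample(length(xs$v), 4)
  num <- vapply(idx, function(j) {
    xs$v[j] <<- xs$v[j] + 1e-6; lp <- loss()
    xs$v[j] <<- xs$v[j] - 2e-6; lm <- loss()
    xs$v[j] <<- xs$v[j] + 1e-6
    (lp - lm) / 2e-6
  }, 0)
  expect_lt(max(abs(num - dx$v[idx])), 1e-5)
})

test_that("batchnorm gradients match finite differences", {
  set.seed(6)
  l <- gw$nn_bn(3)
  xs <- gw$st_new(matrix(rnorm(3 * 40), 3), c(4, 5, 1), 2)
  tgt <- matrix(rnorm(3 * 40), 3)
  loss <- function() { y <- l$fwd(xs, TRUE); sum((y$v - tgt)^2) }
  y <- l$fwd(xs, TRUE)
  dx <- l$bwd(gw$st_new(2 * (y$v - tgt), y$d, y$B))
  expect_lt(fd_param_check(l, "gamma", loss), 1e-5)
  expect_lt(fd_param_check(l, "beta", loss), 1e-5)
  idx <- sample(length(xs$v), 4)
  num <- vapply(idx, function(j) {
    xs$v[j] <<- xs$v[j] + 1e-6; lp <- loss()
    xs$v[j] <<- xs$v[j] - 2e-6; lm <- loss()
    xs$v[j] <<- xs$v[j] + 1e-6
    (lp - lm) / 2e-6
  }, 0)
  expect_lt(max(abs(num - dx$v[idx])), 1e-5)
})

test_that("pooling layers backpropagate exactly", {
  set.seed(7)
  for (mode in c("max", "avg")) {
    l <- gw$nn_pool3d(mode)
    xs <- gw$st_new(matrix(rnorm(2 * 60 * 2), 2), c(5, 4, 3), 2)
    y <- l$fwd(xs)
    expect_identical(y$d, c(3L, 2L, 2L))
    tgt <- matrix(rnorm(length(y$v)), nrow(y$v))
    loss <- function() { y <- l$fwd(xs); sum((y$v - tgt)^2) }
    y <- l$fwd(xs)
    dx <- l$bwd(gw$st_new(2 * (y$v - tgt), y$d, y$B))
    idx <- sample(length(xs$v), 5)
    num <- vapply(idx, function(j) {
      xs$v[j] <<- xs$v[j] + 1e-6; lp <- loss()
      xs$v[j] <<- xs$v[j] - 2e-6; lm <- loss()
      xs$v[j] <<- xs$v[j] + 1e-6
      (lp - lm) / 2e-6
    }, 0)
    expect_lt(max(abs(num - dx$v[idx])), 1e-5)
  }
})

test_that("stacked LSTM matches the literal cell recursion and its gradients check out", {
  set.seed(8)
  H <- 4; D <- 3; B <- 2; Tn <- 5
  l <- gw$nn_lstm(D, H, layers = 2, dropout = 0)
  x <- array(rnorm(D * B * Tn), c(D, B, Tn))
  hT <- l$fwd(x, train = FALSE)
  mkp <- function(W, U, b) list(
    Wf = W[1:H, , drop = FALSE], Uf = U[1:H, , drop = FALSE], bf = b[1:H],
    Wi = W[(H + 1):(2 * H), , drop = FALSE], Ui = U[(H + 1):(2 * H), , drop = FALSE],
    bi = b[(H + 1):(2 * H)],
    Wo = W[(2 * H + 1):(3 * H), , drop = FALSE], Uo = U[(2 * H + 1):(3 * H), , drop = FALSE],
    bo = b[(2 * H + 1):(3 * H)],
    Wc = W[(3 * H + 1):(4 * H), , drop = FALSE], Uc = U[(3 * H + 1):(4 * H), , drop = FALSE],
    bc = b[(3 * H + 1):(4 * H)])
  p1 <- mkp(l$params$W1, l$params$U1, l$params$b1)
  p2 <- mkp(l$params$W2, l$params$U2, l$params$b2)
  h1 <- matrix(0, H, B); c1 <- matrix(0, H, B)
  h2 <- matrix(0, H, B); c2 <- matrix(0, H, B)
  for (t in seq_len(Tn)) {
    r1 <- lstm_cell_reference(x[, , t], h1, c1, p1); h1 <- r1$H; c1 <- r1$C
    r2 <- lstm_cell_reference(h1, h2, c2, p2); h2 <- r2$H; c2 <- r2$C
  }
  expect_equal(hT, h2, tolerance = 1e-12)

  tgt <- matrix(rnorm(H * B), H)
  loss <- function() { y <- l$fwd(x, train = FALSE); sum((y - tgt)^2) }
  y <- l$fwd(x, train = FALSE)
  l$bwd(2 * (y - tgt))
  for (pn in c("W1", "U1", "b1", "W2", "U2", "b2")) {
    expect_lt(fd_param_check(l, pn, loss), 1e-6)
  }
})

test_that("softmax columns are normalized and weighted CE grads are exact", {
  set.seed(10)
  z <- matrix(rnorm(6 * 7, 0, 5), 6)
  p <- gw$softmax_cols(z)
  expect_equal(colSums(p), rep(1, 7), tolerance = 1e-12)
  y <- sample(1:6, 7, replace = TRUE)
  w <- runif(6, 0.5, 2)
  r <- gw$loss_wce(z, y, w)
  idx <- sample(length(z), 6)
  num <- vapply(idx, function(j) {
    z[j] <- z[j] + 1e-6; lp <- gw$loss_wce(z, y, w)$loss
    z[j] <- z[j] - 2e-6; lm <- gw$loss_wce(z, y, w)$loss
    z[j] <- z[j] + 1e-6
    (lp - lm) / 2e-6
  }, 0)
  expect_lt(max(abs(num - r$grad[idx])), 1e-6)
})

test_that("dense block concatenation bookkeeping follows input + (k-1) * growth", {
  set.seed(11)
  blk <- gw$nn_dense_block(8, layers = 3, growth = 4)
  xs <- gw$st_new(matrix(rnorm(8 * 24 * 2), 8), c(4, 3, 2), 2)
  y <- blk$fwd(xs)
  expect_identical(blk$shapes, c(8L, 12L, 16L))   # layer k input channels
  expect_identical(nrow(y$v), 8L + 3L * 4L)
  # gradient through the whole block
  tgt <- matrix(rnorm(length(y$v)), nrow(y$v))
  loss <- function() { y <- blk$fwd(xs); sum((y$v - tgt)^2) }
  y <- blk$fwd(xs)
  blk$bwd(gw$st_new(2 * (y$v - tgt), y$d, y$B))
  u <- blk$units[[2]]
  expect_lt(fd_param_check(u$conv, "W", loss), 1e-4)
  expect_lt(fd_param_check(u$bn, "gamma", loss), 1e-4)
})

test_that("Adam reduces the loss on a toy regression", {
  set.seed(12)
  l <- gw$nn_linear(4, 1)
  Wstar <- matrix(c(1, -2, 3, 0.5), 1)
  x <- matrix(rnorm(4 * 64), 4)
  tgt <- Wstar %*% x
  opt <- gw$adam_new(lr = 0.05)
  losses <- numeric(150)
  for (i in 1:150) {
    y <- l$fwd(x)
    losses[i] <- mean((y - tgt)^2)
    l$bwd(2 * (y - tgt) / length(tgt))
    gw$adam_step(opt, list(l))
  }
  expect_lt(losses[150], losses[1] / 100)
})
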