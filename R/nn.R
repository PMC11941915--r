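# Minimal BLAS-backed neural-network core.
#
# Spatial feature maps travel as a list st = list(v, d, B): v is a
# (C x S*B) matrix with S = prod(d) positions in x-fastest column-major
# order and columns grouped per sample; vector features travel as a plain
# (D x B) matrix.  Layers are environments with $params/$grads and
# $fwd/$bwd closures; gradients are exact (checked against finite
# differences in the test suite).

st_new <- function(v, d, B) list(v = v, d = as.integer(d), B = as.integer(B))

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

# ---- spatial layers ---------------------------------------------------------

nn_conv3d <- function(c_in, c_out, kernel = c(3, 3, 3), pad = NULL) {
  if (is.null(pad)) pad <- (kernel - 1L) %/% 2L
  l <- new_layer("conv3d")
  fan_in <- c_in * prod(kernel)
  l$params$W <- matrix(stats::rnorm(c_out * fan_in, 0, sqrt(2 / fan_in)),
                       c_out, fan_in)
  l$params$b <- numeric(c_out)
  l$kernel <- as.integer(kernel); l$pad <- as.integer(pad)
  l$c_in <- c_in; l$c_out <- c_out
  l$fwd <- function(st, train = TRUE) {
    l$in_st <- st
    k <- l$kernel; p <- l$pad
    y <- cpp_conv3d_fw(st$v, l$params$W, l$params$b,
                       st$d[1], st$d[2], st$d[3], st$B,
                       k[1], k[2], k[3], p[1], p[2], p[3])
    do <- st$d + 2L * p - k + 1L
    st_new(y, do, st$B)
  }
  l$bwd <- function(dst) {
    st <- l$in_st
    k <- l$kernel; p <- l$pad
    r <- cpp_conv3d_bw(st$v, l$params$W, dst$v,
                       st$d[1], st$d[2], st$d[3], st$B,
                       k[1], k[2], k[3], p[1], p[2], p[3])
    l$grads$W <- r$dW
    l$grads$b <- as.vector(r$db)
    st_new(r$dX, st$d, st$B)
  }
  l
}

nn_bn <- function(c, eps = 1e-5, momentum = 0.9) {
  l <- new_layer("bn")
  l$params$gamma <- rep(1, c)
  l$params$beta <- rep(0, c)
  l$run_mean <- rep(0, c); l$run_var <- rep(1, c)
  l$eps <- eps; l$momentum <- momentum
  l$fwd <- function(st, train = TRUE) {
    x <- st$v
    if (train) {
      mu <- rowMeans(x)
      v <- rowMeans(x * x) - mu^2
      l$run_mean <- l$momentum * l$run_mean + (1 - l$momentum) * mu
      l$run_var <- l$momentum * l$run_var + (1 - l$momentum) * v
    } else {
      mu <- l$run_mean; v <- l$run_var
    }
    invstd <- 1 / sqrt(v + l$eps)
    xhat <- (x - mu) * invstd
    l$xhat <- xhat; l$invstd <- invstd; l$train <- train
    st_new(l$params$gamma * xhat + l$params$beta, st$d, st$B)
  }
  l$bwd <- function(dst) {
    dy <- dst$v
    l$grads$gamma <- rowSums(dy * l$xhat)
    l$grads$beta <- rowSums(dy)
    dxhat <- dy * l$params$gamma
    if (l$train) {
      dx <- l$invstd * (dxhat - rowMeans(dxhat) -
                          l$xhat * rowMeans(dxhat * l$xhat))
    } else {
      dx <- l$invstd * dxhat
    }
    st_new(dx, dst$d, dst$B)
  }
  l
}

nn_relu <- function() {
  l <- new_layer("relu")
  l$fwd <- function(st, train = TRUE) {
    vec <- !is.list(st)
    x <- if (vec) st else st$v
    l$mask <- x > 0
    y <- x * l$mask
    if (vec) y else st_new(y, st$d, st$B)
  }
  l$bwd <- function(dst) {
    vec <- !is.list(dst)
    dy <- if (vec) dst else dst$v
    dx <- dy * l$mask
    if (vec) dx else st_new(dx, dst$d, dst$B)
  }
  l
}

nn_pool3d <- function(mode = c("max", "avg")) {
  mode <- match.arg(mode)
  l <- new_layer(paste0(mode, "pool3d"))
  l$mode <- if (mode == "max") 0L else 1L
  l$fwd <- function(st, train = TRUE) {
    l$in_d <- st$d; l$B <- st$B
    r <- cpp_pool3d(st$v, st$d[1], st$d[2], st$d[3], st$B, l$mode)
    l$arg <- if (l$mode == 0L) r$arg else matrix(0L, 0, 0)
    l$cnt <- if (l$mode == 1L) r$cnt else numeric(0)
    st_new(r$y, r$dims, st$B)
  }
  l$bwd <- function(dst) {
    dx <- cpp_pool3d_bw(dst$v, matrix(0), l$in_d[1], l$in_d[2], l$in_d[3],
                        l$B, l$mode, l$arg, l$cnt)
    st_new(dx, l$in_d, l$B)
  }
  l
}

# global average pool: spatial (C, S*B) -> vector (C, B)
nn_gap <- function() {
  l <- new_layer("gap")
  l$fwd <- function(st, train = TRUE) {
    S <- prod(st$d)
    l$S <- S; l$B <- st$B; l$d <- st$d
    G <- kronecker(diag(st$B), matrix(1 / S, S, 1))
    l$G <- G
    st$v %*% G
  }
  l$bwd <- function(dy) {
    st_new(tcrossprod(dy, l$G), l$d, l$B)
  }
  l
}

# spatial (C, S*B) -> vector (C*S, B)
nn_flatten <- function() {
  l <- new_layer("flatten")
  l$fwd <- function(st, train = TRUE) {
    l$d <- st$d; l$B <- st$B; l$C <- nrow(st$v)
    matrix(st$v, ncol = st$B)
  }
  l$bwd <- function(dy) {
    st_new(matrix(dy, nrow = l$C), l$d, l$B)
  }
  l
}

# nearest-neighbor x2 upsampling of a spatial map (used by the GAN generator)
nn_upsample2 <- function() {
  l <- new_layer("upsample2")
  l$fwd <- function(st, train = TRUE) {
    d <- st$d; B <- st$B
    do <- 2L * d
    S <- prod(d); So <- prod(do)
    key <- paste0(paste(d, collapse = "x"), "_", B)
    if (!identical(l$key, key)) {
      xo <- (seq_len(do[1]) + 1L) %/% 2L
      yo <- (seq_len(do[2]) + 1L) %/% 2L
      zo <- (seq_len(do[3]) + 1L) %/% 2L
      sidx <- outer(outer(xo, d[1] * (yo - 1L), "+"),
                    d[1] * d[2] * (zo - 1L), "+")
      l$map <- as.integer(rep(as.vector(sidx), B) +
                            rep((seq_len(B) - 1L) * S, each = So))
      l$key <- key; l$S <- S; l$So <- So
    }
    l$in_d <- d; l$B <- B
    st_new(st$v[, l$map, drop = FALSE], do, B)
  }
  l$bwd <- function(dst) {
    # scatter-add: each input column accumulates its 8 upsampled copies
    dX <- matrix(0, nrow(dst$v), l$S * l$B)
    agg <- rowsum(t(dst$v), group = l$map)
    dX[, as.integer(rownames(agg))] <- t(agg)
    st_new(dX, l$in_d, l$B)
  }
  l
}

# ---- vector layers ----------------------------------------------------------

nn_linear <- function(d_in, d_out) {
  l <- new_layer("linear")
  l$params$W <- matrix(stats::rnorm(d_out * d_in, 0, sqrt(2 / d_in)), d_out, d_in)
  l$params$b <- numeric(d_out)
  l$fwd <- function(x, train = TRUE) {
    l$x <- x
    l$params$W %*% x + l$params$b
  }
  l$bwd <- function(dy) {
    l$grads$W <- tcrossprod(dy, l$x)
    l$grads$b <- rowSums(dy)
    crossprod(l$params$W, dy)
  }
  l
}

nn_dropout <- function(p) {
  l <- new_layer("dropout")
  l$p <- p
  l$fwd <- function(x, train = TRUE) {
    vec <- !is.list(x)
    v <- if (vec) x else x$v
    if (train && l$p > 0) {
      l$mask <- (matrix(stats::runif(length(v)), nrow(v)) >= l$p) / (1 - l$p)
      v <- v * l$mask
    } else {
      l$mask <- NULL
    }
    if (vec) v else st_new(v, x$d, x$B)
  }
  l$bwd <- function(dy) {
    vec <- !is.list(dy)
    dv <- if (vec) dy else dy$v
    if (!is.null(l$mask)) dv <- dv * l$mask
    if (vec) dv else st_new(dv, dy$d, dy$B)
  }
  l
}

# ---- composite: dense block and transition ----------------------------------

# one dense block: `layers` composite units, each BN - ReLU - conv3d(growth),
# whose outputs are concatenated channel-wise onto the running input
nn_dense_block <- function(c_in, layers, growth, kernel = c(3, 3, 3)) {
  l <- new_layer("dense_block")
  l$units <- lapply(seq_len(layers), function(k) {
    ck <- c_in + (k - 1L) * growth
    list(bn = nn_bn(ck), relu = nn_relu(),
         conv = nn_conv3d(ck, growth, kernel))
  })
  l$c_in <- c_in; l$growth <- growth
  l$c_out <- c_in + layers * growth
  l$fwd <- function(st, train = TRUE) {
    acc <- st
    l$shapes <- integer(0)
    for (u in l$units) {
      l$shapes <- c(l$shapes, nrow(acc$v))
      h <- u$conv$fwd(u$relu$fwd(u$bn$fwd(acc, train), train), train)
      acc <- st_new(rbind(acc$v, h$v), acc$d, acc$B)
    }
    acc
  }
  l$bwd <- function(dst) {
    d <- dst
    for (k in rev(seq_along(l$units))) {
      u <- l$units[[k]]
      ck <- l$shapes[k]
      dy_k <- st_new(d$v[(ck + 1):nrow(d$v), , drop = FALSE], d$d, d$B)
      d_rest <- d$v[1:ck, , drop = FALSE]
      dx_k <- u$bn$bwd(u$relu$bwd(u$conv$bwd(dy_k)))
      d <- st_new(d_rest + dx_k$v, d$d, d$B)
    }
    d
  }
  l
}

# transition: BN - ReLU - 1x1x1 conv compressing channels - 2x2x2 avg pool
nn_transition <- function(c_in, compression) {
  l <- new_layer("transition")
  l$c_out <- max(1L, as.integer(floor(c_in * compression)))
  l$bn <- nn_bn(c_in); l$relu <- nn_relu()
  l$conv <- nn_conv3d(c_in, l$c_out, kernel = c(1, 1, 1), pad = c(0, 0, 0))
  l$pool <- nn_pool3d("avg")
  l$fwd <- function(st, train = TRUE) {
    l$pool$fwd(l$conv$fwd(l$relu$fwd(l$bn$fwd(st, train), train), train), train)
  }
  l$bwd <- function(dst) {
    l$bn$bwd(l$relu$bwd(l$conv$bwd(l$pool$bwd(dst))))
  }
  l
}

# ---- LSTM -------------------------------------------------------------------

# stacked LSTM over a (D, B, T) input array; returns the top layer's final
# hidden state (H x B).  Gate row order inside the stacked parameter
# matrices: forget, input, output, candidate.
nn_lstm <- function(d_in, hidden, layers = 1L, dropout = 0) {
  l <- new_layer("lstm")
  l$hidden <- as.integer(hidden); l$layers <- as.integer(layers)
  l$dropout <- dropout
  for (k in seq_len(layers)) {
    dk <- if (k == 1) d_in else hidden
    sd_w <- 1 / sqrt(dk); sd_u <- 1 / sqrt(hidden)
    l$params[[paste0("W", k)]] <- matrix(stats::rnorm(4 * hidden * dk, 0, sd_w),
                                         4 * hidden, dk)
    l$params[[paste0("U", k)]] <- matrix(stats::rnorm(4 * hidden * hidden, 0, sd_u),
                                         4 * hidden, hidden)
    b <- numeric(4 * hidden)
    b[1:hidden] <- 1  # forget-gate bias init
    l$params[[paste0("b", k)]] <- b
  }
  l$fwd <- function(x, train = TRUE) {
    H <- l$hidden; L <- l$layers
    Tn <- dim(x)[3]; B <- dim(x)[2]
    l$Tn <- Tn; l$B <- B
    l$cache <- vector("list", L)
    inp <- x
    for (k in seq_len(L)) {
      W <- l$params[[paste0("W", k)]]
      U <- l$params[[paste0("U", k)]]
      b <- l$params[[paste0("b", k)]]
      h <- matrix(0, H, B); cc <- matrix(0, H, B)
      steps <- vector("list", Tn)
      outs <- array(0, c(H, B, Tn))
      for (t in seq_len(Tn)) {
        xt <- matrix(inp[, , t], ncol = B)
        z <- W %*% xt + U %*% h + b
        f <- 1 / (1 + exp(-z[1:H, , drop = FALSE]))
        i <- 1 / (1 + exp(-z[(H + 1):(2 * H), , drop = FALSE]))
        o <- 1 / (1 + exp(-z[(2 * H + 1):(3 * H), , drop = FALSE]))
        g <- tanh(z[(3 * H + 1):(4 * H), , drop = FALSE])
        c_new <- f * cc + i * g
        tc <- tanh(c_new)
        h_new <- o * tc
        steps[[t]] <- list(x = xt, h_prev = h, c_prev = cc, f = f, i = i,
                           o = o, g = g, c = c_new, tc = tc)
        h <- h_new; cc <- c_new
        outs[, , t] <- h
      }
      mask <- NULL
      if (train && l$dropout > 0 && k < L) {
        mask <- (array(stats::runif(length(outs)), dim(outs)) >= l$dropout) /
          (1 - l$dropout)
        outs <- outs * mask
      }
      l$cache[[k]] <- list(steps = steps, mask = mask)
      inp <- outs
    }
    matrix(inp[, , Tn], ncol = B)  # final hidden state of top layer
  }
  l$bwd <- function(dh_final) {
    H <- l$hidden; L <- l$layers; Tn <- l$Tn; B <- l$B
    d_out <- array(0, c(H, B, Tn))
    d_out[, , Tn] <- dh_final
    dx_below <- NULL
    for (k in rev(seq_len(L))) {
      ck <- l$cache[[k]]
      if (!is.null(ck$mask)) d_out <- d_out * ck$mask
      W <- l$params[[paste0("W", k)]]
      U <- l$params[[paste0("U", k)]]
      dW <- W * 0; dU <- U * 0; db <- numeric(4 * H)
      dk_in <- ncol(W)
      dx_seq <- array(0, c(dk_in, B, Tn))
      dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
      for (t in rev(seq_len(Tn))) {
        s <- ck$steps[[t]]
        dh <- matrix(d_out[, , t], ncol = B) + dh_next
        dc <- dc_next + dh * s$o * (1 - s$tc^2)
        do_ <- dh * s$tc
        df <- dc * s$c_prev
        di <- dc * s$g
        dg <- dc * s$i
        dz <- rbind(df * s$f * (1 - s$f),
                    di * s$i * (1 - s$i),
                    do_ * s$o * (1 - s$o),
                    dg * (1 - s$g^2))
        dW <- dW + tcrossprod(dz, s$x)
        dU <- dU + tcrossprod(dz, s$h_prev)
        db <- db + rowSums(dz)
        dx_seq[, , t] <- crossprod(W, dz)
        dh_next <- crossprod(U, dz)
        dc_next <- dc * s$f
      }
      l$grads[[paste0("W", k)]] <- dW
      l$grads[[paste0("U", k)]] <- dU
      l$grads[[paste0("b", k)]] <- db
      d_out <- dx_seq
      dx_below <- dx_seq
    }
    dx_below
  }
  l
}

# ---- losses -----------------------------------------------------------------

softmax_cols <- function(z) {
  z <- z - apply(z, 2, max)[col(z)]
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# weighted cross-entropy over logits (K x B); labels: integer 1..K;
# weights: per-class, mean ~ 1.  Returns loss and dlogits.
loss_wce <- function(logits, labels, weights = NULL) {
  K <- nrow(logits); B <- ncol(logits)
  if (is.null(weights)) weights <- rep(1, K)
  p <- softmax_cols(logits)
  idx <- cbind(labels, seq_len(B))
  pt <- p[cbind(labels, seq_len(B))]
  w <- weights[labels]
  loss <- mean(-w * log(pmax(pt, 1e-12)))
  onehot <- matrix(0, K, B)
  onehot[cbind(labels, seq_len(B))] <- 1
  dlogits <- (p - onehot) * rep(w, each = K) / B
  list(loss = loss, grad = dlogits)
}

# mean-squared error over matching arrays; grad wrt prediction
loss_mse <- function(pred, target) {
  d <- pred - target
  list(loss = mean(d^2), grad = 2 * d / length(d))
}

# ---- chain helpers and Adam -------------------------------------------------

net_forward <- function(layers, x, train = TRUE) {
  for (l in layers) x <- l$fwd(x, train)
  x
}

net_backward <- function(layers, dy) {
  for (l in rev(layers)) dy <- l$bwd(dy)
  dy
}

# collect every parameterized layer (descending into composites)
collect_layers <- function(layers) {
  out <- list()
  for (l in layers) {
    if (l$type == "dense_block") {
      for (u in l$units) out <- c(out, list(u$bn, u$conv))
    } else if (l$type == "transition") {
      out <- c(out, list(l$bn, l$conv))
    } else {
      out <- c(out, list(l))
    }
  }
  out
}

adam_new <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  e <- new.env(parent = emptyenv())
  e$lr <- lr; e$beta1 <- beta1; e$beta2 <- beta2; e$eps <- eps
  e$t <- 0L
  e$m <- list(); e$v <- list()
  e
}

adam_step <- function(opt, layers) {
  flat <- collect_layers(layers)
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  corr1 <- 1 - b1^opt$t; corr2 <- 1 - b2^opt$t
  for (li in seq_along(flat)) {
    l <- flat[[li]]
    for (pn in names(l$params)) {
      g <- l$grads[[pn]]
      if (is.null(g)) next
      key <- paste0(li, ".", pn)
      if (is.null(opt$m[[key]])) {
        opt$m[[key]] <- g * 0; opt$v[[key]] <- g * 0
      }
      opt$m[[key]] <- b1 * opt$m[[key]] + (1 - b1) * g
      opt$v[[key]] <- b2 * opt$v[[key]] + (1 - b2) * g * g
      mhat <- opt$m[[key]] / corr1
      vhat <- opt$v[[key]] / corr2
      l$params[[pn]] <- l$params[[pn]] - opt$lr * mhat / (sqrt(vhat) + opt$eps)
    }
  }
  invisible(opt)
}
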