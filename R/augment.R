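# Minority-class expansion: axis flips (x4) and a small 3D GAN per state.

#' Axis-flip augmentation
#'
#' Returns the originals plus the X-, Y- and Z-axis mirror of each sample
#' (not all eight combinations), quadrupling the sample count.  Labels are
#' preserved; flipped copies carry provenance `"flipped"`.  Each flip is an
#' involution and only reorders voxel indices, never altering any value.
#'
#' @param samples List of `class_sample`.
#' @param axes Integer axes to flip along, default `1:3`.
#' @return List of length `(1 + length(axes)) * length(samples)`.
#' @export
flip_augment <- function(samples, axes = 1:3) {
  out <- samples
  for (ax in axes) {
    for (s in samples) {
      out[[length(out) + 1]] <- class_sample(flip_grid(s$grid, ax), s$label,
                                             "flipped")
    }
  }
  out
}

#' Mirror a 3D array along one axis
#' @param grid Numeric 3D array.
#' @param axis Axis index 1..3.
#' @return Flipped array, same dims.
#' @export
flip_grid <- function(grid, axis) {
  d <- dim(grid)
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- rev(idx[[axis]])
  grid[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

#' GAN configuration for minority-class synthesis
#'
#' Generator: 100-dim noise through a fully connected layer to a
#' low-resolution 3D map (5 x 3 x 2), nearest-neighbor upsampling to the
#' full lattice, then three convolution stages refining to one channel.
#' Discriminator: two 3D convolution layers (each with ReLU, dropout and
#' 2x2x2 max-pooling), a fully connected layer, and a sigmoid probability.
#' Training uses the non-saturating adversarial loss with Adam.
#'
#' @param noise_dim Noise vector length.
#' @param gen_channels,disc_channels Base channel counts.
#' @param dropout Discriminator dropout rate.
#' @param lr_g,lr_d Adam learning rates.
#' @param epochs,batch_size Training protocol.
#' @param seed RNG seed.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(noise_dim = 100, gen_channels = 16, disc_channels = 8,
                       dropout = 0.25, lr_g = 2e-4, lr_d = 2e-4,
                       epochs = 200, batch_size = 32, seed = 1L) {
  stopifnot(noise_dim >= 1)
  structure(list(noise_dim = as.integer(noise_dim),
                 gen_channels = gen_channels, disc_channels = disc_channels,
                 dropout = dropout, lr_g = lr_g, lr_d = lr_d,
                 epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "gan_config")
}

build_gan <- function(config, dims = c(10, 6, 4)) {
  gc_ <- config$gen_channels
  low <- (dims + 1L) %/% 2L
  gen <- list(
    fc = nn_linear(config$noise_dim, 2 * gc_ * prod(low)),
    fc_relu = nn_relu(),
    up = nn_upsample2(),
    conv1 = nn_conv3d(2 * gc_, gc_), r1 = nn_relu(),
    conv2 = nn_conv3d(gc_, gc_), r2 = nn_relu(),
    conv3 = nn_conv3d(gc_, 1L)
  )
  dc <- config$disc_channels
  d1 <- (dims + 1L) %/% 2L
  d2 <- (d1 + 1L) %/% 2L
  disc <- list(
    conv1 = nn_conv3d(1L, dc), r1 = nn_relu(), do1 = nn_dropout(config$dropout),
    p1 = nn_pool3d("max"),
    conv2 = nn_conv3d(dc, 2 * dc), r2 = nn_relu(), do2 = nn_dropout(config$dropout),
    p2 = nn_pool3d("max"),
    flat = nn_flatten(),
    fc = nn_linear(2 * dc * prod(d2), 1L)
  )
  list(gen = gen, disc = disc, low = low, dims = as.integer(dims))
}

gan_generate_std <- function(gan, config, z, train = TRUE) {
  B <- ncol(z)
  g <- gan$gen
  h <- g$fc_relu$fwd(g$fc$fwd(z, train), train)
  st <- st_new(matrix(h, nrow = 2 * config$gen_channels), gan$low, B)
  st <- g$up$fwd(st, train)
  st <- g$r1$fwd(g$conv1$fwd(st, train), train)
  st <- g$r2$fwd(g$conv2$fwd(st, train), train)
  g$conv3$fwd(st, train)
}

gan_generator_backward <- function(gan, config, dst) {
  g <- gan$gen
  d <- g$conv3$bwd(dst)
  d <- g$conv1$bwd(g$r1$bwd(g$conv2$bwd(g$r2$bwd(d))))
  d <- g$up$bwd(d)
  dh <- matrix(d$v, ncol = d$B)
  g$fc$bwd(g$fc_relu$bwd(dh))
  invisible(NULL)
}

gan_discriminate <- function(gan, st, train = TRUE) {
  dl <- gan$disc
  h <- dl$p1$fwd(dl$do1$fwd(dl$r1$fwd(dl$conv1$fwd(st, train), train), train), train)
  h <- dl$p2$fwd(dl$do2$fwd(dl$r2$fwd(dl$conv2$fwd(h, train), train), train), train)
  dl$fc$fwd(dl$flat$fwd(h, train), train)  # logits (1 x B)
}

gan_discriminator_backward <- function(gan, dlogit) {
  dl <- gan$disc
  d <- dl$flat$bwd(dl$fc$bwd(dlogit))
  d <- dl$conv2$bwd(dl$r2$bwd(dl$do2$bwd(dl$p2$bwd(d))))
  dl$conv1$bwd(dl$r1$bwd(dl$do1$bwd(dl$p1$bwd(d))))
}

# binary cross-entropy from logits; target y in {0,1}
bce_logits <- function(z, y) {
  p <- 1 / (1 + exp(-z))
  loss <- mean(-(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12))))
  list(loss = loss, grad = (p - y) / length(z), p = p)
}

#' Train a per-state 3D GAN
#'
#' Alternating discriminator/generator updates with the non-saturating
#' adversarial objective, Adam, on standardized grids of a single storage
#' state.  Deterministic under the config seed.
#'
#' @param real List of `class_sample`, all one label, at least 8.
#' @param config A [gan_config].
#' @return An object of class `gan_bundle`: `gan` (parameters), `stats`
#'   (standardization used), `state` (the label), `config`, `history`
#'   (per-epoch generator/discriminator losses).
#' @export
train_gan <- function(real, config = gan_config()) {
  if (length(real) < 8) stop("need at least 8 real samples to train a GAN")
  labs <- unique(vapply(real, function(s) s$label, ""))
  if (length(labs) != 1) stop("all GAN training samples must share one label")
  dims <- dim(real[[1]]$grid)
  stats <- standardization_stats(unlist(lapply(real, function(s) as.vector(s$grid))))
  X <- vapply(real, function(s) standardize(as.vector(s$grid), stats),
              numeric(prod(dims)))

  with_seed(config$seed, {
    gan <- build_gan(config, dims)
    opt_g <- adam_new(lr = config$lr_g, beta1 = 0.5)
    opt_d <- adam_new(lr = config$lr_d, beta1 = 0.5)
    hist <- data.frame()
    n <- length(real)
    S <- prod(dims)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      gl <- 0; dl_ <- 0; nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        B <- length(idx)
        real_st <- st_new(matrix(as.vector(X[, idx]), nrow = 1), dims, B)
        # --- discriminator step
        z <- matrix(stats::rnorm(config$noise_dim * B), config$noise_dim)
        fake_st <- gan_generate_std(gan, config, z, train = TRUE)
        lr_real <- bce_logits(gan_discriminate(gan, real_st, TRUE), 1)
        g_real <- lr_real$grad
        gr_d1 <- gan_discriminator_backward(gan, g_real)
        snap_dgrads <- lapply(collect_layers(gan$disc), function(l) l$grads)
        lr_fake <- bce_logits(gan_discriminate(gan, fake_st, TRUE), 0)
        gan_discriminator_backward(gan, lr_fake$grad)
        # accumulate the two passes' gradients, then step D
        flat_d <- collect_layers(gan$disc)
        for (i in seq_along(flat_d)) {
          for (pn in names(flat_d[[i]]$grads)) {
            flat_d[[i]]$grads[[pn]] <- flat_d[[i]]$grads[[pn]] +
              snap_dgrads[[i]][[pn]]
          }
        }
        adam_step(opt_d, gan$disc)
        # --- generator step (non-saturating: push D(G(z)) toward 1)
        z <- matrix(stats::rnorm(config$noise_dim * B), config$noise_dim)
        fake_st <- gan_generate_std(gan, config, z, train = TRUE)
        lg <- bce_logits(gan_discriminate(gan, fake_st, TRUE), 1)
        dfake <- gan_discriminator_backward(gan, lg$grad)
        gan_generator_backward(gan, config, dfake)
        adam_step(opt_g, gan$gen)
        gl <- gl + lg$loss; dl_ <- dl_ + lr_real$loss + lr_fake$loss
        nb <- nb + 1L
      }
      hist <- rbind(hist, data.frame(epoch = epoch, g_loss = gl / nb,
                                     d_loss = dl_ / nb))
    }
    structure(list(gan = gan, stats = stats, state = labs, config = config,
                   history = hist, dims = dims),
              class = "gan_bundle")
  })
}

#' Generate synthetic samples from a trained GAN
#'
#' @param bundle A `gan_bundle`.
#' @param n Number of samples.
#' @param seed RNG seed.
#' @return List of `class_sample` with provenance `"gan"` and the bundle's
#'   label, in raw degC (destandardized).
#' @export
gan_generate <- function(bundle, n, seed = 1L) {
  if (n == 0) return(list())
  with_seed(seed, {
    z <- matrix(stats::rnorm(bundle$config$noise_dim * n),
                bundle$config$noise_dim)
    st <- gan_generate_std(bundle$gan, bundle$config, z, train = FALSE)
    S <- prod(bundle$dims)
    lapply(seq_len(n), function(b) {
      g <- array(st$v[1, (b - 1) * S + seq_len(S)], bundle$dims)
      class_sample(destandardize(g, bundle$stats), bundle$state, "gan")
    })
  })
}

#' Discriminator probability that grids are real
#' @param bundle A `gan_bundle`.
#' @param samples List of `class_sample` (raw degC).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
gan_discriminator_prob <- function(bundle, samples) {
  X <- vapply(samples, function(s) standardize(as.vector(s$grid), bundle$stats),
              numeric(prod(bundle$dims)))
  st <- st_new(matrix(as.vector(X), nrow = 1), bundle$dims, length(samples))
  as.vector(1 / (1 + exp(-gan_discriminate(bundle$gan, st, train = FALSE))))
}

#' Rebalance a labelled dataset to exact per-class targets
#'
#' Classes above target are randomly downsampled (seeded).  Classes below
#' target are expanded by axis flips first; any remainder is filled with
#' GAN samples trained on that class's original pool.  No sample changes
#' label, and final counts equal the targets exactly.
#'
#' @param samples List of `class_sample`.
#' @param targets Named integer vector/list, state -> target count.
#' @param config A [gan_config] (used only if GAN filling is needed).
#' @param seed RNG seed.
#' @return List of `class_sample`.
#' @export
rebalance <- function(samples, targets, config = gan_config(), seed = 1L) {
  targets <- unlist(targets)
  labels <- vapply(samples, function(s) s$label, "")
  out <- list()
  with_seed(seed, {
    for (state in names(targets)) {
      pool <- samples[labels == state]
      tgt <- targets[[state]]
      n <- length(pool)
      if (tgt <= n) {
        keep <- if (tgt == n) seq_len(n) else sample(n, tgt)
        out <- c(out, pool[keep])
        next
      }
      expanded <- flip_augment(pool)
      if (tgt <= length(expanded)) {
        out <- c(out, expanded[seq_len(tgt)])
        next
      }
      if (n < 8) {
        stop("class '", state, "': target ", tgt, " needs GAN filling but only ",
             n, " originals are available (minimum 8)")
      }
      bundle <- train_gan(pool, config)
      extra <- gan_generate(bundle, tgt - length(expanded),
                            seed = derive_seed(seed, match(state, storage_states())))
      out <- c(out, expanded, extra)
    }
  })
  out
}
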