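# Six-way storage-state classifier: a compact 3D DenseNet over the
# 10 x 6 x 4 model lattice.

#' DenseNet classifier configuration
#'
#' Defaults follow the tuned operating point: learning rate 1e-3, 32 base
#' channels, dropout 0.3, three dense blocks of four layers, compression
#' 0.5.  Growth rate defaults to `base_channels`.
#'
#' @param learning_rate Adam learning rate.
#' @param base_channels Stem convolution output channels.
#' @param dropout Dropout rate before the classification head.
#' @param num_dense_blocks,layers_per_block Dense architecture depth.
#' @param compression Transition-layer channel compression in (0, 1].
#' @param growth_rate Channels added by each dense layer.
#' @param batch_size,max_epochs,patience Training protocol: minibatch size,
#'   epoch cap, and early-stopping patience on validation loss.
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @return An object of class `densenet_config`.
#' @export
densenet_config <- function(learning_rate = 0.001, base_channels = 32,
                            dropout = 0.3, num_dense_blocks = 3,
                            layers_per_block = 4, compression = 0.5,
                            growth_rate = base_channels, batch_size = 64,
                            max_epochs = 200, patience = 10, seed = 1L) {
  stopifnot(compression > 0, compression <= 1, num_dense_blocks >= 1,
            layers_per_block >= 1)
  structure(list(learning_rate = learning_rate, base_channels = base_channels,
                 dropout = dropout, num_dense_blocks = num_dense_blocks,
                 layers_per_block = layers_per_block, compression = compression,
                 growth_rate = growth_rate, batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "densenet_config")
}

#' Build an untrained 3D DenseNet classifier
#'
#' Architecture: initial 3x3x3 convolution, then `num_dense_blocks` dense
#' blocks (each layer BN-ReLU-conv, input = concatenation of all earlier
#' outputs in the block) separated by transition layers (1x1x1 compressing
#' convolution + 2x2x2 average pooling), then BN-ReLU, global average
#' pooling, dropout, and a fully connected softmax-6 head.
#'
#' @param config A [densenet_config].
#' @param input_dims Input lattice, default `c(10, 6, 4)`.
#' @return An object of class `classifier_model` (untrained; no
#'   standardization stats yet).  `$shapes` logs the per-stage channel and
#'   spatial dims.
#' @export
build_classifier <- function(config = densenet_config(),
                             input_dims = c(10, 6, 4)) {
  with_seed(config$seed, {
    layers <- list()
    shapes <- list()
    d <- as.integer(input_dims)
    layers$stem <- nn_conv3d(1L, config$base_channels)
    ch <- config$base_channels
    shapes$stem <- list(channels = ch, dims = d)
    for (b in seq_len(config$num_dense_blocks)) {
      blk <- nn_dense_block(ch, config$layers_per_block, config$growth_rate)
      layers[[paste0("block", b)]] <- blk
      ch <- blk$c_out
      shapes[[paste0("block", b)]] <- list(channels = ch, dims = d)
      if (b < config$num_dense_blocks) {
        if (all(d == 1L)) {
          stop("spatial dimensions already collapsed to 1x1x1 at transition ", b)
        }
        tr <- nn_transition(ch, config$compression)
        layers[[paste0("transition", b)]] <- tr
        ch <- tr$c_out
        d <- (d + 1L) %/% 2L
        shapes[[paste0("transition", b)]] <- list(channels = ch, dims = d)
      }
    }
    layers$final_bn <- nn_bn(ch)
    layers$final_relu <- nn_relu()
    layers$gap <- nn_gap()
    layers$dropout <- nn_dropout(config$dropout)
    layers$head <- nn_linear(ch, 6L)
    shapes$head <- list(channels = 6L, dims = c(1L, 1L, 1L))
    structure(list(layers = layers, config = config, stats = NULL,
                   classes = storage_states(), input_dims = as.integer(input_dims),
                   shapes = shapes),
              class = "classifier_model")
  })
}

#' Total trainable parameter count of a model
#' @param model A `classifier_model` or `forecaster_model`.
#' @return Integer parameter count.
#' @export
count_parameters <- function(model) {
  sum(vapply(collect_layers(model$layers),
             function(l) sum(vapply(l$params, length, 0L)), 0L))
}

# stack class_sample grids into the (1, S*B) input matrix
samples_to_input <- function(samples, stats = NULL) {
  S <- length(samples[[1]]$grid)
  v <- vapply(samples, function(s) as.vector(s$grid), numeric(S))
  if (!is.null(stats)) v <- standardize(v, stats)
  st_new(matrix(as.vector(v), nrow = 1), dim(samples[[1]]$grid), length(samples))
}

sample_labels <- function(samples) {
  match(vapply(samples, function(s) s$label, ""), storage_states())
}

#' Stratified train/validation/test split
#'
#' Seeded, stratified by label, with largest-remainder rounding so the
#' fractions are honored within one sample per class.
#'
#' @param samples List of `class_sample`.
#' @param fractions Length-3 fractions summing to 1, default (0.70, 0.15, 0.15).
#' @param seed Integer seed.
#' @return List with `train`, `val`, `test` (lists of samples) and `index`
#'   (the assignment, by input position).
#' @export
split_dataset <- function(samples, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9)
  labels <- vapply(samples, function(s) s$label, "")
  assign <- integer(length(samples))
  with_seed(seed, {
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      if (length(idx) < 3) {
        stop("class '", cls, "' has fewer than 3 samples; cannot split")
      }
      idx <- sample(idx)
      n <- length(idx)
      base <- floor(fractions * n)
      rem <- fractions * n - base
      left <- n - sum(base)
      if (left > 0) {
        base[order(rem, decreasing = TRUE)[seq_len(left)]] <-
          base[order(rem, decreasing = TRUE)[seq_len(left)]] + 1
      }
      parts <- rep(1:3, times = base)
      assign[idx] <- parts
    }
  })
  list(train = samples[assign == 1], val = samples[assign == 2],
       test = samples[assign == 3], index = assign)
}

#' Inverse-frequency class weights
#'
#' `w_c = N_total / (6 * n_c)`, then normalized to mean 1, so rarer classes
#' never receive smaller weights and balanced data gives all-ones.
#'
#' @param labels Character or factor vector of training labels; every one of
#'   the six states must be present.
#' @return Named numeric weight vector over [storage_states()].
#' @export
class_weights <- function(labels) {
  st <- as_storage_state(labels)
  n_c <- table(st)
  if (any(n_c == 0)) {
    stop("empty class(es): ",
         paste(names(n_c)[n_c == 0], collapse = ", "))
  }
  w <- length(labels) / (6 * as.numeric(n_c))
  w <- w / mean(w)
  stats::setNames(w, storage_states())
}

# snapshot/restore trainable parameters AND batchnorm running statistics
# (restoring weights without their matching running stats skews evaluation)
snapshot_params <- function(layers) {
  lapply(collect_layers(layers), function(l) {
    list(params = l$params, run_mean = l$run_mean, run_var = l$run_var)
  })
}

restore_params <- function(layers, snap) {
  flat <- collect_layers(layers)
  for (i in seq_along(flat)) {
    flat[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      flat[[i]]$run_mean <- snap[[i]]$run_mean
      flat[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(NULL)
}

# forward a sample list in memory-bounded chunks; returns the (6 x n) logits
classifier_logits <- function(model, samples, chunk = 128L) {
  out <- matrix(0, 6, length(samples))
  for (start in seq(1, length(samples), by = chunk)) {
    idx <- start:min(start + chunk - 1L, length(samples))
    inp <- samples_to_input(samples[idx], model$stats)
    out[, idx] <- net_forward(model$layers, inp, train = FALSE)
  }
  out
}

eval_classifier_loss <- function(model, samples, weights) {
  logits <- classifier_logits(model, samples)
  y <- sample_labels(samples)
  r <- loss_wce(logits, y, weights)
  pred <- apply(logits, 2, which.max)
  list(loss = r$loss, acc = mean(pred == y))
}

#' Train the storage-state classifier
#'
#' Stratified 70/15/15 split (unless a `split` is supplied), standardization
#' statistics from the training partition only, Adam with weighted
#' cross-entropy, early stopping on validation loss with best-weight
#' restore.  Seeded and reproducible.
#'
#' @param samples List of `class_sample` with raw (degC) grids.
#' @param config A [densenet_config].
#' @param split Optional precomputed split from [split_dataset()].
#' @return List with `model` (a trained `classifier_model`), `history`
#'   (data.frame: epoch, train_loss, train_acc, val_loss, val_acc),
#'   `best_epoch`, `stopped_epoch`, and `split`.
#' @export
train_classifier <- function(samples, config = densenet_config(),
                             split = NULL) {
  if (is.null(split)) split <- split_dataset(samples, seed = config$seed)
  train <- split$train; val <- split$val
  stats <- standardization_stats(
    unlist(lapply(train, function(s) as.vector(s$grid))))
  model <- build_classifier(config, input_dims = dim(train[[1]]$grid))
  model$stats <- stats
  weights <- class_weights(vapply(train, function(s) s$label, ""))
  y_train <- sample_labels(train)

  opt <- adam_new(lr = config$learning_rate)
  hist <- data.frame()
  best_val <- Inf; best_epoch <- 0L; best_snap <- NULL; wait <- 0L
  n <- length(train)

  with_seed(derive_seed(config$seed, 101L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; ep_acc <- 0; nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        inp <- samples_to_input(train[idx], stats)
        logits <- net_forward(model$layers, inp, train = TRUE)
        r <- loss_wce(logits, y_train[idx], weights)
        if (!is.finite(r$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        net_backward(model$layers, r$grad)
        adam_step(opt, model$layers)
        pred <- apply(logits, 2, which.max)
        ep_loss <- ep_loss + r$loss
        ep_acc <- ep_acc + mean(pred == y_train[idx])
        nb <- nb + 1L
      }
      vl <- eval_classifier_loss(model, val, weights)
      hist <- rbind(hist, data.frame(
        epoch = epoch, train_loss = ep_loss / nb, train_acc = ep_acc / nb,
        val_loss = vl$loss, val_acc = vl$acc))
      if (vl$loss < best_val - 1e-6) {
        best_val <- vl$loss; best_epoch <- epoch
        best_snap <- snapshot_params(model$layers); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model$layers, best_snap)
  list(model = model, history = hist, best_epoch = best_epoch,
       stopped_epoch = nrow(hist), split = split)
}

#' Nearest-centroid baseline classifier accuracy
#'
#' Pattern-space nearest-centroid: each grid is mean-centered (removing the
#' seasonal level), class centroids are computed on the training samples,
#' and test samples take the label of the nearest centroid.  A sanity
#' baseline guarding against degenerate class signal, not a model.
#'
#' @param train,test Lists of `class_sample`.
#' @param center Mean-center each grid first (default `TRUE`).
#' @return Test accuracy in `[0, 1]`.
#' @export
nearest_centroid_accuracy <- function(train, test, center = TRUE) {
  feat <- function(s) {
    v <- as.vector(s$grid)
    if (center) v - mean(v) else v
  }
  labs <- vapply(train, function(s) s$label, "")
  cls <- unique(labs)
  cents <- vapply(cls, function(cl) {
    rowMeans(vapply(train[labs == cl], feat, numeric(length(feat(train[[1]])))))
  }, numeric(length(feat(train[[1]]))))
  pred <- vapply(test, function(s) {
    d2 <- colSums((cents - feat(s))^2)
    cls[which.min(d2)]
  }, "")
  mean(pred == vapply(test, function(s) s$label, ""))
}

#' Classify storage-state grids
#'
#' @param model A trained `classifier_model`.
#' @param grids A single 3D array / [temperature_grid] / `class_sample`, or a
#'   list of them, in raw degC on the model lattice (standardization is
#'   applied internally with the model's training stats).
#' @return For a single grid, a list with `state` and `prob` (named 6-vector);
#'   for a list, a data.frame of states plus a probability matrix attribute.
#' @export
classify <- function(model, grids) {
  single <- !is.list(grids) || inherits(grids, c("temperature_grid", "class_sample"))
  if (single) grids <- list(grids)
  grids <- lapply(grids, function(g) {
    if (inherits(g, "temperature_grid")) g <- g$values
    if (inherits(g, "class_sample")) g <- g$grid
    if (!identical(as.integer(dim(g)), model$input_dims)) {
      stop("grid dims ", paste(dim(g), collapse = "x"),
           " do not match model input ",
           paste(model$input_dims, collapse = "x"))
    }
    class_sample(g, "normal")
  })
  logits <- classifier_logits(model, grids)
  probs <- softmax_cols(logits)
  rownames(probs) <- model$classes
  states <- model$classes[apply(probs, 2, which.max)]
  if (single) {
    return(list(state = states[1], prob = probs[, 1]))
  }
  out <- data.frame(state = states, stringsAsFactors = FALSE)
  attr(out, "prob") <- t(probs)
  out
}
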