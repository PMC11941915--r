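# Two-channel 3DCNN-LSTM temperature-field forecaster: a 35-day window of
# (temperature, absolute water potential) grids predicts the next 10 daily
# temperature grids in one shot.

#' Forecaster configuration
#'
#' @param learning_rate Adam learning rate.
#' @param lstm_hidden,lstm_layers Stacked LSTM geometry.
#' @param dropout Dropout between LSTM layers.
#' @param window Input window length T in days.
#' @param horizon Forecast horizon P in days.
#' @param channels 2 (temperature + absolute water potential) or 1
#'   (temperature only; the single-channel ablation variant).
#' @param conv_channels,conv_kernel Per-frame 3D convolution plan (padding
#'   preserves dims; a 2x2x2 max-pool follows).
#' @param embed_dim Per-frame embedding size fed to the LSTM.
#' @param trend_window Days over which the per-voxel drift anchor is
#'   measured (the head predicts corrections to persistence + drift).
#' @param batch_size,max_epochs,patience Training protocol.
#' @param seed RNG seed.
#' @return An object of class `forecast_config`.
#' @export
forecast_config <- function(learning_rate = 0.001, lstm_hidden = 128,
                            lstm_layers = 3, dropout = 0.5, window = 35,
                            horizon = 10, channels = 2, conv_channels = 16,
                            conv_kernel = c(3, 3, 3), embed_dim = 256,
                            trend_window = 10, batch_size = 16,
                            max_epochs = 200, patience = 10, seed = 1L) {
  stopifnot(window >= 1, horizon >= 1, channels %in% c(1, 2))
  structure(list(learning_rate = learning_rate, lstm_hidden = lstm_hidden,
                 lstm_layers = lstm_layers, dropout = dropout,
                 window = as.integer(window), horizon = as.integer(horizon),
                 channels = as.integer(channels),
                 conv_channels = conv_channels, conv_kernel = conv_kernel,
                 embed_dim = embed_dim, trend_window = as.integer(trend_window),
                 batch_size = batch_size,
                 max_epochs = max_epochs, patience = patience,
                 seed = as.integer(seed)),
            class = "forecast_config")
}

# ---- reference (oracle) implementations ------------------------------------

#' Brute-force 3D convolution (testing oracle)
#'
#' Direct triple-sum evaluation of the valid 3D convolution
#' `O(i,j,k) = sum_m sum_n sum_p W(m,n,p) * I(i+m, j+n, k+p) + b`,
#' optionally on a zero-padded input.  Exists solely as an independent
#' reference for the production convolution; do not use it for training.
#'
#' @param input Numeric 3D array.
#' @param W Numeric 3D kernel array.
#' @param b Scalar bias.
#' @param pad Integer zero-padding per axis.
#' @return Numeric 3D output array.
#' @export
conv3d_reference <- function(input, W, b = 0, pad = c(0, 0, 0)) {
  stopifnot(length(dim(input)) == 3, length(dim(W)) == 3)
  d <- dim(input); k <- dim(W); pad <- rep(as.integer(pad), length.out = 3)
  dp <- d + 2L * pad
  x <- array(0, dp)
  x[pad[1] + seq_len(d[1]), pad[2] + seq_len(d[2]), pad[3] + seq_len(d[3])] <- input
  do <- dp - k + 1L
  if (any(do < 1)) stop("kernel larger than (padded) input")
  out <- array(0, do)
  for (i in seq_len(do[1])) for (j in seq_len(do[2])) for (kk in seq_len(do[3])) {
    acc <- 0
    for (m in seq_len(k[1])) for (n in seq_len(k[2])) for (p in seq_len(k[3])) {
      acc <- acc + W[m, n, p] * x[i + m - 1, j + n - 1, kk + p - 1]
    }
    out[i, j, kk] <- acc + b
  }
  out
}

#' One literal LSTM cell step (testing oracle)
#'
#' Evaluates the gate equations exactly as written: forget
#' `F = sigma(Wf X + Uf H_prev + bf)`, input `I`, candidate
#' `G = tanh(Wc X + Uc H_prev + bc)`, output `O`, then
#' `C = F * C_prev + I * G` and `H = O * tanh(C)`.  Reference for the
#' production recurrent unit.
#'
#' @param X_t Input column vector (or matrix D x B).
#' @param H_prev,C_prev Previous hidden/cell state (H x B).
#' @param params List with `Wf, Uf, bf, Wi, Ui, bi, Wo, Uo, bo, Wc, Uc, bc`.
#' @return List with `H`, `C` and `gates` (`F`, `I`, `O`, `G`).
#' @export
lstm_cell_reference <- function(X_t, H_prev, C_prev, params) {
  sg <- function(z) 1 / (1 + exp(-z))
  F_t <- sg(params$Wf %*% X_t + params$Uf %*% H_prev + params$bf)
  I_t <- sg(params$Wi %*% X_t + params$Ui %*% H_prev + params$bi)
  G_t <- tanh(params$Wc %*% X_t + params$Uc %*% H_prev + params$bc)
  O_t <- sg(params$Wo %*% X_t + params$Uo %*% H_prev + params$bo)
  C_t <- F_t * C_prev + I_t * G_t
  H_t <- O_t * tanh(C_t)
  list(H = H_t, C = C_t, gates = list(F = F_t, I = I_t, O = O_t, G = G_t))
}

# ---- window extraction ------------------------------------------------------

#' Extract sliding windows from preprocessed series
#'
#' Runs the preprocessing chain on each series, computes the absolute-water-
#' potential channel (when `channels = 2`), and cuts stride-1 windows of
#' `window` input days and `horizon` target days: per series of length L,
#' `L - window - horizon + 1` windows.  A chronological 70/15/15 split is
#' applied per series at day boundaries; windows whose target days cross a
#' boundary are dropped, so no test target day ever appears in a training
#' window.
#'
#' @param series_list A [granary_series] or list of them.
#' @param config A [forecast_config].
#' @param coeffs A [grain_coefficients] (used when `channels = 2`; variety
#'   taken per series when `NULL`).
#' @param preprocessed Set `TRUE` if the series are already cleaned/imputed/
#'   resized to the model lattice.
#' @return List of `window_sample` objects: `input` array (T, X, Y, Z, C) in
#'   raw units, `target` array (P, X, Y, Z) in degC, `series_id`, `start`
#'   (1-based first input day), `split` in {"train","val","test"}.
#' @export
make_windows <- function(series_list, config = forecast_config(),
                         coeffs = NULL, preprocessed = FALSE) {
  if (inherits(series_list, "granary_series")) series_list <- list(series_list)
  Tn <- config$window; P <- config$horizon
  out <- list()
  for (ser in series_list) {
    L <- length(ser$days)
    if (L < Tn + P) {
      stop("series '", ser$granary_id, "' has ", L,
           " days; need at least ", Tn + P)
    }
    pp <- if (preprocessed) ser else preprocess_series(ser)
    arr <- series_array(pp)                      # (10,6,4,L)
    d <- dim(arr)[1:3]
    awp_arr <- NULL
    if (config$channels == 2) {
      co <- coeffs %||% grain_coefficients(ser$variety)
      moist <- series_moisture(pp)
      awp_arr <- array(0, dim(arr))
      for (t in seq_len(L)) {
        awp_arr[, , , t] <- awp_field(arr[, , , t, drop = TRUE], moist[t], co)
      }
    }
    L1 <- floor(0.70 * L); L2 <- floor(0.85 * L)
    for (i in seq_len(L - Tn - P + 1)) {
      t0 <- i + Tn          # first target day
      t1 <- i + Tn + P - 1  # last target day
      # windows whose target days cross a split boundary stay unassigned
      split <- if (t1 <= L1) "train"
        else if (t0 > L1 && t1 <= L2) "val"
        else if (t0 > L2) "test"
        else NA_character_
      input <- array(0, c(Tn, d, config$channels))
      for (t in seq_len(Tn)) {
        input[t, , , , 1] <- arr[, , , i + t - 1]
        if (config$channels == 2) input[t, , , , 2] <- awp_arr[, , , i + t - 1]
      }
      target <- array(0, c(P, d))
      for (p in seq_len(P)) target[p, , , ] <- arr[, , , t0 + p - 1]
      out[[length(out) + 1]] <- structure(
        list(input = input, target = target, series_id = ser$granary_id,
             start = i, split = split),
        class = "window_sample")
    }
  }
  out
}

# stack windows into the conv input matrix (C, S*T*B), frame index t fastest
windows_to_input <- function(windows, stats = NULL) {
  Tn <- dim(windows[[1]]$input)[1]
  d <- dim(windows[[1]]$input)[2:4]
  C <- dim(windows[[1]]$input)[5]
  S <- prod(d)
  B <- length(windows)
  v <- matrix(0, C, S * Tn * B)
  for (b in seq_len(B)) {
    w <- windows[[b]]$input  # (T, X, Y, Z, C)
    for (ch in seq_len(C)) {
      x <- aperm(w[, , , , ch, drop = FALSE][, , , , 1], c(2, 3, 4, 1)) # (X,Y,Z,T)
      if (!is.null(stats)) x <- standardize(x, stats, ch)
      v[ch, (b - 1) * S * Tn + seq_len(S * Tn)] <- as.vector(x)
    }
  }
  list(v = v, d = d, Tn = Tn, B = B)
}

windows_to_target <- function(windows, stats = NULL) {
  P <- dim(windows[[1]]$target)[1]
  S <- prod(dim(windows[[1]]$target)[2:4])
  m <- vapply(windows, function(w) {
    x <- aperm(w$target, c(2, 3, 4, 1))  # (X,Y,Z,P), voxel-fastest
    as.vector(x)
  }, numeric(P * S))
  m <- matrix(m, nrow = P * S)
  if (!is.null(stats)) m <- standardize(m, stats, 1)
  m
}

# ---- model ------------------------------------------------------------------

#' Build an untrained 3DCNN-LSTM forecaster
#'
#' Per-frame path: 3D convolution (padding preserves dims) - ReLU - 2x2x2
#' max-pool - flatten - fully connected embedding - ReLU.  The T per-frame
#' embeddings form the input sequence of a stacked LSTM; the final hidden
#' state is mapped by a fully connected output layer to P x (X*Y*Z) values,
#' reshaped to (P, X, Y, Z).
#'
#' @param config A [forecast_config].
#' @param input_dims Spatial lattice, default `c(10, 6, 4)`.
#' @return An object of class `forecaster_model`.
#' @export
build_forecaster <- function(config = forecast_config(),
                             input_dims = c(10, 6, 4)) {
  with_seed(config$seed, {
    d <- as.integer(input_dims)
    dp <- (d + 1L) %/% 2L
    flat_dim <- config$conv_channels * prod(dp)
    S <- prod(d)
    layers <- list(
      conv = nn_conv3d(config$channels, config$conv_channels,
                       kernel = config$conv_kernel),
      conv_relu = nn_relu(),
      pool = nn_pool3d("max"),
      flatten = nn_flatten(),
      embed = nn_linear(flat_dim, config$embed_dim),
      embed_relu = nn_relu(),
      lstm = nn_lstm(config$embed_dim, config$lstm_hidden, config$lstm_layers,
                     config$dropout),
      head = nn_linear(config$lstm_hidden, config$horizon * S)
    )
    # near-zero head: the residual forecaster starts at the persistence
    # solution and learns corrections
    layers$head$params$W <- layers$head$params$W * 0.01
    structure(list(layers = layers, config = config, stats = NULL,
                   input_dims = d, coeffs = NULL),
              class = "forecaster_model")
  })
}

# forward pass over a packed batch; returns (P*S, B) predictions in
# standardized space.  The head is residual on a persistence + drift anchor:
# horizon day p is predicted as last_frame + p * drift + correction, where
# drift is the per-voxel mean daily change over the final `trend_window`
# input days.  The network therefore learns corrections to a standard
# drift-extrapolation baseline rather than absolute temperature levels —
# local ramps (mildew heating, condensation gradients) are extrapolated by
# the anchor and damped or sharpened by the learned correction.
forecaster_forward <- function(model, packed, train = TRUE) {
  ly <- model$layers
  Tn <- packed$Tn; B <- packed$B
  S <- prod(packed$d)
  st <- st_new(packed$v, packed$d, Tn * B)
  h <- ly$flatten$fwd(ly$pool$fwd(ly$conv_relu$fwd(ly$conv$fwd(st, train), train), train), train)
  e <- ly$embed_relu$fwd(ly$embed$fwd(h, train), train)   # (E, T*B), t fastest
  E <- nrow(e)
  seqs <- aperm(array(e, c(E, Tn, B)), c(1, 3, 2))        # (E, B, T)
  hT <- ly$lstm$fwd(seqs, train)
  y <- ly$head$fwd(hT, train)
  frame_cols <- function(t) outer(seq_len(S), (seq_len(B) - 1L) * S * Tn +
                                    (t - 1L) * S, "+")
  last <- matrix(packed$v[1, frame_cols(Tn)], S, B)
  K <- min(model$config$trend_window %||% 10L, Tn - 1L)
  drift <- if (K >= 1) {
    (last - matrix(packed$v[1, frame_cols(Tn - K)], S, B)) / K
  } else matrix(0, S, B)
  P <- nrow(y) / S
  rowsel <- rep(seq_len(S), P)
  y + last[rowsel, , drop = FALSE] +
    rep(seq_len(P), each = S) * drift[rowsel, , drop = FALSE]
}

forecaster_backward <- function(model, dout) {
  ly <- model$layers
  dhT <- ly$head$bwd(dout)
  dseqs <- ly$lstm$bwd(dhT)                               # (E, B, T)
  E <- dim(dseqs)[1]; B <- dim(dseqs)[2]; Tn <- dim(dseqs)[3]
  de <- matrix(aperm(dseqs, c(1, 3, 2)), E, Tn * B)
  dh <- ly$embed$bwd(ly$embed_relu$bwd(de))
  ly$conv$bwd(ly$conv_relu$bwd(ly$pool$bwd(ly$flatten$bwd(dh))))
  invisible(NULL)
}

eval_forecaster <- function(model, windows, batch_size = 32) {
  if (length(windows) == 0) return(list(mse = NA_real_, mae = NA_real_))
  se <- 0; ae <- 0; n <- 0
  for (start in seq(1, length(windows), by = batch_size)) {
    idx <- start:min(start + batch_size - 1, length(windows))
    packed <- windows_to_input(windows[idx], model$stats)
    pred_std <- forecaster_forward(model, packed, train = FALSE)
    tgt <- windows_to_target(windows[idx], NULL)
    pred <- destandardize(pred_std, model$stats, 1)
    se <- se + sum((pred - tgt)^2); ae <- ae + sum(abs(pred - tgt))
    n <- n + length(tgt)
  }
  list(mse = se / n, mae = ae / n)
}

#' Train the temperature-field forecaster
#'
#' Adam on mean-squared error over standardized targets, chronological
#' train/val/test windows (from [make_windows()]), early stopping on
#' validation loss with best-weight restore.  Standardization statistics per
#' channel come from the training windows only.
#'
#' @param windows Output of [make_windows()].
#' @param config A [forecast_config].
#' @return List with `model` (trained `forecaster_model`), `history`,
#'   `best_epoch`, `stopped_epoch`, and the train/val/test window lists.
#' @export
train_forecaster <- function(windows, config = forecast_config()) {
  train <- Filter(function(w) isTRUE(w$split == "train"), windows)
  val <- Filter(function(w) isTRUE(w$split == "val"), windows)
  test <- Filter(function(w) isTRUE(w$split == "test"), windows)
  if (length(train) == 0) stop("no training windows")
  d <- dim(train[[1]]$input)[2:4]

  chans <- lapply(seq_len(config$channels), function(ch) {
    unlist(lapply(train, function(w) as.vector(w$input[, , , , ch])))
  })
  stats <- standardization_stats(chans)

  model <- build_forecaster(config, input_dims = d)
  model$stats <- stats
  opt <- adam_new(lr = config$learning_rate)
  hist <- data.frame()
  best_val <- Inf; best_epoch <- 0L; best_snap <- NULL; wait <- 0L
  n <- length(train)

  with_seed(derive_seed(config$seed, 202L), {
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      ep_loss <- 0; nb <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1, n)]
        packed <- windows_to_input(train[idx], stats)
        pred <- forecaster_forward(model, packed, train = TRUE)
        tgt <- windows_to_target(train[idx], stats)
        r <- loss_mse(pred, tgt)
        if (!is.finite(r$loss)) {
          stop("training diverged (non-finite loss) at epoch ", epoch)
        }
        forecaster_backward(model, r$grad)
        adam_step(opt, model$layers)
        ep_loss <- ep_loss + r$loss; nb <- nb + 1L
      }
      vl <- if (length(val) > 0) {
        ev <- eval_forecaster(model, val)
        (ev$mae / stats$sd[1])  # scale-free monitor
      } else ep_loss / nb
      ev_mae <- if (length(val) > 0) eval_forecaster(model, val)$mae else NA_real_
      hist <- rbind(hist, data.frame(epoch = epoch, train_loss = ep_loss / nb,
                                     val_mae = ev_mae))
      if (vl < best_val - 1e-6) {
        best_val <- vl; best_epoch <- epoch
        best_snap <- snapshot_params(model$layers); wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$patience) break
      }
    }
  })
  if (!is.null(best_snap)) restore_params(model$layers, best_snap)
  list(model = model, history = hist, best_epoch = best_epoch,
       stopped_epoch = nrow(hist), train = train, val = val, test = test)
}

#' Forecast the next P daily temperature grids
#'
#' @param model A trained `forecaster_model`.
#' @param series A [granary_series] whose tail supplies the input window;
#'   preprocessed internally unless `preprocessed = TRUE`.
#' @param coeffs Optional [grain_coefficients] for the water-potential
#'   channel (defaults to the series variety).
#' @param preprocessed Set `TRUE` if already on the model lattice with no
#'   missing voxels.
#' @return Numeric array (P, X, Y, Z) of predicted temperatures, degC.
#' @export
forecast <- function(model, series, coeffs = NULL, preprocessed = FALSE) {
  cfg <- model$config
  L <- length(series$days)
  if (L < cfg$window) {
    stop("series tail has ", L, " days; the model needs ", cfg$window)
  }
  pp <- if (preprocessed) series else preprocess_series(series)
  # keep only the last T days
  keep <- (L - cfg$window + 1):L
  moist_all <- if (all(is.na(pp$moisture))) pp$moisture else series_moisture(pp)
  tail_ser <- granary_series(pp$granary_id, pp$variety, pp$days[keep],
                             pp$grids[keep], moist_all[keep], pp$region)
  arr <- series_array(tail_ser)
  d <- dim(arr)[1:3]
  input <- array(0, c(cfg$window, d, cfg$channels))
  for (t in seq_len(cfg$window)) input[t, , , , 1] <- arr[, , , t]
  if (cfg$channels == 2) {
    co <- coeffs %||% model$coeffs %||% grain_coefficients(series$variety)
    moist <- series_moisture(tail_ser)
    for (t in seq_len(cfg$window)) {
      input[t, , , , 2] <- awp_field(arr[, , , t, drop = TRUE], moist[t], co)
    }
  }
  w <- structure(list(input = input), class = "window_sample")
  packed <- windows_to_input(list(w), model$stats)
  pred_std <- forecaster_forward(model, packed, train = FALSE)
  pred <- destandardize(pred_std, model$stats, 1)
  # columns of pred: voxel-fastest then day; reshape to (P, X, Y, Z)
  aperm(array(pred, c(d, cfg$horizon)), c(4, 1, 2, 3))
}

#' Persistence baseline forecast error
#'
#' Predicts every horizon day as the last observed input grid; the naive
#' reference any trained forecaster must beat.
#'
#' @param windows List of `window_sample`.
#' @return List with `mae` and `rmse` (degC) over all voxel-days.
#' @export
persistence_baseline <- function(windows) {
  se <- 0; ae <- 0; n <- 0
  for (w in windows) {
    Tn <- dim(w$input)[1]; P <- dim(w$target)[1]
    last <- w$input[Tn, , , , 1]
    for (p in seq_len(P)) {
      d <- w$target[p, , , ] - last
      se <- se + sum(d^2); ae <- ae + sum(abs(d)); n <- n + length(d)
    }
  }
  list(mae = ae / n, rmse = sqrt(se / n))
}
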