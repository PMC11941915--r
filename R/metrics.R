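# Classification metrics, regression metrics, series diagnostics
# (moments, ACF/PACF), improvement arithmetic, and channel ablation.

#' Multiclass classification metrics with confusion matrix
#'
#' One-vs-rest precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and
#' `F1 = 2PR/(P+R)` per class, macro-averaged unweighted; accuracy over all
#' samples.  Classes with a zero denominator score 0 and are flagged.  Both
#' macro-F1 conventions are reported: `f1_macro` (mean of per-class F1, the
#' headline) and `f1_of_macro_pr` (harmonic mean of macro P and macro R).
#' Micro-averaged P/R/F1 (equal to accuracy in single-label tasks) are
#' included for completeness.
#'
#' @param truth,predicted Equal-length vectors of storage-state labels.
#' @return An object of class `classification_metrics`: `accuracy`,
#'   `precision_macro`, `recall_macro`, `f1_macro`, `f1_of_macro_pr`,
#'   micro variants, `per_class` data.frame, `confusion` (6x6, rows = truth),
#'   and `undefined` (classes with zero denominators).
#' @export
classification_metrics <- function(truth, predicted) {
  t_f <- as_storage_state(truth)
  p_f <- as_storage_state(predicted)
  if (length(t_f) != length(p_f)) stop("truth and predicted lengths differ")
  cm <- table(truth = t_f, predicted = p_f)
  cm <- matrix(as.integer(cm), 6, 6, dimnames = dimnames(cm))
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn

  safe_div <- function(a, b) ifelse(b > 0, a / b, 0)
  prec <- safe_div(tp, tp + fp)
  rec <- safe_div(tp, tp + fn)
  f1 <- safe_div(2 * prec * rec, prec + rec)
  undefined <- storage_states()[(tp + fp) == 0 | (tp + fn) == 0]

  pm <- mean(prec); rm_ <- mean(rec)
  micro_p <- safe_div(sum(tp), sum(tp + fp))
  micro_r <- safe_div(sum(tp), sum(tp + fn))
  structure(list(
    accuracy = sum(tp) / total,
    precision_macro = pm, recall_macro = rm_,
    f1_macro = mean(f1),
    f1_of_macro_pr = if (pm + rm_ > 0) 2 * pm * rm_ / (pm + rm_) else 0,
    precision_micro = micro_p, recall_micro = micro_r,
    f1_micro = if (micro_p + micro_r > 0)
      2 * micro_p * micro_r / (micro_p + micro_r) else 0,
    per_class = data.frame(state = storage_states(), tp = tp, fp = fp,
                           fn = fn, tn = tn, precision = prec, recall = rec,
                           f1 = f1, row.names = NULL),
    confusion = cm, undefined = undefined),
    class = "classification_metrics")
}

#' Forecast error metrics
#'
#' `MAE = mean(|pred - truth|)` and `RMSE = sqrt(mean((pred - truth)^2))`
#' over all voxel-days (K = total element count).
#'
#' @param truth,predicted Aligned numeric arrays.
#' @return An object of class `regression_score`: `mae`, `rmse`, `k`.
#' @export
regression_metrics <- function(truth, predicted) {
  if (!identical(dim(truth) %||% length(truth),
                 dim(predicted) %||% length(predicted))) {
    stop("truth and predicted shapes differ")
  }
  d <- as.numeric(predicted) - as.numeric(truth)
  structure(list(mae = mean(abs(d)), rmse = sqrt(mean(d^2)), k = length(d)),
            class = "regression_score")
}

# sample autocorrelation (biased estimator) of a vector, lags 0..max_lag
acf_values <- function(x, max_lag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  if (denom == 0) return(c(1, rep(NA_real_, max_lag)))
  vapply(0:max_lag, function(k) {
    sum(xc[1:(n - k)] * xc[(1 + k):n]) / denom
  }, 0)
}

# PACF via Durbin-Levinson from the ACF sequence (lag 1..max_lag)
pacf_durbin_levinson <- function(rho, max_lag) {
  # rho: autocorrelations at lags 0..max_lag, rho[1] = 1
  phi <- matrix(0, max_lag, max_lag)
  pacf <- numeric(max_lag)
  if (max_lag >= 1) {
    phi[1, 1] <- rho[2]
    pacf[1] <- rho[2]
  }
  for (k in seq_len(max_lag)[-1]) {
    num <- rho[k + 1] - sum(phi[k - 1, 1:(k - 1)] * rho[k:2])
    den <- 1 - sum(phi[k - 1, 1:(k - 1)] * rho[2:k])
    phi[k, k] <- num / den
    phi[k, 1:(k - 1)] <- phi[k - 1, 1:(k - 1)] - phi[k, k] * phi[k - 1, (k - 1):1]
    pacf[k] <- phi[k, k]
  }
  pacf
}

#' Statistical and temporal diagnostics for a temperature series
#'
#' Moments (mean, median, sd, max, min, skewness, excess kurtosis) over all
#' pooled voxel values, and ACF/PACF (Durbin-Levinson) of the daily
#' pile-mean trace, used to choose the forecaster's input window length.
#'
#' @param series A [granary_series] (missing voxels ignored in pooling).
#' @param max_lag Maximum ACF/PACF lag; series must be longer than this.
#' @return An object of class `series_diagnostics`.
#' @export
series_diagnostics <- function(series, max_lag = 40) {
  arr <- series_array(series)
  if (dim(arr)[4] <= max_lag) stop("series length must exceed max_lag")
  vals <- arr[!is.na(arr)]
  m <- mean(vals)
  m2 <- mean((vals - m)^2)
  m3 <- mean((vals - m)^3)
  m4 <- mean((vals - m)^4)
  daily <- apply(arr, 4, mean, na.rm = TRUE)
  constant <- stats::var(daily) == 0
  rho <- if (constant) c(1, rep(NA_real_, max_lag)) else acf_values(daily, max_lag)
  pacf <- if (constant) rep(NA_real_, max_lag) else
    pacf_durbin_levinson(rho, max_lag)
  structure(list(
    mean = m, median = stats::median(vals), sd = sqrt(m2),
    max = max(vals), min = min(vals),
    skewness = m3 / m2^1.5, kurtosis = m4 / m2^2 - 3,
    acf = rho, pacf = pacf, max_lag = max_lag, constant = constant),
    class = "series_diagnostics")
}

#' Relative improvement of a model score over a baseline
#'
#' `100 * (baseline - model) / baseline`, reported to two decimals.  Smaller
#' scores are better (error metrics).
#'
#' @param model_score,baseline_score Positive error scores.
#' @return Percentage, rounded to two decimals.
#' @export
relative_improvement <- function(model_score, baseline_score) {
  if (any(baseline_score <= 0)) stop("baseline score must be positive")
  round(100 * (baseline_score - model_score) / baseline_score, 2)
}

#' Input-channel ablation for a trained two-channel forecaster
#'
#' Replaces one input channel at a time with its training mean (zero in
#' standardized space) and reports the MAE increase over the intact model:
#' a larger delta marks a more influential channel.  A lightweight,
#' model-agnostic substitute for gradient- or game-theoretic attribution.
#'
#' @param model A trained two-channel `forecaster_model`.
#' @param windows Evaluation windows (e.g. the test split).
#' @return Data.frame with `channel`, `mae`, `delta` (degC); row 0 is the
#'   intact baseline.
#' @export
channel_ablation <- function(model, windows) {
  if (model$config$channels != 2) {
    stop("channel ablation requires a two-channel model")
  }
  mae_for <- function(ablate) {
    se <- 0; ae <- 0; n <- 0
    for (start in seq(1, length(windows), by = 32)) {
      idx <- start:min(start + 31, length(windows))
      packed <- windows_to_input(windows[idx], model$stats)
      if (!is.na(ablate)) packed$v[ablate, ] <- 0
      pred <- destandardize(forecaster_forward(model, packed, train = FALSE),
                            model$stats, 1)
      tgt <- windows_to_target(windows[idx], NULL)
      ae <- ae + sum(abs(pred - tgt)); n <- n + length(tgt)
    }
    ae / n
  }
  base <- mae_for(NA)
  m1 <- mae_for(1L)
  m2 <- mae_for(2L)
  data.frame(channel = c("none", "temperature", "water_potential"),
             mae = c(base, m1, m2), delta = c(0, m1 - base, m2 - base))
}
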