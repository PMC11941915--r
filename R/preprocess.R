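# Cleaning -> imputation -> spline resize -> standardization.
# The pipeline order is fixed; each stage's output satisfies the next
# stage's preconditions.

#' Cleaning configuration
#'
#' Sensor firmware emits exact sentinel temperatures on failure (commonly
#' 888, -85 and 85 degC); these, values outside the physically plausible
#' range, and pooled Z-score outliers are all turned into missing voxels.
#'
#' @param error_codes Numeric vector of sentinel temperatures (degC).
#' @param z_threshold Positive Z-score cutoff; `|Z| >` threshold is removed.
#' @param physical_range Length-2 numeric, plausible temperature range (degC).
#' @return An object of class `cleaning_config`.
#' @export
cleaning_config <- function(error_codes = c(888, -85, 85),
                            z_threshold = 3,
                            physical_range = c(-40, 60)) {
  stopifnot(z_threshold > 0, length(physical_range) == 2,
            physical_range[1] < physical_range[2])
  structure(list(error_codes = error_codes, z_threshold = z_threshold,
                 physical_range = physical_range),
            class = "cleaning_config")
}

#' Clean a granary series
#'
#' Two passes over the whole series: (1) voxels exactly equal to a sentinel
#' error code (matched after rounding to 0.1 degC) or outside the physical
#' range become missing; (2) Z-scores `Z = (X - mu) / sigma` are computed
#' over all surviving values pooled across the series (population sigma) and
#' values with `|Z|` above the threshold become missing.  With degenerate
#' dispersion (`sigma = 0`) no Z-removals occur and the report says so.
#'
#' @param series A [granary_series].
#' @param config A [cleaning_config].
#' @return List with `series` (cleaned) and `report` (class `zscore_report`:
#'   `mu`, `sigma`, `z` 4D array, `removed` 4D logical, removal counts,
#'   `degenerate` flag).
#' @export
clean_series <- function(series, config = cleaning_config()) {
  arr <- series_array(series)

  rounded <- round(arr, 1)
  is_code <- array(FALSE, dim(arr))
  for (code in config$error_codes) {
    is_code <- is_code | (!is.na(rounded) & rounded == round(code, 1))
  }
  out_of_range <- !is.na(arr) &
    (arr < config$physical_range[1] | arr > config$physical_range[2])
  arr[is_code | out_of_range] <- NA_real_

  vals <- arr[!is.na(arr)]
  mu <- mean(vals)
  sigma <- sqrt(mean((vals - mu)^2))   # population sd over the pooled series
  z <- array(NA_real_, dim(arr))
  removed_z <- array(FALSE, dim(arr))
  degenerate <- !is.finite(sigma) || sigma == 0
  if (!degenerate) {
    z[!is.na(arr)] <- (arr[!is.na(arr)] - mu) / sigma
    removed_z <- !is.na(z) & abs(z) > config$z_threshold
    arr[removed_z] <- NA_real_
  }

  list(
    series = series_with_values(series, arr),
    report = structure(
      list(mu = mu, sigma = sigma, z = z, removed = removed_z,
           n_code_removed = sum(is_code | out_of_range),
           n_z_removed = sum(removed_z), degenerate = degenerate),
      class = "zscore_report")
  )
}

#' Impute missing voxels by adjacent-day means
#'
#' Each missing value of a voxel's daily trace becomes the mean of the
#' nearest previous and nearest next observed values of that voxel (not a
#' distance-weighted interpolation); leading/trailing gaps take the single
#' nearest observed value.
#'
#' @param series A [granary_series] (typically the output of [clean_series()]).
#' @return A [granary_series] with no missing voxels.
#' @export
impute_missing <- function(series) {
  arr <- series_array(series)
  d <- dim(arr)
  nt <- d[4]
  flat <- matrix(arr, ncol = nt)  # voxels x days
  miss_rows <- which(rowSums(is.na(flat)) > 0)
  for (v in miss_rows) {
    tr <- flat[v, ]
    kn <- which(!is.na(tr))
    if (length(kn) == 0) {
      vox <- arrayInd(v, d[1:3])
      stop(sprintf("voxel (%d,%d,%d) is missing on all days; cannot impute",
                   vox[1], vox[2], vox[3]))
    }
    gaps <- which(is.na(tr))
    i <- findInterval(gaps, kn)            # index of nearest previous known day
    prev_val <- ifelse(i >= 1, tr[kn[pmax(i, 1)]], NA_real_)
    nxt_val <- ifelse(i + 1 <= length(kn), tr[kn[pmin(i + 1, length(kn))]], NA_real_)
    tr[gaps] <- rowMeans(cbind(prev_val, nxt_val), na.rm = TRUE)
    flat[v, ] <- tr
  }
  series_with_values(series, array(flat, d))
}

# cached linear interpolation operators: natural cubic spline (n >= 4) or
# linear (n in 2..3) on a normalized [0,1] lattice; interpolation is linear
# in the data, so an n_out x n_in matrix applied per axis is exact
.gw_cache <- new.env(parent = emptyenv())

resize_operator <- function(n_in, n_out) {
  key <- paste0("rs_", n_in, "_", n_out)
  if (!is.null(.gw_cache[[key]])) return(.gw_cache[[key]])
  if (n_in < 2) stop("resize requires at least 2 samples along each axis")
  xin <- seq(0, 1, length.out = n_in)
  xout <- seq(0, 1, length.out = n_out)
  A <- matrix(0, n_out, n_in)
  for (i in seq_len(n_in)) {
    e <- numeric(n_in); e[i] <- 1
    A[, i] <- if (n_in >= 4) {
      stats::spline(xin, e, xout = xout, method = "natural")$y
    } else {
      stats::approx(xin, e, xout = xout)$y
    }
  }
  .gw_cache[[key]] <- A
  A
}

#' Resize a grid to the model lattice by separable spline interpolation
#'
#' Natural cubic splines per axis (linear where the axis has fewer than 4
#' samples) on normalized per-axis coordinates, applied separably.  The
#' default target is the unified 10 x 6 x 4 model input lattice.
#'
#' @param grid A [temperature_grid] with no missing values, or a bare 3D array.
#' @param target Integer target dims, default `c(10, 6, 4)`.
#' @return Same type as the input, resized.
#' @export
resize_spline <- function(grid, target = c(10, 6, 4)) {
  is_grid <- inherits(grid, "temperature_grid")
  v <- if (is_grid) grid$values else grid
  if (any(is.na(v))) stop("grid has missing values; run impute_missing first")
  d <- dim(v)
  # axis 1
  m <- resize_operator(d[1], target[1]) %*% matrix(v, nrow = d[1])
  v <- array(m, c(target[1], d[2], d[3]))
  # axis 2
  v <- aperm(v, c(2, 1, 3))
  m <- resize_operator(d[2], target[2]) %*% matrix(v, nrow = d[2])
  v <- aperm(array(m, c(target[2], target[1], d[3])), c(2, 1, 3))
  # axis 3
  v <- aperm(v, c(3, 1, 2))
  m <- resize_operator(d[3], target[3]) %*% matrix(v, nrow = d[3])
  v <- aperm(array(m, c(target[3], target[1], target[2])), c(2, 3, 1))
  if (is_grid) temperature_grid(v, date = grid$date) else v
}

#' Standardization statistics
#'
#' Per-channel mean and standard deviation, computed on the training
#' partition only and reused verbatim at validation/test/inference time.
#'
#' @param x Numeric vector/array (one channel) or list of them (one per channel).
#' @return An object of class `standardization_stats` (`mean`, `sd`, per channel).
#' @export
standardization_stats <- function(x) {
  chans <- if (is.list(x)) x else list(x)
  mean <- vapply(chans, function(v) mean(as.numeric(v)), 0)
  # population sd: the scaling convention used throughout
  sd <- vapply(chans, function(v) sqrt(mean((as.numeric(v) - mean(as.numeric(v)))^2)), 0)
  if (any(!is.finite(sd)) || any(sd == 0)) {
    stop("standardization requires positive per-channel sd")
  }
  structure(list(mean = mean, sd = sd), class = "standardization_stats")
}

#' Standardize values with training-partition statistics
#' @param x Numeric vector/array.
#' @param stats A [standardization_stats].
#' @param channel Channel index into `stats`, default 1.
#' @return `(x - mean) / sd`.
#' @export
standardize <- function(x, stats, channel = 1) {
  (x - stats$mean[channel]) / stats$sd[channel]
}

#' Invert [standardize()]
#' @inheritParams standardize
#' @return `x * sd + mean`.
#' @export
destandardize <- function(x, stats, channel = 1) {
  x * stats$sd[channel] + stats$mean[channel]
}

#' Run the full grid preprocessing chain on a series
#'
#' clean -> impute -> per-day spline resize; standardization is left to the
#' dataset builders because its statistics must come from a training
#' partition.
#'
#' @param series A [granary_series].
#' @param config A [cleaning_config].
#' @param target Target grid dims.
#' @return A [granary_series] on the target lattice with no missing voxels.
#' @export
preprocess_series <- function(series, config = cleaning_config(),
                              target = c(10, 6, 4)) {
  cleaned <- clean_series(series, config)$series
  imputed <- impute_missing(cleaned)
  grids <- lapply(imputed$grids, resize_spline, target = target)
  granary_series(series$granary_id, series$variety, series$days, grids,
                 series$moisture, series$region)
}
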