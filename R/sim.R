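# Synthetic granary generator: a discrete heat-relaxation pile driven by
# seasonal ambient forcing, with injectable storage-state events, sensor
# noise, sentinel error codes and dropouts.  Every downstream stage trains
# and tests against this simulator.

#' Simulator configuration
#'
#' Defaults emulate a temperate-climate flat warehouse instrumented with a
#' 12 x 8 x 6 sensor lattice and observed daily for 540 days starting in
#' midwinter: ambient mean 7 degC, seasonal amplitude 16 degC over a 365-day
#' period, ambient day-to-day noise 1 degC, and a per-day relaxation
#' coefficient of 0.35 toward the local neighbor/ambient mean (chosen so the
#' pooled pile statistics sit in the realistic range for a temperate
#' continental storage region).
#'
#' @param dims Integer sensor lattice dims (M, N, H); z = H is the surface.
#' @param n_days Number of simulated days.
#' @param ambient_mean,ambient_amplitude,ambient_period Seasonal forcing:
#'   `A(t) = mean - amplitude * cos(2 pi t / period) + noise`, so day 1 sits
#'   near the winter trough.
#' @param daily_noise_sd Ambient day-to-day noise sd, degC.
#' @param diffusivity Per-day relaxation coefficient in (0, 1): the fraction
#'   each voxel moves toward the mean of its 6-neighborhood (out-of-domain
#'   neighbors count as ambient) per day.
#' @param sensor_noise_sd Per-voxel measurement noise sd, degC.
#' @param error_code_rate Probability a reading is replaced by a sentinel
#'   error code (888, -85 or 85 degC).
#' @param dropout_rate Probability a reading is missing entirely.
#' @param seed RNG seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dims = c(12, 8, 6), n_days = 540,
                       ambient_mean = 7, ambient_amplitude = 16,
                       ambient_period = 365, daily_noise_sd = 1.0,
                       diffusivity = 0.35, sensor_noise_sd = 0.2,
                       error_code_rate = 0.001, dropout_rate = 0.01,
                       seed = 1L) {
  stopifnot(length(dims) == 3, all(dims >= 1), n_days >= 1,
            diffusivity > 0, diffusivity < 1,
            error_code_rate >= 0, error_code_rate < 1,
            dropout_rate >= 0, dropout_rate < 1)
  structure(list(dims = as.integer(dims), n_days = as.integer(n_days),
                 ambient_mean = ambient_mean,
                 ambient_amplitude = ambient_amplitude,
                 ambient_period = ambient_period,
                 daily_noise_sd = daily_noise_sd, diffusivity = diffusivity,
                 sensor_noise_sd = sensor_noise_sd,
                 error_code_rate = error_code_rate,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "sim_config")
}

# mean of the 6-neighborhood with out-of-domain neighbors replaced by ambient;
# vectorized via shifted copies of the padded field
neighbor_mean <- function(field, ambient) {
  d <- dim(field)
  pad <- array(ambient, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- field
  acc <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] +
         pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] +
         pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] +
         pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] +
         pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] +
         pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  acc / 6
}

#' Simulate a granary temperature series
#'
#' Discrete daily relaxation: each voxel moves a fraction `diffusivity`
#' toward the mean of its 6-neighborhood, with out-of-domain neighbors
#' replaced by the ambient temperature, so boundary voxels track ambient and
#' interior voxels lag it with depth.  Sensor noise, sentinel error codes
#' and dropouts are applied on top of the physical field.  Deterministic
#' under the config seed.
#'
#' @param config A [sim_config].
#' @param granary_id,variety,region Series metadata.
#' @param start_date First calendar day.
#' @return A [granary_series]; the clean physical field (pre-noise, no
#'   dropouts) is attached as attribute `"physical"` (4D array) and the
#'   ambient trace as attribute `"ambient"` for diagnostics.
#' @export
simulate_series <- function(config = sim_config(), granary_id = "sim-1",
                            variety = "wheat", region = "sim",
                            start_date = as.Date("2023-01-01")) {
  with_seed(config$seed, {
    d <- config$dims
    nt <- config$n_days
    tt <- seq_len(nt)
    ambient <- config$ambient_mean -
      config$ambient_amplitude * cos(2 * pi * tt / config$ambient_period) +
      stats::rnorm(nt, 0, config$daily_noise_sd)

    phys <- array(NA_real_, c(d, nt))
    field <- array(ambient[1], d)
    k <- config$diffusivity
    for (t in tt) {
      field <- field + k * (neighbor_mean(field, ambient[t]) - field)
      phys[, , , t] <- field
    }

    nv <- prod(d) * nt
    obs <- phys + stats::rnorm(nv, 0, config$sensor_noise_sd)
    codes <- c(888, -85, 85)
    idx_code <- which(stats::runif(nv) < config$error_code_rate)
    obs[idx_code] <- sample(codes, length(idx_code), replace = TRUE)
    idx_drop <- stats::runif(nv) < config$dropout_rate
    obs[idx_drop] <- NA_real_

    # moisture: slow AR(1) around a variety-specific mean, sampled weekly
    m_mean <- c(wheat = 12.5, corn = 14, rice = 13.5)[[variety]]
    m <- numeric(nt)
    m[1] <- m_mean
    for (t in 2:max(nt, 2)) {
      if (t <= nt) m[t] <- m_mean + 0.995 * (m[t - 1] - m_mean) +
          stats::rnorm(1, 0, 0.05)
    }
    moisture <- rep(NA_real_, nt)
    sampled <- seq(1, nt, by = 7)
    moisture[sampled] <- pmin(pmax(m[sampled], 5), 35)

    days <- start_date + tt - 1
    grids <- lapply(tt, function(t) {
      temperature_grid(obs[, , , t, drop = TRUE], date = days[t])
    })
    out <- granary_series(granary_id, variety, days, grids, moisture, region)
    attr(out, "physical") <- phys
    attr(out, "ambient") <- ambient
    out
  })
}

#' Storage-state event specification
#'
#' Encodes the temperature signature of one abnormal storage state to be
#' injected into a simulated series.  Intensity parameters per state:
#' * `mildew`: `rate` (degC/day warming at the hotspot center, default 1.0),
#'   `radius0` (initial hotspot radius in voxels, default 1.2), `radius_growth`
#'   (voxels/day, default 0.08) — a localized, spreading exothermic ramp.
#' * `condensation`: `gradient` (degC, default 14) — the extra core-minus-
#'   surface vertical gradient reached at full ramp ("cold skin, hot core");
#'   the injector guarantees the achieved gradient is at least the ramped
#'   target regardless of the seasonal baseline.
#' * `aeration`: `tau` (days, default 2) — pile-wide exponential pull toward
#'   ambient.
#' * `new_grain`: `delta` (degC, default 6) — step increase in the upper half
#'   of the pile.
#' * `empty`: `jitter_sd` (degC, default 0.2) — all voxels track ambient with
#'   near-zero spatial variance.
#'
#' @param state A storage state other than `"normal"`.
#' @param start_day First event day (1-based index into the series).
#' @param duration Event length in days.
#' @param center Integer voxel (x, y, z), 1-based, for localized events; for
#'   `condensation` the center marks the cold-skin spot on the surface layer.
#' @param intensity Named list of state-specific parameters (see above).
#' @return An object of class `event_spec`.
#' @export
event_spec <- function(state, start_day, duration, center = NULL,
                       intensity = list()) {
  state <- as.character(as_storage_state(state))
  if (state == "normal") stop("cannot inject a 'normal' event")
  stopifnot(start_day >= 1, duration >= 1)
  structure(list(state = state, start_day = as.integer(start_day),
                 duration = as.integer(duration), center = center,
                 intensity = intensity),
            class = "event_spec")
}

#' Inject a storage-state event into a series
#'
#' Returns a modified copy of the series plus a per-day label track.  Each
#' injector realizes the defining temperature signature of its state (see
#' [event_spec()]); the inequality that defines each signature holds on the
#' labelled days, so injected events are label-recoverable.
#'
#' @param series A [granary_series].
#' @param event An [event_spec].
#' @param labels Optional existing per-day label track (character); event
#'   days that are already non-normal raise an overlap error.
#' @return List with `series` (modified copy), `labels` (character per-day
#'   track), and `center` (the event's 1-based center voxel, possibly
#'   defaulted).
#' @export
inject_state <- function(series, event, labels = NULL) {
  d <- series_dims(series)
  nt <- length(series$days)
  if (event$start_day + event$duration - 1L > nt) {
    stop("event does not fit within the series")
  }
  if (is.null(labels)) labels <- rep("normal", nt)
  span <- seq(event$start_day, event$start_day + event$duration - 1L)
  if (any(labels[span] != "normal")) stop("overlapping events")

  center <- event$center
  if (is.null(center)) {
    center <- if (event$state == "condensation") {
      c(ceiling(d[1] / 2), ceiling(d[2] / 2), d[3])
    } else {
      c(ceiling(d[1] / 2), ceiling(d[2] / 2), ceiling(d[3] / 2))
    }
  }
  if (any(center < 1) || any(center > d)) stop("event center outside dims")

  arr <- series_array(series)
  ambient <- attr(series, "ambient")
  if (is.null(ambient)) {
    # fall back to the surface-layer mean as an ambient proxy
    ambient <- apply(arr[, , d[3], , drop = FALSE], 4, mean, na.rm = TRUE)
  }
  ix <- slice.index(array(0, d), 1)
  iy <- slice.index(array(0, d), 2)
  iz <- slice.index(array(0, d), 3)
  inten <- event$intensity
  moisture <- series$moisture

  for (s in seq_along(span)) {
    t <- span[s]
    g <- arr[, , , t]
    el <- s  # elapsed event days (1-based)
    if (event$state == "mildew") {
      # ramp starts at `onset` above baseline: a mildew day is labelled once
      # the exothermic hotspot is already noticeable, then heats by `rate`
      # degC/day while the affected radius grows
      rate <- inten$rate %||% 1.0
      onset <- inten$onset %||% 2.0
      r <- (inten$radius0 %||% 1.2) + (inten$radius_growth %||% 0.08) * (el - 1)
      dist2 <- (ix - center[1])^2 + (iy - center[2])^2 + (iz - center[3])^2
      g <- g + (onset + rate * el) * exp(-dist2 / (2 * r^2))
      # mildew moistens the grain locally; the pile-level track creeps up
      if (!all(is.na(moisture))) {
        obs <- which(!is.na(moisture) & seq_len(nt) >= t)
        moisture[obs] <- pmin(moisture[obs] + 0.1 / length(span), 35)
      }
    } else if (event$state == "condensation") {
      gtar <- inten$gradient %||% 14
      core <- iz <= ceiling(d[3] / 2)
      surf <- iz == d[3]
      b <- mean(g[core], na.rm = TRUE) - mean(g[surf], na.rm = TRUE)
      boost <- gtar * el / event$duration - min(b, 0)
      g[core] <- g[core] + boost / 2
      g[surf] <- g[surf] - boost / 2
    } else if (event$state == "aeration") {
      # forced-air cooling front: air enters at the duct layer (bottom) a few
      # degrees below ambient and the cooled zone rises through the pile;
      # uncooled layers relax mildly toward ambient.  The front never quite
      # reaches the surface within the event, preserving a two-zone profile.
      tau <- inten$tau %||% 8
      chill <- inten$chill %||% 4
      front <- ceiling(d[3] * el / (event$duration + 1))
      g <- ambient[t] + (g - ambient[t]) * exp(-el / tau)
      if (front >= 1) {
        low <- iz <= min(front, d[3] - 1L)
        g[low] <- ambient[t] - chill + 0.15 * (g[low] - ambient[t])
      }
    } else if (event$state == "new_grain") {
      delta <- inten$delta %||% 6
      upper <- iz > floor(d[3] / 2)
      g[upper] <- g[upper] + delta
    } else if (event$state == "empty") {
      jit <- inten$jitter_sd %||% 0.2
      keep_na <- is.na(g)
      g <- array(ambient[t] + stats::rnorm(prod(d), 0, jit), d)
      g[keep_na] <- NA_real_
    }
    arr[, , , t] <- g
    labels[t] <- event$state
  }

  out <- series_with_values(series, arr)
  out$moisture <- moisture
  attr(out, "ambient") <- attr(series, "ambient")
  attr(out, "physical") <- attr(series, "physical")
  list(series = out, labels = labels, center = center)
}

#' Build a labelled classification dataset from simulated granaries
#'
#' Generates seeded granary series, injects one event per abnormal-state
#' request batch, runs the preprocessing chain (clean, impute, spline-resize
#' to the target lattice) and extracts one sample per labelled day until the
#' requested per-class counts are met exactly.  Grids are returned in degC
#' (unstandardized); classifier training standardizes from its own training
#' partition.
#'
#' @param n_per_class Named integer vector/list, state -> requested count.
#' @param config A [sim_config] used as the base for every generated series
#'   (per-series seeds and ambient parameters are jittered deterministically).
#' @param seed Integer seed for the whole build.
#' @param target Target grid dims, default `c(10, 6, 4)`.
#' @return List of `class_sample` objects (`grid`, `label`, `provenance`).
#' @export
build_classification_dataset <- function(n_per_class, config = sim_config(),
                                         seed = 1L, target = c(10, 6, 4)) {
  n_per_class <- unlist(n_per_class)
  bad <- setdiff(names(n_per_class), storage_states())
  if (length(bad)) stop("unknown states: ", paste(bad, collapse = ", "))
  samples <- list()
  sidx <- 0L
  for (state in names(n_per_class)) {
    need <- n_per_class[[state]]
    while (need > 0) {
      sidx <- sidx + 1L
      sseed <- derive_seed(seed, sidx)
      # mildew episodes are acute (detected and treated within days); the
      # other states persist for weeks
      dur <- min(if (state == "mildew") 10L else 30L, need)
      # long warmup: the pile must forget its uniform initialization and
      # show mature seasonal structure before samples are drawn, otherwise
      # the classifier never sees deployment-age piles labelled "normal"
      warm <- 160L
      cfg <- config
      cfg$seed <- sseed
      cfg$n_days <- warm + 40L + dur + 10L
      jit <- with_seed(derive_seed(sseed, 999L), {
        list(mean = stats::rnorm(1, 0, 2), amp = stats::rnorm(1, 0, 2),
             phase = sample.int(365, 1))
      })
      cfg$ambient_mean <- cfg$ambient_mean + jit$mean
      cfg$ambient_amplitude <- max(4, cfg$ambient_amplitude + jit$amp)
      ser <- simulate_series(cfg, granary_id = sprintf("cls-%04d", sidx),
                             start_date = as.Date("2023-01-01") + jit$phase)
      start <- with_seed(derive_seed(sseed, 13L),
                         sample(seq(warm, warm + 40L), 1))
      if (state == "normal") {
        lab <- rep("normal", cfg$n_days)
        take <- seq(start, start + dur - 1L)
      } else {
        ctr <- with_seed(derive_seed(sseed, 7L), {
          d <- cfg$dims
          if (state == "condensation") {
            c(sample(2:(d[1] - 1), 1), sample(2:(d[2] - 1), 1), d[3])
          } else {
            c(sample(2:(d[1] - 1), 1), sample(2:(d[2] - 1), 1),
              sample(2:(d[3] - 1), 1))
          }
        })
        inj <- inject_state(ser, event_spec(state, start, dur, center = ctr))
        ser <- inj$series
        lab <- inj$labels
        take <- which(lab == state)
      }
      pp <- preprocess_series(ser, target = target)
      for (t in take[seq_len(min(dur, need))]) {
        samples[[length(samples) + 1L]] <- class_sample(
          pp$grids[[t]]$values, lab[t], "real")
      }
      need <- need - min(dur, need)
    }
  }
  samples
}

#' A labelled classifier sample
#'
#' @param grid Numeric 3D array on the model lattice, no missing values.
#' @param label A storage state.
#' @param provenance One of `"real"`, `"flipped"`, `"gan"` (here `"real"`
#'   means simulator-derived as opposed to augmentation-derived).
#' @return An object of class `class_sample`.
#' @export
class_sample <- function(grid, label, provenance = "real") {
  if (inherits(grid, "temperature_grid")) grid <- grid$values
  stopifnot(is.array(grid), length(dim(grid)) == 3, !anyNA(grid))
  provenance <- match.arg(provenance, c("real", "flipped", "gan"))
  structure(list(grid = grid, label = as.character(as_storage_state(label)),
                 provenance = provenance),
            class = "class_sample")
}

#' Build a multi-granary forecasting dataset
#'
#' Simulates `n_granaries` seeded series long enough for sliding-window
#' extraction (`window + horizon + 100` days at minimum), each with a
#' moisture track, optionally with injected events.
#'
#' @param config A [sim_config]; `n_days` is raised to the minimum if needed.
#' @param events List of [event_spec] (applied to every granary, with
#'   per-granary jittered centers), or `NULL`.
#' @param seed Integer seed.
#' @param n_granaries Number of series.
#' @param window,horizon Sliding-window geometry used for the length floor.
#' @return List of [granary_series]; each carries attribute `"labels"` (and
#'   `"event_centers"` when events were injected).
#' @export
build_forecast_dataset <- function(config = sim_config(), events = NULL,
                                   seed = 1L, n_granaries = 3L,
                                   window = 35L, horizon = 10L) {
  min_days <- window + horizon + 100L
  out <- vector("list", n_granaries)
  for (i in seq_len(n_granaries)) {
    cfg <- config
    cfg$n_days <- max(config$n_days, min_days)
    cfg$seed <- derive_seed(seed, i)
    variety <- c("wheat", "corn")[(i %% 2) + 1]
    ser <- simulate_series(cfg, granary_id = sprintf("fc-%02d", i),
                           variety = variety)
    labels <- rep("normal", cfg$n_days)
    centers <- list()
    for (j in seq_along(events %||% list())) {
      ev <- events[[j]]
      if (is.null(ev$center) && ev$state == "mildew") {
        # jitter localized event centers per granary so the forecaster sees
        # hotspots at more than one location
        d <- cfg$dims
        ev$center <- with_seed(derive_seed(seed, 500L + 10L * i + j), {
          c(sample(2:(d[1] - 1), 1), sample(2:(d[2] - 1), 1),
            sample(2:(d[3] - 1), 1))
        })
      }
      inj <- inject_state(ser, ev, labels)
      ser <- inj$series
      labels <- inj$labels
      centers[[length(centers) + 1L]] <- inj$center
    }
    attr(ser, "labels") <- labels
    if (length(centers)) attr(ser, "event_centers") <- centers
    out[[i]] <- ser
  }
  out
}
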