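#' One day's 3D granary temperature field
#'
#' The sensor lattice of a flat granary holds `M x N x H` temperature
#' sensors along the X, Y and Z axes.  `values` is indexed `[x, y, z]`;
#' z increases upward so `z = H` is the pile surface layer.  `mask` flags
#' missing voxels (sensor dropouts, removed error codes, removed outliers).
#'
#' @param values Numeric 3D array (M, N, H), degrees C.  `NA` entries are
#'   treated as missing and added to the mask.
#' @param mask Logical 3D array, `TRUE` = missing.  Defaults to `is.na(values)`.
#' @param date A `Date` (or string coercible to one).
#' @return An object of class `temperature_grid`.
#' @export
temperature_grid <- function(values, mask = NULL, date = as.Date("2000-01-01")) {
  if (!is.array(values) || length(dim(values)) != 3) {
    stop("values must be a 3D array")
  }
  if (any(dim(values) < 1)) stop("all grid dimensions must be >= 1")
  if (is.null(mask)) mask <- is.na(values)
  if (!identical(dim(mask), dim(values))) {
    stop("mask and values must have identical dimensions")
  }
  mask <- mask | is.na(values)
  values[mask] <- NA_real_
  if (any(!is.finite(values[!mask]))) {
    stop("non-missing grid values must be finite")
  }
  structure(
    list(values = values, mask = mask, date = as.Date(date)),
    class = "temperature_grid"
  )
}

#' @export
print.temperature_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "<temperature_grid %s  %dx%dx%d  %d missing  range [%.1f, %.1f] degC>\n",
    format(x$date), d[1], d[2], d[3], sum(x$mask),
    suppressWarnings(min(x$values, na.rm = TRUE)),
    suppressWarnings(max(x$values, na.rm = TRUE))
  ))
  invisible(x)
}

#' A date-ordered series of temperature grids for one granary
#'
#' The unit of ingestion and simulation: daily 3D grids plus a (possibly
#' sparse) grain-moisture track and the grain variety.  Moisture is sampled
#' irregularly by granary staff; `series_moisture()` forward-fills between
#' sampling dates.
#'
#' @param granary_id Character id.
#' @param variety One of `"wheat"`, `"corn"`, `"rice"`.
#' @param days Strictly increasing `Date` vector.
#' @param grids List of [temperature_grid], one per day, shared dims.
#' @param moisture Numeric vector, grain moisture content in percent, one per
#'   day; `NA` where not sampled.  Values must lie in (0, 40).
#' @param region Character region label (used in dataset summaries).
#' @return An object of class `granary_series`.
#' @export
granary_series <- function(granary_id, variety, days, grids,
                           moisture = NULL, region = "") {
  variety <- match.arg(variety, c("wheat", "corn", "rice"))
  days <- as.Date(days)
  if (length(days) != length(grids)) stop("days and grids lengths differ")
  if (length(days) > 1 && any(diff(as.numeric(days)) <= 0)) {
    stop("days must be strictly increasing")
  }
  dims <- dim(grids[[1]]$values)
  for (g in grids) {
    if (!inherits(g, "temperature_grid")) stop("grids must be temperature_grid")
    if (!identical(dim(g$values), dims)) stop("all grids must share dims")
  }
  if (is.null(moisture)) moisture <- rep(NA_real_, length(days))
  if (length(moisture) != length(days)) stop("moisture must be per-day")
  mq <- moisture[!is.na(moisture)]
  if (length(mq) > 0 && (any(mq <= 0) || any(mq >= 40))) {
    stop("moisture values must lie in (0, 40) percent")
  }
  structure(
    list(granary_id = as.character(granary_id), variety = variety,
         days = days, grids = grids, moisture = moisture,
         region = as.character(region)),
    class = "granary_series"
  )
}

#' @export
print.granary_series <- function(x, ...) {
  d <- series_dims(x)
  cat(sprintf(
    "<granary_series '%s' (%s, %s)  %d days [%s .. %s]  grid %dx%dx%d>\n",
    x$granary_id, x$variety, x$region, length(x$days),
    format(min(x$days)), format(max(x$days)), d[1], d[2], d[3]
  ))
  invisible(x)
}

#' Grid dimensions of a series
#' @param series A [granary_series].
#' @return Integer vector (M, N, H).
#' @export
series_dims <- function(series) dim(series$grids[[1]]$values)

#' Series values as a 4D array (M, N, H, T), NA where missing
#' @param series A [granary_series].
#' @return Numeric 4D array.
#' @export
series_array <- function(series) {
  d <- series_dims(series)
  arr <- array(NA_real_, c(d, length(series$days)))
  for (t in seq_along(series$grids)) {
    v <- series$grids[[t]]$values
    v[series$grids[[t]]$mask] <- NA_real_
    arr[, , , t] <- v
  }
  arr
}

#' Replace series values from a 4D array, preserving metadata
#' @param series A [granary_series].
#' @param arr Numeric 4D array (M, N, H, T); NA entries become missing voxels.
#' @return A [granary_series].
#' @export
series_with_values <- function(series, arr) {
  stopifnot(identical(dim(arr)[1:3], as.integer(series_dims(series))),
            dim(arr)[4] == length(series$days))
  d3 <- dim(arr)[1:3]
  grids <- lapply(seq_along(series$days), function(t) {
    temperature_grid(array(arr[, , , t], d3), date = series$days[t])
  })
  granary_series(series$granary_id, series$variety, series$days, grids,
                 series$moisture, series$region)
}

#' Forward-filled per-day moisture track
#'
#' Moisture is carried forward from the most recent sampling date; days before
#' the first sample take the first sampled value.
#'
#' @param series A [granary_series].
#' @return Numeric vector, one moisture percentage per day.
#' @export
series_moisture <- function(series) {
  m <- series$moisture
  if (all(is.na(m))) stop("series has no moisture measurements")
  idx <- which(!is.na(m))
  filled <- m
  last <- m[idx[1]]
  for (t in seq_along(m)) {
    if (!is.na(m[t])) last <- m[t]
    filled[t] <- last
  }
  filled
}

# ---- readers / writers ------------------------------------------------------

#' Read a granary series from a directory of long-format files
#'
#' Expects `temps.csv` (columns `date`, `x`, `y`, `z`, `temp_c`; 1-based
#' sensor indices), optionally `moisture.csv` (columns `date`,
#' `moisture_pct`) and `manifest.json` (fields `granary_id`, `variety`,
#' `region`, `dims`).  Sensor positions absent from the file on a given day
#' become missing voxels.
#'
#' @param path Directory containing the files.
#' @return A [granary_series].
#' @export
read_series <- function(path) {
  tf <- file.path(path, "temps.csv")
  if (!file.exists(tf)) stop("no temps.csv under ", path)
  rec <- utils::read.csv(tf, stringsAsFactors = FALSE)
  need <- c("date", "x", "y", "z", "temp_c")
  if (!all(need %in% names(rec))) {
    stop("temps.csv must have columns ", paste(need, collapse = ", "))
  }
  rec$date <- as.Date(rec$date)

  manifest <- NULL
  mf <- file.path(path, "manifest.json")
  if (file.exists(mf)) manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  dims <- if (!is.null(manifest$dims)) as.integer(manifest$dims) else
    c(max(rec$x), max(rec$y), max(rec$z))
  if (max(rec$x) > dims[1] || max(rec$y) > dims[2] || max(rec$z) > dims[3]) {
    stop(sprintf(
      "sensor index (%d,%d,%d) exceeds declared dims (%d,%d,%d)",
      max(rec$x), max(rec$y), max(rec$z), dims[1], dims[2], dims[3]))
  }

  key <- paste(rec$date, rec$x, rec$y, rec$z)
  if (anyDuplicated(key)) {
    stop("duplicate record for (date,x,y,z): ", key[anyDuplicated(key)])
  }

  days <- sort(unique(rec$date))
  day_idx <- match(rec$date, days)
  grids <- vector("list", length(days))
  flat <- (rec$x - 1L) + dims[1] * (rec$y - 1L) + dims[1] * dims[2] * (rec$z - 1L) + 1L
  for (t in seq_along(days)) {
    v <- array(NA_real_, dims)
    sel <- day_idx == t
    v[flat[sel]] <- rec$temp_c[sel]
    grids[[t]] <- temperature_grid(v, date = days[t])
  }

  moisture <- rep(NA_real_, length(days))
  mo <- file.path(path, "moisture.csv")
  if (file.exists(mo)) {
    md <- utils::read.csv(mo, stringsAsFactors = FALSE)
    hit <- match(as.Date(md$date), days)
    moisture[hit[!is.na(hit)]] <- md$moisture_pct[!is.na(hit)]
  }

  granary_series(
    granary_id = if (!is.null(manifest$granary_id)) manifest$granary_id else basename(path),
    variety    = if (!is.null(manifest$variety)) manifest$variety else "wheat",
    days = days, grids = grids, moisture = moisture,
    region = if (!is.null(manifest$region)) manifest$region else ""
  )
}

#' Write a granary series to a directory of long-format files
#'
#' Inverse of [read_series()]: `temps.csv` (missing voxels omitted, 1-based
#' indices), `moisture.csv` (sampled days only) and `manifest.json`.
#'
#' @param series A [granary_series].
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(path)) stop("cannot create directory ", path)
  d <- series_dims(series)
  xyz <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
  rows <- lapply(seq_along(series$days), function(t) {
    g <- series$grids[[t]]
    keep <- !as.vector(g$mask)
    if (!any(keep)) return(NULL)
    data.frame(date = format(series$days[t]),
               x = xyz$x[keep], y = xyz$y[keep], z = xyz$z[keep],
               temp_c = as.vector(g$values)[keep])
  })
  utils::write.csv(do.call(rbind, rows), file.path(path, "temps.csv"),
                   row.names = FALSE, quote = FALSE)
  ms <- !is.na(series$moisture)
  if (any(ms)) {
    utils::write.csv(
      data.frame(date = format(series$days[ms]),
                 moisture_pct = series$moisture[ms]),
      file.path(path, "moisture.csv"), row.names = FALSE, quote = FALSE)
  }
  jsonlite::write_json(
    list(granary_id = series$granary_id, variety = series$variety,
         region = series$region, dims = as.integer(d)),
    file.path(path, "manifest.json"), auto_unbox = TRUE)
  invisible(path)
}

# ---- dataset summary --------------------------------------------------------

#' Tabulate storage-state sample counts by region
#'
#' @param samples A data.frame with columns `region` and `state`, one row per
#'   labelled sample (states validated against [storage_states()]).  An
#'   optional integer column `n` gives a pre-aggregated count per row
#'   (defaults to 1), so already-tabulated counts can be summarized directly.
#' @return An object of class `dataset_summary` with a `counts` matrix
#'   (regions x 6 states) and a `totals` vector (per-state column sums).
#' @export
summarize_dataset <- function(samples) {
  st <- as_storage_state(if (nrow(samples) > 0) samples$state else character(0))
  if (nrow(samples) == 0) {
    counts <- matrix(0L, 0, 6, dimnames = list(NULL, storage_states()))
  } else {
    n <- if ("n" %in% names(samples)) as.numeric(samples$n) else rep(1, nrow(samples))
    if (any(n < 0)) stop("counts must be non-negative")
    reg <- factor(samples$region, levels = unique(samples$region))
    counts <- vapply(storage_states(), function(s) {
      vapply(levels(reg), function(r) sum(n[reg == r & st == s]), 0)
    }, numeric(nlevels(reg)))
    counts <- matrix(as.integer(counts), nrow = nlevels(reg),
                     dimnames = list(levels(reg), storage_states()))
  }
  structure(list(counts = counts, totals = colSums(counts)),
            class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat("<dataset_summary>\n")
  print(rbind(x$counts, Total = x$totals))
  invisible(x)
}
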