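# Forecast -> classify early-warning chain: forecast P days ahead, classify
# each predicted grid, and raise an alert on the first condensation/mildew
# day, with hotspot localization from the predicted fields.

#' Hotspot localization rule
#'
#' Heuristics applied to the predicted grids of the alerted state (a
#' package addition for localization; alerts themselves come from the
#' classifier):
#' * mildew: voxels whose predicted warming rate over the horizon exceeds
#'   `mildew_rate` (degC/day).
#' * condensation: surface-layer voxels whose deficit below the predicted
#'   core mean exceeds `condensation_gradient` (degC).
#'
#' @param mildew_rate Warming-rate threshold, degC/day, > 0.
#' @param condensation_gradient Core-minus-voxel threshold, degC, > 0.
#' @return An object of class `hotspot_rule`.
#' @export
hotspot_rule <- function(mildew_rate = 0.5, condensation_gradient = 8) {
  stopifnot(mildew_rate > 0, condensation_gradient > 0)
  structure(list(mildew_rate = mildew_rate,
                 condensation_gradient = condensation_gradient),
            class = "hotspot_rule")
}

hotspot_voxels <- function(pred, state, rule) {
  P <- dim(pred)[1]
  d <- dim(pred)[2:4]
  if (state == "mildew") {
    if (P < 2) return(matrix(integer(0), 0, 3))
    rate <- (pred[P, , , ] - pred[1, , , ]) / (P - 1)
    hit <- which(rate > rule$mildew_rate, arr.ind = TRUE)
  } else if (state == "condensation") {
    last <- pred[P, , , ]
    core <- last[, , seq_len(ceiling(d[3] / 2)), drop = FALSE]
    surf <- last[, , d[3], drop = FALSE]
    deficit <- mean(core) - surf
    hit2 <- which(deficit > rule$condensation_gradient, arr.ind = TRUE)
    if (nrow(hit2) == 0) return(matrix(integer(0), 0, 3))
    hit <- cbind(hit2[, 1], hit2[, 2], d[3])
  } else {
    return(matrix(integer(0), 0, 3))
  }
  if (length(hit) == 0) return(matrix(integer(0), 0, 3))
  hit <- matrix(as.integer(hit), ncol = 3)
  colnames(hit) <- c("x", "y", "z")
  hit
}

#' Run the forecast-then-classify early-warning chain
#'
#' Forecasts `P` daily grids from the series tail, classifies each predicted
#' grid with the storage-state model, and reports the first horizon day
#' classified as condensation or mildew (operational states are reported
#' but never alerted).  Lead time is counted from the forecast issue date
#' (the last observed day), so horizon day `k` has lead time `k`.
#'
#' @param series A [granary_series] whose tail supplies the forecast window.
#' @param forecaster A trained `forecaster_model`.
#' @param classifier A trained `classifier_model`.
#' @param rule A [hotspot_rule].
#' @param preprocessed `TRUE` if the series is already on the model lattice.
#' @return An object of class `alert_report`: `horizon_states`, `prob`
#'   (P x 6), `alert_day`, `alert_state`, `lead_time_days`, `hotspot`
#'   (1-based voxel matrix), and `pred` (the forecast grids, degC).
#' @export
run_alert <- function(series, forecaster, classifier, rule = hotspot_rule(),
                      preprocessed = FALSE) {
  if (is.null(forecaster$stats) || is.null(classifier$stats)) {
    stop("both models must be trained (standardization stats missing)")
  }
  if (!identical(forecaster$input_dims, classifier$input_dims)) {
    stop("forecaster lattice ", paste(forecaster$input_dims, collapse = "x"),
         " does not match classifier lattice ",
         paste(classifier$input_dims, collapse = "x"))
  }
  pred <- forecast(forecaster, series, preprocessed = preprocessed)
  P <- dim(pred)[1]
  grids <- lapply(seq_len(P), function(p) pred[p, , , ])
  cl <- classify(classifier, grids)
  states <- cl$state
  prob <- attr(cl, "prob")
  risk <- which(states %in% risk_states())
  alert_day <- if (length(risk) > 0) min(risk) else NA_integer_
  alert_state <- if (length(risk) > 0) states[alert_day] else NA_character_
  hotspot <- if (!is.na(alert_day)) {
    hotspot_voxels(pred, alert_state, rule)
  } else matrix(integer(0), 0, 3)
  structure(list(horizon_states = states, prob = prob,
                 alert_day = alert_day, alert_state = alert_state,
                 lead_time_days = alert_day, hotspot = hotspot, pred = pred,
                 issue_date = series$days[length(series$days)]),
            class = "alert_report")
}

#' @export
print.alert_report <- function(x, ...) {
  cat("<alert_report issued", format(x$issue_date), ">\n")
  cat(" horizon:", paste(x$horizon_states, collapse = ", "), "\n")
  if (is.na(x$alert_day)) {
    cat(" no risk alert\n")
  } else {
    cat(sprintf(" ALERT: %s on horizon day %d (lead time %d days), %d hotspot voxel(s)\n",
                x$alert_state, x$alert_day, x$lead_time_days, nrow(x$hotspot)))
  }
  invisible(x)
}

#' Score an alert report against ground truth
#'
#' Attaches forecast MAE/RMSE over the horizon and the alert timing error
#' (alert day minus the first true risk day within the horizon).
#'
#' @param report An `alert_report`.
#' @param truth_labels Character per-horizon-day true states (length P).
#' @param truth_grids Numeric array (P, X, Y, Z) of true temperatures, or a
#'   list of P grids.
#' @return The report with `forecast_mae`, `forecast_rmse`, `true_risk_day`,
#'   and `timing_error_days` added.
#' @export
evaluate_alert <- function(report, truth_labels, truth_grids) {
  P <- dim(report$pred)[1]
  if (length(truth_labels) != P) {
    stop("truth labels length ", length(truth_labels),
         " does not cover the horizon (", P, ")")
  }
  if (is.list(truth_grids)) {
    truth <- array(0, dim(report$pred))
    for (p in seq_len(P)) truth[p, , , ] <- truth_grids[[p]]
  } else {
    truth <- truth_grids
  }
  if (!identical(dim(truth), dim(report$pred))) {
    stop("truth grids do not match the forecast horizon shape")
  }
  rs <- regression_metrics(truth, report$pred)
  true_risk <- which(truth_labels %in% risk_states())
  true_day <- if (length(true_risk) > 0) min(true_risk) else NA_integer_
  report$forecast_mae <- rs$mae
  report$forecast_rmse <- rs$rmse
  report$true_risk_day <- true_day
  report$timing_error_days <- if (!is.na(report$alert_day) && !is.na(true_day)) {
    report$alert_day - true_day
  } else NA_integer_
  report
}
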