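# Absolute water potential E_jg (kJ/kg): a thermodynamic feature expressing
# the energy state of moisture in stored grain as a function of grain
# temperature Tg (degC), moisture content M (%), and variety-specific
# sorption fitting coefficients.  It is used as the forecaster's second
# input channel.

#' Variety-specific sorption fitting coefficients
#'
#' The published coefficient fits for each grain variety are not freely
#' available, so the sets shipped here (`"wheat-default"`, `"corn-default"`,
#' `"rice-default"`) are SYNTHETIC PLACEHOLDERS: dimensionally sensible
#' values chosen so the feature is finite, smooth, and strictly increasing
#' in temperature over the storage range.  For production use supply fitted
#' coefficients for your grain.
#'
#' @param variety One of `"wheat"`, `"corn"`, `"rice"`, or a named set such
#'   as `"wheat-default"`.
#' @param A1,A2,B1,B2,D Optional numeric overrides of the fitting
#'   coefficients; `A1`, `A2` must be nonzero.
#' @return An object of class `grain_coefficients`.
#' @export
grain_coefficients <- function(variety = "wheat", A1 = NULL, A2 = NULL,
                               B1 = NULL, B2 = NULL, D = NULL) {
  base <- sub("-default$", "", variety)
  base <- match.arg(base, c("wheat", "corn", "rice"))
  defaults <- list(
    wheat = list(A1 = 30, A2 = 15, B1 = 25, B2 = 35, D = 0.60),
    corn  = list(A1 = 28, A2 = 14, B1 = 27, B2 = 37, D = 0.55),
    rice  = list(A1 = 32, A2 = 16, B1 = 24, B2 = 34, D = 0.65)
  )[[base]]
  co <- list(A1 = A1 %||% defaults$A1, A2 = A2 %||% defaults$A2,
             B1 = B1 %||% defaults$B1, B2 = B2 %||% defaults$B2,
             D = D %||% defaults$D)
  if (!all(vapply(co, is.finite, TRUE))) stop("coefficients must be finite")
  if (co$A1 == 0 || co$A2 == 0) stop("A1 and A2 must be nonzero")
  structure(c(list(variety = base, placeholder = TRUE), co),
            class = "grain_coefficients")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read grain coefficients from a JSON/YAML-like config file
#'
#' The file maps variety to `{A1, A2, B1, B2, D}` (JSON).
#' @param path JSON file path.
#' @param variety Variety key to extract.
#' @return A [grain_coefficients].
#' @export
read_grain_coefficients <- function(path, variety) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(cfg[[variety]])) stop("no coefficient set for variety ", variety)
  co <- cfg[[variety]]
  grain_coefficients(variety, A1 = co$A1, A2 = co$A2, B1 = co$B1,
                     B2 = co$B2, D = co$D)
}

# inner log-domain exponent of the water-potential expression; the outer
# ln(exp(u) * 133.3) is evaluated as u + ln(133.3), which is exact and
# cannot overflow
awp_inner <- function(Tg, M, co) {
  e1 <- exp((co$B1 - M) / co$A1)
  e2 <- exp((co$B2 - M) / co$A2)
  (co$D^2 / 22 * (e1 - e2) + 0.9854) * (1737.1 - 474242 / (273 + Tg)) +
    co$D * (1 - e1) - 68.578 / 7.72
}

#' Absolute water potential of grain
#'
#' Evaluates, per value,
#' `E_jg = 8.31 * (Tg + 273) * ln( exp(u) * 133.3 ) / 18` with
#' `u = (D^2/22 * (e^{(B1-M)/A1} - e^{(B2-M)/A2}) + 0.9854) *
#'      (1737.1 - 474242/(273+Tg)) + D * (1 - e^{(B1-M)/A1}) - 68.578/7.72`,
#' composed in the log domain (`ln(exp(u)*133.3) = u + ln 133.3`) so no
#' overflow can occur.  The grouping of the inner expression follows the
#' package's documented reconstruction and is isolated in one place so an
#' alternative grouping can be swapped without touching callers.
#'
#' @param Tg Grain temperature, degC, in `[-40, 60]`.
#' @param M Grain moisture content, percent, in `(0, 40)`.
#' @param coeffs A [grain_coefficients].
#' @return Absolute water potential, kJ/kg (vectorized over `Tg`).
#' @export
awp <- function(Tg, M, coeffs = grain_coefficients("wheat")) {
  if (any(Tg < -40 | Tg > 60)) stop("Tg out of range [-40, 60] degC")
  if (any(M <= 0 | M >= 40)) stop("M out of range (0, 40) percent")
  u <- awp_inner(Tg, M, coeffs)
  if (any(!is.finite(u))) {
    stop(sprintf("water-potential exponent non-finite at Tg=%g, M=%g",
                 Tg[which(!is.finite(u))[1]], M[1]))
  }
  8.31 * (Tg + 273) * (u + log(133.3)) / 18
}

#' Absolute water potential over a whole grid
#'
#' Element-wise [awp()] over an imputed temperature grid with that day's
#' (forward-filled) moisture.
#'
#' @param grid A [temperature_grid] with no missing voxels, or a 3D array.
#' @param moisture Scalar moisture percent for the day.
#' @param coeffs A [grain_coefficients].
#' @return Numeric 3D array of `E_jg`, aligned with the grid.
#' @export
awp_field <- function(grid, moisture, coeffs = grain_coefficients("wheat")) {
  v <- if (inherits(grid, "temperature_grid")) grid$values else grid
  if (any(is.na(v))) stop("grid has missing values; impute first")
  array(awp(as.vector(v), moisture, coeffs), dim(v))
}
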