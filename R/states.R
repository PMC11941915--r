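#' The six granary storage states
#'
#' A granary-day is in exactly one of six operational/risk conditions:
#' `normal` storage, `empty` (no grain in the bin), `aeration` (forced-air
#' cooling in progress), `new_grain` (fresh grain recently added),
#' `condensation` ("cold skin, hot core" vertical gradient risk), and
#' `mildew` (localized exothermic fungal heating).  The order is fixed and
#' used everywhere a state is encoded as an integer (classifier heads,
#' confusion matrices, weight vectors).
#'
#' @return Character vector of the six state names, in canonical order.
#' @export
storage_states <- function() {
  c("normal", "empty", "aeration", "new_grain", "condensation", "mildew")
}

#' Validate and canonicalize a storage-state label
#'
#' @param x Character or factor scalar/vector of state labels.
#' @return Factor with levels `storage_states()`.
#' @export
as_storage_state <- function(x) {
  x <- as.character(x)
  bad <- setdiff(unique(x), storage_states())
  if (length(bad) > 0) {
    stop("unknown storage state(s): ", paste(bad, collapse = ", "))
  }
  factor(x, levels = storage_states())
}

# risk states that trigger an alert (operational states do not)
risk_states <- function() c("condensation", "mildew")
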