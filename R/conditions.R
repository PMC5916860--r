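#' Structured conditions used across the package
#'
#' All recoverable failures are signalled as classed conditions so that batch
#' drivers can catch a specific failure (e.g. an empty segmentation mask)
#' without masking programming errors.
#'
#' @name riceleafdyn-conditions
#' @keywords internal
NULL

rld_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "riceleafdyn_error")))
}

stop_zero_area <- function(message = "region is empty (zero area)") {
  rld_error("rld_zero_area", message)
}

stop_no_leaf <- function(message = "no leaf-sized component found in image") {
  rld_error("rld_no_leaf", message)
}

stop_invariant <- function(message) {
  rld_error("rld_invariant_violation", message)
}

stop_division_by_zero <- function(message = "channel sum is zero") {
  rld_error("rld_division_by_zero", message)
}

stop_achromatic <- function(message = "achromatic color: hue undefined") {
  rld_error("rld_achromatic", message)
}

stop_nonpositive <- function(message = "non-positive value where a log is required") {
  rld_error("rld_nonpositive", message)
}

stop_bad_interval <- function(message = "interval end must exceed its start") {
  rld_error("rld_bad_interval", message)
}

stop_bad_spacing <- function(message = "spacing not representable on this schedule") {
  rld_error("rld_bad_spacing", message)
}

stop_fit_failure <- function(message, diagnostics = NULL) {
  rld_error("rld_fit_failure", message, diagnostics = diagnostics)
}

stop_degenerate_labels <- function(message = "need at least two classes") {
  rld_error("rld_degenerate_labels", message)
}

stop_empty_dataset <- function(message = "no complete rows left after dropping missing cells") {
  rld_error("rld_empty_dataset", message)
}

warn_tip_ambiguous <- function(message = "mask nearly isotropic: tip chosen by fixed convention") {
  warning(warningCondition(message, class = c("rld_tip_ambiguous", "riceleafdyn_warning")))
}

#' Record a skipped observation
#'
#' A `missing_observation` stands in for a leaf scan that does not exist
#' (senesced leaf) or could not be measured; batch drivers keep it as a row
#' with a machine-readable reason instead of aborting.
#'
#' @param reason short reason code, e.g. `"senesced"` or `"no_leaf_found"`.
#' @param ... metadata fields (plant_id, dat, leaf_position, ...).
#' @return an object of class `missing_observation`.
#' @export
missing_observation <- function(reason, ...) {
  structure(list(reason = reason, meta = list(...)), class = "missing_observation")
}

#' @export
print.missing_observation <- function(x, ...) {
  cat("<missing observation:", x$reason, ">\n")
  invisible(x)
}

#' Test for a missing observation
#' @param x object to test.
#' @return `TRUE` if `x` marks a missing observation.
#' @export
is_missing_observation <- function(x) inherits(x, "missing_observation")
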