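#' Rehydration curve
#'
#' A time series of moisture ratio (g water per g dry matter) for a
#' rehydrating dried gel.  This is the object all kinetic models fit.
#'
#' @param times sampling times in minutes; strictly increasing, first >= 0.
#' @param moisture moisture ratio M(t) in g/g; non-negative, same length as
#'   `times`.
#' @param W0 optional initial dry mass in grams (kept as metadata when the
#'   curve was derived from raw masses).
#' @return An object of class `rehydration_curve`: a data frame with columns
#'   `time_min` and `moisture_g_per_g`.
#' @seealso [fit_kinetics()], [gen_rehydration_curve()]
#' @export
rehydration_curve <- function(times, moisture, W0 = NULL) {
  times <- as.numeric(times)
  moisture <- as.numeric(moisture)
  if (length(times) != length(moisture)) {
    stop("`times` and `moisture` must have equal length", call. = FALSE)
  }
  if (anyNA(times) || anyNA(moisture) || any(!is.finite(times)) ||
      any(!is.finite(moisture))) {
    stop("`times` and `moisture` must be finite and free of NA", call. = FALSE)
  }
  if (length(times) > 0 && times[1] < 0) {
    stop("first sampling time must be >= 0", call. = FALSE)
  }
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(moisture < 0)) {
    stop("`moisture` must be non-negative", call. = FALSE)
  }
  out <- data.frame(time_min = times, moisture_g_per_g = moisture)
  class(out) <- c("rehydration_curve", "data.frame")
  if (!is.null(W0)) {
    attr(out, "W0") <- stopifnot_scalar(W0, "W0", positive = TRUE)
  }
  out
}

#' @export
print.rehydration_curve <- function(x, ...) {
  cat(sprintf("Rehydration curve: %d points, t in [%g, %g] min, M in [%g, %g] g/g\n",
              nrow(x), min(x$time_min), max(x$time_min),
              min(x$moisture_g_per_g), max(x$moisture_g_per_g)))
  invisible(x)
}

#' Rehydration ratio from sample masses
#'
#' Mass of absorbed water per gram of dry gel at a given moment:
#' `(Wt - W0) / W0`, where `W0` is the initial dry mass and `Wt` the mass
#' after rehydration.
#'
#' @param W0 initial dry mass (g), > 0.
#' @param Wt rehydrated mass (g), >= 0; may be a vector.
#' @return Rehydration ratio(s) in g water / g dry matter.
#' @examples
#' rehydration_ratio(1, 7.52)  # 6.52 g/g
#' @export
rehydration_ratio <- function(W0, Wt) {
  stopifnot_scalar(W0, "W0", positive = TRUE)
  if (any(!is.finite(Wt)) || any(Wt < 0)) {
    stop("`Wt` must be finite and >= 0", call. = FALSE)
  }
  (Wt - W0) / W0
}

#' Water-holding capacity after centrifugation
#'
#' Percentage of the rehydrated sample mass retained after centrifugation:
#' `100 * mass_after / mass_before`.  Centrifugation expels loosely held
#' water, so `mass_after` cannot exceed `mass_before`.
#'
#' @param mass_before sample mass before centrifugation (g), > 0.
#' @param mass_after sample mass after centrifugation (g), > 0 and
#'   <= `mass_before`.
#' @return Water-holding capacity in percent.
#' @examples
#' water_holding_capacity(10, 7.048)  # 70.48 %
#' @export
water_holding_capacity <- function(mass_before, mass_after) {
  stopifnot_scalar(mass_before, "mass_before", positive = TRUE)
  stopifnot_scalar(mass_after, "mass_after", positive = TRUE)
  if (mass_after > mass_before) {
    stop("`mass_after` exceeds `mass_before`: centrifugation cannot add mass",
         call. = FALSE)
  }
  100 * mass_after / mass_before
}
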