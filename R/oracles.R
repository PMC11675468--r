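#' Young-Laplace pressure jump across a meniscus in a cylindrical pore
#'
#' Static pressure difference across a spherical-cap gas-liquid interface
#' pinned in a cylindrical pore of radius `radius` at equilibrium contact
#' angle `theta_deg`:
#' \deqn{\Delta p = 2 \sigma \cos\theta / R.}
#' Used as an independent ground truth when validating the two-phase
#' level-set solver.
#'
#' @param sigma surface tension (N/m), > 0.
#' @param theta_deg contact angle (degrees), in (0, 180).
#' @param radius pore radius (m), > 0.
#' @return Pressure jump in Pa (water side minus air side for theta < 90).
#' @examples
#' young_laplace_jump(0.072, 0, 69.11e-6)    # fully wetting, ~2084 Pa
#' young_laplace_jump(0.072, 90, 69.11e-6)   # neutral wetting, 0
#' @export
young_laplace_jump <- function(sigma, theta_deg, radius) {
  stopifnot_scalar(sigma, "sigma", nonneg = TRUE)
  stopifnot_scalar(theta_deg, "theta_deg")
  stopifnot_scalar(radius, "radius", positive = TRUE)
  2 * sigma * cos(theta_deg * pi / 180) / radius
}

#' Jurin equilibrium capillary rise height
#'
#' Height at which the hydrostatic weight of the risen liquid column balances
#' the capillary pull: \eqn{h = 2 \sigma \cos\theta / (\rho g R)}.
#'
#' @param fluids a [fluid_pair()] (supplies sigma, contact angle, water
#'   density and gravity).
#' @param radius pore radius (m), > 0.
#' @return Equilibrium rise height in m.
#' @export
jurin_equilibrium_height <- function(fluids, radius) {
  stopifnot(inherits(fluids, "fluid_pair"))
  stopifnot_scalar(radius, "radius", positive = TRUE)
  2 * fluids$sigma * cos(fluids$contact_angle * pi / 180) /
    (fluids$rho_water * fluids$gravity * radius)
}

#' Lucas-Washburn viscous imbibition trajectory
#'
#' Penetration depth of a wetting liquid into a cylindrical pore in the
#' viscous-dominated regime:
#' \deqn{z(t) = \sqrt{\sigma R \cos\theta \, t / (2 \mu_w)}.}
#' Air viscosity is neglected, as is standard for liquid-gas imbibition.
#'
#' @param fluids a [fluid_pair()].
#' @param radius pore radius (m), > 0.
#' @param t time (s), >= 0; may be a vector.
#' @return Penetration depth(s) in m.
#' @export
washburn_trajectory <- function(fluids, radius, t) {
  stopifnot(inherits(fluids, "fluid_pair"))
  stopifnot_scalar(radius, "radius", positive = TRUE)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  cosi <- cos(fluids$contact_angle * pi / 180)
  sqrt(pmax(fluids$sigma * radius * cosi * t, 0) / (2 * fluids$mu_water))
}
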