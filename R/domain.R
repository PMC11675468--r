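#' Fluid properties of the water/air pair
#'
#' Property bundle for the two-phase capillary-filling model.  Defaults are
#' water and air at 25 degrees C with a wetted-wall contact angle of 70
#' degrees (a calibrated default: the static Young-Laplace jumps of the
#' three standard pore radii then fall inside the 200-1200 Pa band seen in
#' the pressure-field simulations; see the methods vignette).
#'
#' @param rho_water,rho_air densities (kg/m^3), > 0.
#' @param mu_water,mu_air dynamic viscosities (Pa s), > 0.
#' @param sigma surface tension (N/m), > 0.
#' @param contact_angle equilibrium contact angle at the gel wall (degrees),
#'   in (0, 180).
#' @param gravity gravitational acceleration (m/s^2), acting downward.
#' @param slip_length Navier slip length at wetted walls (m).  `NA` (the
#'   default) resolves to one grid spacing at simulation time.
#' @return An object of class `fluid_pair`.
#' @export
fluid_pair <- function(rho_water = 997, rho_air = 1.184,
                       mu_water = 8.9e-4, mu_air = 1.85e-5,
                       sigma = 0.072, contact_angle = 70,
                       gravity = 9.81, slip_length = NA_real_) {
  stopifnot_scalar(rho_water, "rho_water", positive = TRUE)
  stopifnot_scalar(rho_air, "rho_air", positive = TRUE)
  stopifnot_scalar(mu_water, "mu_water", positive = TRUE)
  stopifnot_scalar(mu_air, "mu_air", positive = TRUE)
  stopifnot_scalar(sigma, "sigma", nonneg = TRUE)
  stopifnot_scalar(contact_angle, "contact_angle")
  if (contact_angle <= 0 || contact_angle >= 180) {
    stop("`contact_angle` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  stopifnot_scalar(gravity, "gravity", nonneg = TRUE)
  if (!is.na(slip_length)) {
    stopifnot_scalar(slip_length, "slip_length", positive = TRUE)
  }
  structure(list(rho_water = rho_water, rho_air = rho_air,
                 mu_water = mu_water, mu_air = mu_air, sigma = sigma,
                 contact_angle = contact_angle, gravity = gravity,
                 slip_length = slip_length),
            class = "fluid_pair")
}

#' Build an axisymmetric pore-plus-reservoir simulation domain
#'
#' Constructs the structured r-z grid for a single vertical cylindrical pore
#' of radius `pore_radius_um` and length `pore_length_um` sitting on top of
#' a water reservoir (radius `reservoir_radius_um`, depth
#' `reservoir_depth_um`).  The gel occupying `r > pore_radius` above the
#' reservoir is masked as solid.  The reservoir bottom is a pressure inlet
#' (water inflow at gauge pressure 0) and the pore top a pressure outlet,
#' unless closed for validation set-ups.
#'
#' @param pore_radius_um pore radius in micrometres, in \[25, 250\] (the
#'   model targets pores of 50-500 um diameter).
#' @param pore_length_um pore length in micrometres, > 0.
#' @param h_um grid spacing in micrometres; must satisfy
#'   `h_um <= pore_radius_um / 8` (resolution floor for the interface).
#' @param reservoir_radius_um,reservoir_depth_um reservoir dimensions in
#'   micrometres; defaults scale with the pore radius.
#' @param open_top,open_bottom open the pore outlet / reservoir inlet
#'   (default) or close them (walls) for closed-domain validation tests.
#' @return Object of class `sim_domain`: grid dimensions, spacing (m),
#'   solid mask and derived indices.  Cell volumes carry the axisymmetric
#'   2*pi*r weight.
#' @examples
#' dom <- build_domain(69.11, 400, h_um = 4)
#' dom$iRp  # cells across the pore radius
#' @export
build_domain <- function(pore_radius_um, pore_length_um, h_um,
                         reservoir_radius_um = 1.5 * pore_radius_um,
                         reservoir_depth_um = pore_radius_um,
                         open_top = TRUE, open_bottom = TRUE) {
  stopifnot_scalar(pore_radius_um, "pore_radius_um", positive = TRUE)
  stopifnot_scalar(pore_length_um, "pore_length_um", positive = TRUE)
  stopifnot_scalar(h_um, "h_um", positive = TRUE)
  if (pore_radius_um < 25 || pore_radius_um > 250) {
    stop("`pore_radius_um` outside the modelled range [25, 250] um",
         call. = FALSE)
  }
  if (h_um > pore_radius_um / 8) {
    stop(sprintf(
      "grid spacing %.3g um under-resolves the interface: need h <= R/8 = %.3g um",
      h_um, pore_radius_um / 8), call. = FALSE)
  }
  if (reservoir_radius_um < pore_radius_um) {
    stop("reservoir radius must be >= pore radius", call. = FALSE)
  }
  iRp <- max(1L, as.integer(round(pore_radius_um / h_um)))
  Nr <- max(iRp, as.integer(round(reservoir_radius_um / h_um)))
  jD <- as.integer(round(reservoir_depth_um / h_um))
  jL <- max(1L, as.integer(round(pore_length_um / h_um)))
  Nz <- jD + jL
  mask <- matrix(0L, Nr, Nz)
  if (jD > 0) mask[, seq_len(jD)] <- 1L
  mask[seq_len(iRp), jD + seq_len(jL)] <- 1L
  structure(list(
    h = h_um * 1e-6, Nr = Nr, Nz = Nz, mask = mask,
    jD = jD, iRp = iRp,
    open_top = open_top, open_bottom = open_bottom,
    pore_radius = iRp * h_um * 1e-6,
    pore_length = jL * h_um * 1e-6,
    reservoir_radius = Nr * h_um * 1e-6,
    reservoir_depth = jD * h_um * 1e-6,
    pore_radius_nominal = pore_radius_um * 1e-6
  ), class = "sim_domain")
}

#' @export
print.sim_domain <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric domain: pore R = %.2f um x L = %.0f um, reservoir %.0f x %.0f um\n",
    x$pore_radius * 1e6, x$pore_length * 1e6,
    x$reservoir_radius * 1e6, x$reservoir_depth * 1e6))
  cat(sprintf("  grid %d x %d cells, h = %.2f um, %s top, %s bottom\n",
              x$Nr, x$Nz, x$h * 1e6,
              if (x$open_top) "open" else "closed",
              if (x$open_bottom) "open" else "closed"))
  invisible(x)
}

# grid descriptor consumed by the C++ kernels
grid_for_cpp <- function(domain, fluids) {
  slip <- fluids$slip_length
  if (is.na(slip)) slip <- domain$h
  list(Nr = domain$Nr, Nz = domain$Nz, h = domain$h, mask = domain$mask,
       open_top = domain$open_top, open_bottom = domain$open_bottom,
       slip = slip, jD = domain$jD, iRp = domain$iRp)
}

#' Initialise the two-phase state
#'
#' The reservoir is filled with water and the pore with air; the level-set
#' field is smoothed to the equilibrium tanh profile of half-thickness
#' `eps = h/2` across the initially flat interface at the reservoir
#' surface.  Velocity starts at rest; pressure is hydrostatic in the water
#' column and zero in air.  For closed-domain validation tests, `drop`
#' replaces the flat interface by a spherical water drop centred on the
#' axis.
#'
#' @param domain a [build_domain()] grid.
#' @param fluids a [fluid_pair()].
#' @param water_level_um height of the initial water surface above the
#'   domain bottom (um); defaults to the reservoir depth (pore inlet).
#' @param drop optional `list(center_z_um, radius_um)` for a spherical drop
#'   initial condition (replaces the reservoir fill).
#' @return Object of class `twophase_state` with fields `phi` (Nr x Nz),
#'   `ur` ((Nr+1) x Nz), `uz` (Nr x (Nz+1)), `p` (Nr x Nz), `t`, `eps`,
#'   `gamma`.
#' @export
initialize_state <- function(domain, fluids,
                             water_level_um = domain$reservoir_depth * 1e6,
                             drop = NULL) {
  stopifnot(inherits(domain, "sim_domain"), inherits(fluids, "fluid_pair"))
  h <- domain$h
  eps <- h / 2
  Nr <- domain$Nr; Nz <- domain$Nz
  rc <- (seq_len(Nr) - 0.5) * h
  zc <- (seq_len(Nz) - 0.5) * h
  if (is.null(drop)) {
    zw <- water_level_um * 1e-6
    # signed distance to the flat interface (positive in water)
    d <- outer(rep(1, Nr), zw - zc)
  } else {
    cz <- drop$center_z_um * 1e-6
    rad <- drop$radius_um * 1e-6
    d <- rad - sqrt(outer(rc^2, (zc - cz)^2, `+`))
  }
  phi <- 0.5 * (1 + tanh(d / (2 * eps)))
  phi[domain$mask == 0L] <- 0
  p <- matrix(0, Nr, Nz)
  if (is.null(drop)) {
    zw <- water_level_um * 1e-6
    hyd <- fluids$rho_water * fluids$gravity * pmax(zw - zc, 0)
    p <- outer(rep(1, Nr), hyd) * (phi > 0.5)
  }
  p[domain$mask == 0L] <- 0
  structure(list(phi = phi, ur = matrix(0, Nr + 1, Nz),
                 uz = matrix(0, Nr, Nz + 1), p = p,
                 t = 0, eps = eps, gamma = 0),
            class = "twophase_state")
}

#' @export
print.twophase_state <- function(x, ...) {
  cat(sprintf(
    "Two-phase state at t = %.4g s: phi in [%.3f, %.3f], max|u| = %.3g m/s\n",
    x$t, min(x$phi), max(x$phi), max(abs(x$ur), abs(x$uz))))
  invisible(x)
}
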