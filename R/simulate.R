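#' Mixture and interface fields of a two-phase state
#'
#' Cell-centred fields derived from the level-set function: mixture density
#' `rho = rho_air + (rho_water - rho_air) phi` and viscosity
#' `mu = mu_air + (mu_water - mu_air) phi`, the smoothed interface delta
#' `6 |phi(1-phi)| |grad phi|`, the interface normal `grad phi / |grad phi|`
#' and the curvature `kappa = -div n` (face-normal divergence, with the
#' contact-angle ghost applied at wetted walls).  Cells with `|grad phi| = 0`
#' report a zero normal and zero curvature.
#'
#' @param state a [initialize_state()] / advanced `twophase_state`.
#' @param domain the [build_domain()] grid.
#' @param fluids a [fluid_pair()].
#' @return List of Nr x Nz matrices: `rho`, `mu`, `delta`, `normal_r`,
#'   `normal_z`, `kappa`.
#' @export
mixture_fields <- function(state, domain, fluids) {
  stopifnot(inherits(state, "twophase_state"))
  cpp_mixture_fields(grid_for_cpp(domain, fluids), unclass(fluids), state$phi)
}

#' Continuum surface-tension body force
#'
#' The capillary force `F = sigma * kappa * delta * n`, discretised at the
#' staggered velocity faces as `sigma * kappa_f * 6 phi(1-phi) grad phi`
#' so that it balances the discrete pressure gradient.
#'
#' @inheritParams mixture_fields
#' @return List with face fields `Fr` ((Nr+1) x Nz) and `Fz` (Nr x (Nz+1)),
#'   in N/m^3.
#' @export
surface_tension_force <- function(state, domain, fluids) {
  stopifnot(inherits(state, "twophase_state"))
  cpp_surface_tension(grid_for_cpp(domain, fluids), unclass(fluids), state$phi)
}

# admissible explicit time step for the current state
admissible_dt <- function(state, domain, fluids, cfl = 0.5) {
  h <- domain$h
  nu_max <- max(fluids$mu_water / fluids$rho_water,
                fluids$mu_air / fluids$rho_air)
  dt_visc <- h^2 / (6 * nu_max)
  dt_cap <- if (fluids$sigma > 0) {
    sqrt((fluids$rho_water + fluids$rho_air) / 2 * h^3 /
           (4 * pi * fluids$sigma))
  } else Inf
  umax <- max(abs(state$ur), abs(state$uz), state$gamma, 1e-6)
  cfl * min(dt_visc, dt_cap, h / umax)
}

#' Advance the level-set field by one step
#'
#' Conservative transport of the water volume fraction by the current
#' velocity (MUSCL-limited upwind fluxes) plus the interface-sharpening
#' reinitialisation term `gamma * div(eps grad phi - phi(1-phi) n)`.
#' The step is rejected if `dt` exceeds the explicit stability limit; the
#' admissible step is reported in the error.
#'
#' @inheritParams mixture_fields
#' @param dt time step (s).
#' @return The updated `twophase_state` (phi advanced, time incremented).
#' @export
advance_level_set <- function(state, domain, fluids, dt) {
  stopifnot(inherits(state, "twophase_state"))
  dt_adm <- admissible_dt(state, domain, fluids, cfl = 1)
  if (dt > dt_adm) {
    stop(sprintf("dt = %.3g s violates the CFL limit; admissible dt <= %.3g s",
                 dt, dt_adm), call. = FALSE)
  }
  state$phi <- cpp_levelset_step(grid_for_cpp(domain, fluids),
                                 unclass(fluids), state$phi, state$ur,
                                 state$uz, dt, state$eps, state$gamma)
  state$t <- state$t + dt
  state
}

#' Advance the flow field by one incompressible step
#'
#' Explicit momentum predictor (upwind convection, variable-viscosity
#' diffusion with Navier wall friction, surface tension, gravity) followed
#' by a variable-density pressure projection enforcing a divergence-free
#' velocity to relative tolerance `div_rtol` (max cell divergence below
#' `div_rtol * max|u| / h`).  Open boundaries carry gauge pressure 0.
#'
#' @inheritParams advance_level_set
#' @param div_rtol relative divergence tolerance of the projection.
#' @param maxit conjugate-gradient iteration cap; exceeding it aborts with
#'   diagnostics.
#' @return The updated `twophase_state` (`ur`, `uz`, `p` advanced).
#' @export
advance_flow <- function(state, domain, fluids, dt, div_rtol = 1e-8,
                         maxit = 20000L) {
  stopifnot(inherits(state, "twophase_state"))
  res <- cpp_flow_step(grid_for_cpp(domain, fluids), unclass(fluids),
                       state$phi, state$ur, state$uz, state$p,
                       dt, div_rtol, as.integer(maxit))
  state$ur <- res$ur
  state$uz <- res$uz
  state$p <- res$p
  state$gamma <- max(state$gamma, max(abs(res$ur)), max(abs(res$uz)))
  state
}

#' Run the coupled capillary-filling simulation
#'
#' Time-steps the two-phase level-set / Navier-Stokes system from the rest
#' state until `t_end_s`, the pore is full (`fill_fraction >= fill_stop`),
#' or an instability is detected (the last valid snapshot is returned with
#' `status = "nan"`).  The reinitialisation velocity scale `gamma` tracks
#' the running maximum flow speed.
#'
#' @param domain a [build_domain()] grid.
#' @param fluids a [fluid_pair()].
#' @param t_end_s end time (s).
#' @param cfl safety factor on the explicit stability limit.
#' @param record_every record interface diagnostics every this many steps.
#' @param snapshot_dt_s interval between stored field snapshots (s).
#' @param fill_stop fill fraction at which the run terminates (pore deemed
#'   fully covered).
#' @param div_rtol,maxit projection controls, see [advance_flow()].
#' @param max_steps hard step cap.
#' @param state optional initial state (default [initialize_state()]).
#' @return List with `trace` (an `interface_trace` data frame: time,
#'   fill fraction, contact-point height in um above the pore inlet, max
#'   speed, total water volume), `snapshots` (list of field snapshots with
#'   their times), `snapshot_metrics` (per-snapshot [interface_metrics()]
#'   including the interface pressure jump), `fill_time_s` (first time the
#'   pore is fully covered, `NA` if not reached), `state` (final fields)
#'   and `status`.
#' @export
run_capillary_filling <- function(domain, fluids, t_end_s,
                                  cfl = 0.5, record_every = 10L,
                                  snapshot_dt_s = t_end_s / 10,
                                  fill_stop = 0.999,
                                  div_rtol = 1e-8, maxit = 20000L,
                                  max_steps = 2e6, state = NULL) {
  stopifnot(inherits(domain, "sim_domain"), inherits(fluids, "fluid_pair"))
  stopifnot_scalar(t_end_s, "t_end_s", positive = TRUE)
  if (is.null(state)) state <- initialize_state(domain, fluids)
  gl <- grid_for_cpp(domain, fluids)
  res <- cpp_run(gl, unclass(fluids), state$phi, state$ur, state$uz,
                 state$p, state$t, t_end_s, state$eps, state$gamma,
                 cfl, div_rtol, as.integer(maxit), as.integer(record_every),
                 snapshot_dt_s, fill_stop, as.integer(max_steps))
  trace <- data.frame(
    time_s = res$trace$times,
    fill_fraction = res$trace$fill_fraction,
    contact_point_height_um = res$trace$contact_point_height * 1e6,
    max_speed_m_s = res$trace$umax,
    water_volume_m3 = res$trace$water_volume
  )
  class(trace) <- c("interface_trace", "data.frame")
  final <- structure(list(phi = res$phi, ur = res$ur, uz = res$uz,
                          p = res$p, t = res$t, eps = state$eps,
                          gamma = res$gamma),
                     class = "twophase_state")
  snap_metrics <- do.call(rbind, lapply(res$snapshots, function(sn) {
    st <- structure(list(phi = sn$phi, ur = sn$ur, uz = sn$uz, p = sn$p,
                         t = sn$t, eps = state$eps, gamma = res$gamma),
                    class = "twophase_state")
    m <- interface_metrics(st, domain)
    data.frame(time_s = sn$t, fill_fraction = m$fill_fraction,
               contact_point_height_um = m$contact_point_height_um,
               pressure_jump_Pa = m$pressure_jump_Pa)
  }))
  list(trace = trace, snapshots = res$snapshots,
       snapshot_metrics = snap_metrics,
       fill_time_s = if (is.na(res$fill_time)) NA_real_ else res$fill_time,
       state = final, status = res$status, n_steps = res$n_steps)
}

#' Interface diagnostics of a two-phase state
#'
#' Computes, inside the pore: the fill fraction (phi-weighted water volume
#' over pore volume), the contact-point height (highest `phi = 0.5`
#' crossing of the wall-adjacent cell column, linearly interpolated,
#' measured from the pore inlet) and the interface pressure jump (mean
#' pressure over water-side cells `phi > 0.9` adjacent to the interface
#' band minus the mean over air-side cells `phi < 0.1` adjacent to it).
#' When the pore holds no interface the pressure jump is reported as `NA`
#' (absent), not zero.
#'
#' @inheritParams mixture_fields
#' @param band_halfwidth how many cells from the interface band still count
#'   as "adjacent".
#' @return List with `fill_fraction`, `contact_point_height_um`,
#'   `pressure_jump_Pa`.
#' @export
interface_metrics <- function(state, domain, band_halfwidth = 2L) {
  stopifnot(inherits(state, "twophase_state"), inherits(domain, "sim_domain"))
  gl <- grid_for_cpp(domain, fluid_pair())
  d <- cpp_diagnostics(gl, state$phi)

  jump <- NA_real_
  iRp <- domain$iRp; jD <- domain$jD
  if (iRp >= 1 && domain$Nz > jD) {
    phi <- state$phi[seq_len(iRp), (jD + 1):domain$Nz, drop = FALSE]
    p <- state$p[seq_len(iRp), (jD + 1):domain$Nz, drop = FALSE]
    band <- phi > 0.1 & phi < 0.9
    if (any(band)) {
      near <- dilate_mask(band, band_halfwidth)
      water <- near & phi > 0.9
      air <- near & phi < 0.1
      if (any(water) && any(air)) {
        jump <- mean(p[water]) - mean(p[air])
      }
    }
  }
  list(fill_fraction = d$fill_fraction,
       contact_point_height_um = d$contact_point_height * 1e6,
       pressure_jump_Pa = jump)
}

# binary dilation of a logical matrix by k cells (von Neumann neighbourhood)
dilate_mask <- function(m, k) {
  out <- m
  for (iter in seq_len(k)) {
    grown <- out
    nr <- nrow(out); nc <- ncol(out)
    grown[-1, ] <- grown[-1, ] | out[-nr, ]
    grown[-nr, ] <- grown[-nr, ] | out[-1, ]
    grown[, -1] <- grown[, -1] | out[, -nc]
    grown[, -nc] <- grown[, -nc] | out[, -1]
    out <- grown
  }
  out
}
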