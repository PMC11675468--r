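# shared fixtures and a session-level cache for expensive simulations

water_air <- function(...) fluid_pair(...)

# standard noise-free generating specs for the three kinetic models
std_params <- list(
  weibull = list(a = 20, beta = 0.8),
  first_order = list(k = 0.05),
  peleg = list(K1 = 3.3, K2 = 0.154)
)

make_curve <- function(model, noise_sd = 0, seed = 1, M0 = 0, Me = 6.5,
                       params = std_params[[model]]) {
  suppressMessages(gen_rehydration_curve(
    curve_spec(model, params, M0 = M0, Me = Me, noise_sd = noise_sd,
               seed = seed)))
}

# cache shared across test files (files run in one process, alphabetically)
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .sim_cache)) {
    assign(key, force(expr), envir = .sim_cache)
  }
  get(key, envir = .sim_cache)
}

# capillary-filling run for one of the standard pore radii; h_um = 2 is the
# reference resolution, coarser grids are used for auxiliary checks
fill_run <- function(radius_um, h_um = 2, t_end_s = 1.5e-3, fill_stop = 0.999,
                     snapshot_dt_s = 1e-4) {
  key <- sprintf("fill_%g_%g_%g", radius_um, h_um, t_end_s)
  cached(key, {
    dom <- build_domain(radius_um, 400, h_um = h_um)
    run_capillary_filling(dom, fluid_pair(), t_end_s = t_end_s,
                          record_every = 50L, snapshot_dt_s = snapshot_dt_s,
                          fill_stop = fill_stop)
  })
}

# static spherical drop in a closed box (no gravity): spurious currents,
# Young-Laplace jump of a sphere, closed-domain volume conservation
drop_run <- function(t_end_s = 9e-4) {
  cached("drop", {
    dom <- build_domain(100, 200, h_um = 4, reservoir_radius_um = 100,
                        reservoir_depth_um = 0, open_top = FALSE,
                        open_bottom = FALSE)
    fl <- fluid_pair(gravity = 0, contact_angle = 90)
    st <- initialize_state(dom, fl,
                           drop = list(center_z_um = 100, radius_um = 40))
    st$gamma <- 0.01
    res <- run_capillary_filling(dom, fl, t_end_s = t_end_s,
                                 record_every = 50L, snapshot_dt_s = t_end_s,
                                 state = st)
    res$domain <- dom; res$fluids <- fl
    res
  })
}

# meniscus relaxing in a closed-top pore (no net flow possible): static
# Young-Laplace benchmark at the standard contact angle
static_meniscus_run <- function() {
  cached("static_meniscus", {
    dom <- build_domain(41.67, 160, h_um = 2, open_top = FALSE)
    fl <- fluid_pair(gravity = 0)
    st <- initialize_state(dom, fl,
                           water_level_um = (dom$reservoir_depth + 80e-6) * 1e6)
    res <- run_capillary_filling(dom, fl, t_end_s = 4e-4, record_every = 200L,
                                 snapshot_dt_s = 4e-4, state = st)
    res$domain <- dom; res$fluids <- fl
    res
  })
}

# capillary rise against boosted gravity: equilibrium at the Jurin height
# (gravity scaled so the equilibrium fits in a 250 um pore; viscosity raised
# to damp the approach)
jurin_run <- function() {
  cached("jurin", {
    R_um <- 30
    h_eq <- 150e-6
    g <- 2 * 0.072 * cos(70 * pi / 180) / (997 * R_um * 1e-6 * h_eq)
    fl <- fluid_pair(gravity = g, mu_water = 3e-3)
    dom <- build_domain(R_um, 250, h_um = 3)
    res <- run_capillary_filling(dom, fl, t_end_s = 2e-3, record_every = 100L,
                                 snapshot_dt_s = 2e-3)
    res$domain <- dom; res$fluids <- fl; res$h_eq <- h_eq
    res
  })
}

# long-pore viscous imbibition (viscosity raised so the viscous regime is
# reached within the pore): Lucas-Washburn sqrt(t) trajectory
washburn_run <- function() {
  cached("washburn", {
    fl <- fluid_pair(gravity = 0, mu_water = 0.02)
    dom <- build_domain(30, 600, h_um = 3)
    res <- run_capillary_filling(dom, fl, t_end_s = 1.2e-3,
                                 record_every = 200L, snapshot_dt_s = 1.2e-3)
    res$domain <- dom; res$fluids <- fl
    res
  })
}

# interpolated contact-point height at given times
contact_at <- function(trace, times_s) {
  approx(trace$time_s, trace$contact_point_height_um, xout = times_s)$y
}

# snapshot pressure-jump magnitude nearest to a given time
jump_at <- function(res, t_s) {
  sm <- res$snapshot_metrics
  abs(sm$pressure_jump_Pa[which.min(abs(sm$time_s - t_s))])
}
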