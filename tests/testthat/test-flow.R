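test_that("a quiescent state without forcing stays at rest", {
  dom <- build_domain(40, 100, h_um = 4)
  fl <- fluid_pair(sigma = 0, gravity = 0)
  st <- initialize_state(dom, fl)
  st2 <- advance_flow(st, dom, fl, 1e-7)
  expect_equal(max(abs(st2$ur), abs(st2$uz)), 0)
})

test_that("gravity in a closed water box settles to hydrostatic balance", {
  dom <- build_domain(50, 100, h_um = 5, reservoir_radius_um = 50,
                      reservoir_depth_um = 0, open_top = FALSE,
                      open_bottom = FALSE)
  fl <- fluid_pair(sigma = 0, contact_angle = 90)
  st <- initialize_state(dom, fl, water_level_um = 1e9)  # single fluid
  for (k in 1:300) {
    dt <- gelrehyd:::admissible_dt(st, dom, fl)
    st <- advance_level_set(st, dom, fl, dt)
    st <- advance_flow(st, dom, fl, dt)
  }
  expect_lt(max(abs(st$ur), abs(st$uz)), 1e-6)
  dpdz <- (st$p[5, 2] - st$p[5, dom$Nz - 1]) / ((dom$Nz - 3) * dom$h)
  expect_lt(abs(dpdz / (fl$rho_water * fl$gravity) - 1), 0.01)
})

test_that("projection leaves the velocity divergence-free to tolerance", {
  res <- fill_run(69.11, h_um = 4, t_end_s = 2e-5)
  s <- res$state
  dom <- build_domain(69.11, 400, h_um = 4)
  h <- dom$h; Nr <- dom$Nr; Nz <- dom$Nz
  rc <- (seq_len(Nr) - 0.5) * h; rf <- (0:Nr) * h
  div <- (sweep(s$ur[2:(Nr + 1), , drop = FALSE], 1, rf[2:(Nr + 1)], `*`) -
          sweep(s$ur[1:Nr, , drop = FALSE], 1, rf[1:Nr], `*`)) / (rc * h) +
         (s$uz[, 2:(Nz + 1), drop = FALSE] - s$uz[, 1:Nz, drop = FALSE]) / h
  div[dom$mask == 0L] <- 0
  uref <- max(abs(s$ur), abs(s$uz), s$gamma)
  expect_lt(max(abs(div)), 1.2 * 1e-8 * uref / h)
})

test_that("without surface tension the pore barely fills within 1 ms", {
  dom <- build_domain(69.11, 400, h_um = 8)
  fl <- fluid_pair(sigma = 0)
  res <- run_capillary_filling(dom, fl, t_end_s = 1e-3, record_every = 200,
                               snapshot_dt_s = 1e-3)
  expect_lt(max(res$trace$fill_fraction), 0.05)
})
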