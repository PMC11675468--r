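test_that("build_domain resolves the pore and rejects bad geometry", {
  dom <- build_domain(69.11, 400, h_um = 2)
  expect_equal(dom$iRp, 35)            # ~35 cells across the radius
  expect_equal(dom$pore_length, 400e-6)
  expect_error(build_domain(40, 100, h_um = 6), "under-resolve")
  expect_error(build_domain(20, 100, h_um = 2), "range")
  expect_error(build_domain(300, 100, h_um = 10), "range")
})

test_that("axisymmetric cell volumes reproduce the cylinder volume", {
  dom <- build_domain(69.11, 400, h_um = 2)
  h <- dom$h
  rc <- (seq_len(dom$iRp) - 0.5) * h
  vol <- sum(2 * pi * rc * h * h) * (dom$Nz - dom$jD)
  expect_lt(abs(vol / (pi * dom$pore_radius^2 * dom$pore_length) - 1), 0.01)
})

test_that("initial state is dry pore over full reservoir at rest", {
  dom <- build_domain(60, 300, h_um = 5)
  fl <- fluid_pair()
  st <- initialize_state(dom, fl)
  gl <- gelrehyd:::grid_for_cpp(dom, fl)
  d <- gelrehyd:::cpp_diagnostics(gl, st$phi)
  expect_lt(d$fill_fraction, 0.01)            # pore starts dry
  expect_equal(d$contact_point_height, 0)     # contact at the reservoir surface
  expect_equal(st$phi[1, 1], 1, tolerance = 1e-6)   # reservoir bottom water
  expect_equal(st$phi[1, dom$Nz], 0, tolerance = 1e-6)  # pore top air
  expect_true(all(st$ur == 0) && all(st$uz == 0))
  # total initial water volume = reservoir volume within one cell layer
  res_vol <- pi * dom$reservoir_radius^2 * dom$reservoir_depth
  layer <- pi * dom$reservoir_radius^2 * dom$h
  expect_lt(abs(d$water_volume - res_vol), layer)
})

test_that("mixture fields recover the single-phase limits", {
  dom <- build_domain(40, 100, h_um = 4)
  fl <- fluid_pair()
  st <- initialize_state(dom, fl)
  st$phi[] <- 1; st$phi[dom$mask == 0L] <- 0
  mf <- mixture_fields(st, dom, fl)
  expect_equal(mf$rho[1, 1], fl$rho_water)    # pins the mixture-rule sign
  expect_equal(mf$mu[1, 1], fl$mu_water)
  expect_true(all(mf$delta[dom$mask == 1L] == 0))  # no interface, no delta
  st$phi[] <- 0
  mf0 <- mixture_fields(st, dom, fl)
  expect_equal(mf0$rho[1, 1], fl$rho_air)
  expect_true(all(mf0$delta == 0))
})

test_that("curvature of a spherical water blob is 2/r within 5%", {
  dom <- build_domain(100, 200, h_um = 4, reservoir_radius_um = 100,
                      reservoir_depth_um = 0, open_top = FALSE,
                      open_bottom = FALSE)
  st <- initialize_state(dom, fluid_pair(),
                         drop = list(center_z_um = 100, radius_um = 40))
  mf <- mixture_fields(st, dom, fluid_pair())
  band <- mf$delta > 0.1 * max(mf$delta)
  kbar <- weighted.mean(mf$kappa[band], mf$delta[band])
  expect_lt(abs(kbar / (2 / 40e-6) - 1), 0.05)
})

test_that("surface tension force vanishes without sigma or curvature", {
  dom <- build_domain(40, 160, h_um = 4, reservoir_radius_um = 40,
                      reservoir_depth_um = 0, open_top = FALSE,
                      open_bottom = FALSE)
  st <- initialize_state(dom, fluid_pair(contact_angle = 90),
                         water_level_um = 80)
  f0 <- surface_tension_force(st, dom, fluid_pair(sigma = 0))
  expect_true(all(f0$Fr == 0) && all(f0$Fz == 0))
  # flat interface, neutral wetting: zero curvature, force far below the
  # capillary scale sigma/h^2
  ff <- surface_tension_force(st, dom, fluid_pair(contact_angle = 90))
  expect_lt(max(abs(ff$Fz)), 1e-6 * fluid_pair()$sigma / dom$h^2)
})
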