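test_that("reinitialisation has the equilibrium profile as fixed point", {
  # closed box, neutral wetting: relax to the discrete equilibrium of the
  # sharpening operator, then one more step must leave phi unchanged
  dom <- build_domain(40, 160, h_um = 4, reservoir_radius_um = 40,
                      reservoir_depth_um = 0, open_top = FALSE,
                      open_bottom = FALSE)
  fl <- fluid_pair(contact_angle = 90)
  st <- initialize_state(dom, fl, water_level_um = 80)
  st$gamma <- 0.5
  dt <- 1e-7
  for (k in 1:3000) st <- advance_level_set(st, dom, fl, dt)
  st2 <- advance_level_set(st, dom, fl, dt)
  expect_lt(max(abs(st2$phi - st$phi)), 1e-6)
})

test_that("gamma = 0 with zero velocity leaves phi exactly unchanged", {
  dom <- build_domain(40, 100, h_um = 4)
  fl <- fluid_pair()
  st <- initialize_state(dom, fl)
  st$gamma <- 0
  st2 <- advance_level_set(st, dom, fl, 1e-7)
  expect_identical(st2$phi, st$phi)
})

test_that("transport plus reinitialisation conserve water in a closed box", {
  dom <- build_domain(40, 160, h_um = 4, reservoir_radius_um = 40,
                      reservoir_depth_um = 0, open_top = FALSE,
                      open_bottom = FALSE)
  fl <- fluid_pair(contact_angle = 90)
  st <- initialize_state(dom, fl, water_level_um = 80)
  st$gamma <- 0.5
  gl <- gelrehyd:::grid_for_cpp(dom, fl)
  v0 <- gelrehyd:::cpp_diagnostics(gl, st$phi)$water_volume
  # wall-bounded reinitialisation must not create or destroy water
  for (k in 1:200) st <- advance_level_set(st, dom, fl, 1e-7)
  v1 <- gelrehyd:::cpp_diagnostics(gl, st$phi)$water_volume
  expect_lt(abs(v1 / v0 - 1), 1e-4 * 200)
})

test_that("CFL violations are rejected with the admissible step reported", {
  dom <- build_domain(40, 100, h_um = 4)
  fl <- fluid_pair()
  st <- initialize_state(dom, fl)
  st$gamma <- 1
  expect_error(advance_level_set(st, dom, fl, 1), "admissible dt")
})

test_that("phi stays within [0, 1] through a dynamic run", {
  res <- fill_run(69.11, h_um = 4, t_end_s = 1e-4)
  expect_true(all(res$state$phi >= 0 & res$state$phi <= 1))
})
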