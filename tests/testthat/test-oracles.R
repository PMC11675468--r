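test_that("Young-Laplace jump matches the closed form and its limits", {
  expect_equal(young_laplace_jump(0.072, 90, 1e-3), 0)
  expect_equal(young_laplace_jump(0.072, 0, 69.11e-6),
               2 * 0.072 / 69.11e-6, tolerance = 1e-12)
  expect_equal(young_laplace_jump(0.072, 0, 69.11e-6), 2083.6,
               tolerance = 1e-4)
  expect_equal(young_laplace_jump(0.072, 70, 41.67e-6), 1182, tolerance = 1e-3)
  expect_error(young_laplace_jump(0.072, 0, -1), "radius")
})

test_that("Jurin height matches the closed form and exceeds the pore length", {
  fl <- fluid_pair(sigma = 0.072, contact_angle = 90)
  expect_equal(jurin_equilibrium_height(fl, 1e-3), 0, tolerance = 1e-12)
  fl0 <- fluid_pair(rho_water = 1000, sigma = 0.072, contact_angle = 0.0001,
                    gravity = 9.81)
  expect_equal(jurin_equilibrium_height(fl0, 1e-3), 14.68e-3, tolerance = 1e-3)
  # standard pore: equilibrium rise is ~72.6 mm >> 400 um pore length,
  # so the simulated pore must fill completely
  fl70 <- fluid_pair()
  h <- jurin_equilibrium_height(fl70, 69.11e-6)
  expect_equal(h, 72.6e-3, tolerance = 0.01)
  expect_gt(h, 400e-6)
})

test_that("Washburn trajectory has the closed form and sqrt(t) scaling", {
  fl <- fluid_pair(mu_water = 1e-3, contact_angle = 0.0001)
  expect_equal(washburn_trajectory(fl, 69.11e-6, 0), 0)
  expect_equal(washburn_trajectory(fl, 69.11e-6, 1e-3), 1.58e-3,
               tolerance = 2e-3)
  t <- c(1e-4, 2e-4, 5e-4)
  expect_equal(washburn_trajectory(fl, 50e-6, 4 * t),
               2 * washburn_trajectory(fl, 50e-6, t), tolerance = 1e-12)
})

test_that("oracles are monotone in cos(theta) and inverse in radius", {
  thetas <- c(10, 30, 50, 70, 85)
  radii <- c(30e-6, 50e-6, 100e-6)
  jumps <- vapply(thetas, young_laplace_jump, numeric(1), sigma = 0.072,
                  radius = 50e-6)
  expect_true(all(diff(jumps) < 0))  # decreasing with theta (cos decreasing)
  for (th in thetas) {
    fl <- fluid_pair(contact_angle = th)
    hts <- vapply(radii, jurin_equilibrium_height, numeric(1), fluids = fl)
    # exact inverse proportionality to radius
    expect_equal(hts * radii / (hts[1] * radii[1]), rep(1, 3),
                 tolerance = 1e-12)
    jj <- vapply(radii, young_laplace_jump, numeric(1), sigma = fl$sigma,
                 theta_deg = th)
    expect_equal(jj * radii / (jj[1] * radii[1]), rep(1, 3), tolerance = 1e-12)
  }
})
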