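# module-level physics invariants of the capillary-filling solver; the
# headline reproduction checks live in test-acceptance.R and share these
# cached runs

test_that("closed-domain water volume drifts less than 1% over the run", {
  res <- drop_run()
  v <- res$trace$water_volume_m3
  expect_gt(res$n_steps, 5000)
  expect_lt(max(abs(v / v[1] - 1)), 0.01)
})

test_that("static drop: spurious currents stay below 1% of sigma/mu", {
  res <- drop_run()
  s <- res$state
  u_cap <- res$fluids$sigma / res$fluids$mu_water
  expect_lt(max(abs(s$ur), abs(s$uz)), 0.01 * u_cap)
})

test_that("static drop pressure jump approximates 2 sigma / r", {
  res <- drop_run()
  s <- res$state
  dp <- mean(s$p[s$phi > 0.95]) - mean(s$p[s$phi < 0.05])
  expect_lt(abs(dp / (2 * res$fluids$sigma / 40e-6) - 1), 0.10)
})

test_that("interface metrics report absence without an interface in the pore", {
  dom <- build_domain(40, 100, h_um = 4)
  fl <- fluid_pair()
  st <- initialize_state(dom, fl)
  st$phi[seq_len(dom$iRp), (dom$jD + 1):dom$Nz] <- 1   # force a wet pore
  m <- interface_metrics(st, dom)
  expect_equal(m$fill_fraction, 1, tolerance = 1e-9)
  expect_true(is.na(m$pressure_jump_Pa))
})

test_that("halving the grid changes the bulk filling time by < 10%", {
  t95 <- function(res) {
    tr <- res$trace
    approx(tr$fill_fraction, tr$time_s, xout = 0.95, ties = "ordered")$y
  }
  coarse <- fill_run(69.11, h_um = 4)
  fine <- fill_run(69.11, h_um = 2)
  expect_lt(abs(t95(coarse) / t95(fine) - 1), 0.10)
})

test_that("filling terminates with a monotone early-stage advance", {
  res <- fill_run(69.11, h_um = 2)
  expect_equal(res$status, "filled")
  tr <- res$trace
  early <- tr$time_s <= 4e-4
  expect_true(all(diff(tr$fill_fraction[early]) > -1e-3))
  expect_true(all(diff(tr$contact_point_height_um[early]) > -1))
})
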