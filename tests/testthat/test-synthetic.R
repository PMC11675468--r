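test_that("curve generator evaluates the model exactly when noise-free", {
  # Weibull at t = a gives Me*(1 - exp(-1)) when M0 = 0
  sp <- curve_spec("weibull", list(a = 20, beta = 0.8), M0 = 0, Me = 6.5,
                   times = c(0, 10, 20, 40), noise_sd = 0)
  cv <- gen_rehydration_curve(sp)
  expect_equal(cv$moisture_g_per_g[3], 6.5 * (1 - exp(-1)), tolerance = 1e-12)
  expect_equal(cv$moisture_g_per_g[3], 4.109, tolerance = 1e-3)
  expect_equal(cv$moisture_g_per_g[1], 0)
})

test_that("generators are bit-reproducible under a fixed seed", {
  sp <- curve_spec("weibull", list(a = 20, beta = 0.8), noise_sd = 0.05,
                   seed = 42)
  expect_identical(suppressMessages(gen_rehydration_curve(sp)),
                   suppressMessages(gen_rehydration_curve(sp)))
  dsp <- decay_spec(noise_sd = 1, seed = 42, n_echoes = 200)
  expect_identical(gen_cpmg_decay(dsp), gen_cpmg_decay(dsp))
  expect_identical(gen_pore_radii(138.21, 9.14, 50, seed = 9),
                   gen_pore_radii(138.21, 9.14, 50, seed = 9))
  # and the generators do not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_pore_radii(138.21, 9.14, 10, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("additive noise has the configured standard deviation", {
  # Monte-Carlo check: sample SD across replicate curves at one time point
  vals <- vapply(1:1000, function(s) {
    sp <- curve_spec("weibull", list(a = 20, beta = 0.8), M0 = 0, Me = 6.5,
                     times = c(0, 30), noise_sd = 0.05, seed = s)
    suppressMessages(gen_rehydration_curve(sp))$moisture_g_per_g[2]
  }, numeric(1))
  expect_lt(abs(sd(vals) / 0.05 - 1), 0.10)
})

test_that("curve generator clips negative draws and logs the count", {
  sp <- curve_spec("first_order", list(k = 0.05), M0 = 0, Me = 0.01,
                   times = c(0, 1, 2, 3, 4), noise_sd = 0.5, seed = 3)
  expect_message(cv <- gen_rehydration_curve(sp), "clipped")
  expect_true(all(cv$moisture_g_per_g >= 0))
  expect_gt(attr(cv, "clipped"), 0)
})

test_that("unknown kinetic model is rejected with a named error", {
  expect_error(curve_spec("biexponential", list(k = 1)), "biexponential")
})

test_that("CPMG generator produces the stated multi-exponential decay", {
  d1 <- gen_cpmg_decay(decay_spec(populations = cbind(100, 1),
                                  echo_spacing = 1, n_echoes = 200,
                                  noise_sd = 0))
  expect_equal(d1$amplitude[100], exp(-1), tolerance = 1e-12)
  # tri-exponential patterned on the untreated gel: S just below sum(areas)
  d3 <- gen_cpmg_decay(decay_spec(noise_sd = 0))
  expect_equal(d3$amplitude[1],
               sum(c(2, 772, 66) * exp(-0.35 / c(2.25, 44.5, 333))),
               tolerance = 1e-12)
  expect_lt(abs(d3$amplitude[1] - 838) / 838, 0.01)
  # strictly decreasing when noise-free
  expect_true(all(diff(d3$amplitude) < 0))
  expect_error(decay_spec(populations = cbind(-1, 1)), "T2")
})

test_that("pore radius sampler matches the SEM statistics", {
  r <- gen_pore_radii(138.21, 9.14, n = 1e5, seed = 11)
  expect_length(r, 1e5)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) / 69.105 - 1), 0.01)
  expect_lt(abs(sd(r) / (9.14 / 2) - 1), 0.02)
  r3 <- gen_pore_radii(138.21, 9.14, n = 3, seed = 1)
  expect_length(r3, 3)
  expect_error(gen_pore_radii(138.21, 9.14, n = 0), "n")
})

test_that("generated data are finite and non-negative after clipping", {
  for (s in 1:5) {
    cv <- make_curve("weibull", noise_sd = 0.2, seed = s)
    expect_true(all(is.finite(cv$moisture_g_per_g)))
    expect_true(all(cv$moisture_g_per_g >= 0))
  }
})
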