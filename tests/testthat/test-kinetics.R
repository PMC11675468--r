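test_that("predict_moisture implements the three model forms", {
  mk_fit <- function(model, params, M0 = 0, Me = 6.5) {
    structure(list(model = model, params = params, M0 = M0, Me = Me,
                   converged = TRUE), class = "kinetic_fit")
  }
  fo <- mk_fit("first_order", list(k = 0.05))
  pe <- mk_fit("peleg", list(K1 = 3.3, K2 = 0.154))
  we <- mk_fit("weibull", list(a = 20, beta = 0.8))
  # t = 0 returns M0 for every model
  for (f in list(fo, pe, we)) expect_equal(predict_moisture(f, 0), f$M0)
  # Peleg asymptote M0 + 1/K2
  expect_equal(predict_moisture(pe, 1e9), 1 / 0.154, tolerance = 1e-6)
  # Weibull at t = a completes 1 - exp(-1) of the change, for any beta
  for (beta in c(0.3, 0.8, 1, 2.5)) {
    w <- mk_fit("weibull", list(a = 20, beta = beta))
    frac <- (predict_moisture(w, 20) - w$M0) / (w$Me - w$M0)
    expect_equal(frac, 1 - exp(-1), tolerance = 1e-12)
  }
  expect_error(predict_moisture(we, -1), ">= 0")
  nc <- mk_fit("weibull", list(a = 20, beta = 0.8))
  nc$converged <- FALSE
  expect_error(predict_moisture(nc, 1), "converge")
})

test_that("goodness_of_fit matches hand-computed SSE and R^2", {
  g <- goodness_of_fit(c(1, 2, 3), c(1, 2, 3))
  expect_equal(g$r_squared, 1)
  expect_equal(g$sse, 0)
  obs <- c(1, 2, 3, 6)
  g0 <- goodness_of_fit(obs, rep(mean(obs), 4))
  expect_equal(g0$r_squared, 0)
  g1 <- goodness_of_fit(c(1, 2, 3), c(1, 2, 4))
  expect_equal(g1$sse, 1)
  expect_equal(g1$r_squared, 0.5)
  expect_error(goodness_of_fit(c(2, 2, 2), c(1, 2, 3)), "constant")
})

test_that("noise-free generate-and-refit recovers parameters to 1e-6", {
  for (model in names(std_params)) {
    cv <- make_curve(model)
    fit <- fit_kinetics(cv, model)
    expect_true(fit$converged, info = model)
    truth <- unlist(std_params[[model]])
    est <- unlist(fit$params[names(std_params[[model]])])
    expect_lt(max(abs(est - truth) / truth), 1e-6)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_lt(fit$sse, 1e-12)
    if (model != "peleg") expect_equal(fit$Me, 6.5, tolerance = 1e-6)
  }
})

test_that("Weibull with beta = 1 coincides with first-order k = 1/a", {
  cv <- make_curve("weibull", params = list(a = 25, beta = 1))
  fw <- fit_kinetics(cv, "weibull")
  ff <- fit_kinetics(cv, "first_order")
  expect_equal(ff$params$k, 1 / fw$params$a, tolerance = 1e-6)
  expect_lt(abs(fw$sse - ff$sse), 1e-10)
})

test_that("fitted monotone models predict monotone uptake when Me > M0", {
  tgrid <- seq(0, 180, by = 1)
  for (model in c("first_order", "weibull")) {
    fit <- fit_kinetics(make_curve(model), model)
    pred <- predict_moisture(fit, tgrid)
    expect_true(all(diff(pred) >= -1e-12), info = model)
  }
})

test_that("Peleg cannot represent sigmoidal uptake", {
  cv <- make_curve("weibull", params = list(a = 30, beta = 2.5))
  fp <- fit_kinetics(cv, "peleg")
  fw <- fit_kinetics(cv, "weibull")
  expect_true(!fp$converged || fp$r_squared < fw$r_squared)
})

test_that("noisy replicates give small median parameter bias", {
  est <- vapply(1:100, function(s) {
    fit <- fit_kinetics(make_curve("weibull", noise_sd = 0.05, seed = s),
                        "weibull")
    c(fit$params$a, fit$params$beta)
  }, numeric(2))
  expect_lt(abs(median(est[1, ]) / 20 - 1), 0.05)
  expect_lt(abs(median(est[2, ]) / 0.8 - 1), 0.05)
})

test_that("fit rejects degenerate inputs", {
  cv <- rehydration_curve(c(0, 5, 10), c(0, 1, 2))
  expect_error(fit_kinetics(cv, "weibull"), "4 points")
  expect_error(fit_kinetics(make_curve("weibull"), "exponential"))
})

test_that("R^2 never exceeds 1 and noise cannot improve it in expectation", {
  fit <- fit_kinetics(make_curve("weibull"), "weibull")
  r2 <- vapply(1:50, function(s) {
    cv <- make_curve("weibull", noise_sd = 0.1, seed = s)
    goodness_of_fit(cv$moisture_g_per_g, fit$fitted)$r_squared
  }, numeric(1))
  expect_true(all(r2 <= 1))
  expect_lt(mean(r2), 1)
})
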