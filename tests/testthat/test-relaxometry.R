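test_that("single-exponential inversion localises the T2 peak", {
  d <- gen_cpmg_decay(decay_spec(populations = cbind(100, 1), noise_sd = 0))
  sp <- invert_cpmg(d, reg_lambda = 0)
  g <- sp$t2_ms
  step <- log(g[2]) - log(g[1])
  near <- abs(log(g) - log(100)) <= step * 1.00001
  expect_gte(sum(sp$weight[near]) / sum(sp$weight), 0.95)
})

test_that("zero decay inverts to the zero spectrum", {
  d <- cpmg_decay(1:100, rep(0, 100))
  sp <- invert_cpmg(d)
  expect_true(all(sp$weight == 0))
  expect_error(cpmg_decay(1:3, c(1, Inf, 0)), "finite")
})

test_that("tri-exponential inversion separates three modes with true areas", {
  d <- gen_cpmg_decay(decay_spec(noise_sd = 0))
  sp <- invert_cpmg(d, t2_grid = default_t2_grid(256), reg_lambda = 0)
  pops <- classify_water_populations(sp)
  expect_lt(abs(pops$bound$area / 2 - 1), 0.05)
  expect_lt(abs(pops$immobilized$area / 772 - 1), 0.05)
  expect_lt(abs(pops$free$area / 66 - 1), 0.05)
})

test_that("inversion residual is non-increasing as reg_lambda decreases", {
  d <- gen_cpmg_decay(decay_spec(noise_sd = 0, n_echoes = 1000))
  lams <- c(10, 1, 0.1, 0.01, 0)
  res <- vapply(lams, function(l) {
    attr(invert_cpmg(d, reg_lambda = l), "residual_norm")
  }, numeric(1))
  expect_true(all(diff(res) <= 1e-8))
})

test_that("classification windows assign single modes correctly", {
  g <- default_t2_grid()
  put <- function(t2) {
    w <- rep(0, length(g)); w[which.min(abs(g - t2))] <- 1
    classify_water_populations(t2_spectrum(g, w))
  }
  p1 <- put(2.25)
  expect_equal(p1$bound$area, 1)
  expect_equal(p1$immobilized$area + p1$free$area, 0)
  p2 <- put(44.49)   # T22 of the untreated gel
  expect_equal(p2$immobilized$area, 1)
  p3 <- put(333.13)  # T23 of the untreated gel
  expect_equal(p3$free$area, 1)
  expect_lt(abs(p3$free$peak_T2 - 333.13), 20)
})

test_that("classified areas plus unclassified remainder conserve total mass", {
  set.seed(5)
  for (rep in 1:5) {
    g <- default_t2_grid()
    w <- runif(length(g))  # mass everywhere, incl. outside all windows
    pops <- classify_water_populations(t2_spectrum(g, w))
    tot <- pops$bound$area + pops$immobilized$area + pops$free$area +
      pops$unclassified
    expect_equal(tot, sum(w), tolerance = 1e-12)
    expect_gt(pops$unclassified, 0)
  }
})

test_that("round trip at SNR 500 recovers the resolvable populations", {
  S0 <- sum(c(2, 772, 66))
  d <- gen_cpmg_decay(decay_spec(noise_sd = 0.002 * S0, seed = 1))
  pops <- classify_water_populations(
    invert_cpmg(d, t2_grid = default_t2_grid(256), reg_lambda = 0.01))
  # populations above the acquisition noise floor: 5% relative
  expect_lt(abs(pops$immobilized$area / 772 - 1), 0.05)
  expect_lt(abs(pops$free$area / 66 - 1), 0.05)
  # the bound population (0.24% of total signal) is below the noise floor;
  # its area fraction is still recovered within 5 percentage points
  expect_lt(abs(pops$bound$area / pops$total - 2 / S0), 0.05)
})

test_that("select_reg_lambda picks a weight in the flat-residual region", {
  d <- gen_cpmg_decay(decay_spec(noise_sd = 0.002 * 840, seed = 3,
                                 n_echoes = 1000))
  lam <- select_reg_lambda(d, lambdas = 10^seq(-3, 2, length.out = 11))
  expect_gt(lam, 1e-3)
  expect_lt(lam, 100)
  r_sel <- attr(invert_cpmg(d, reg_lambda = lam), "residual_norm")
  r_min <- attr(invert_cpmg(d, reg_lambda = 1e-3), "residual_norm")
  expect_lt(r_sel / r_min - 1, 0.021)
})
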