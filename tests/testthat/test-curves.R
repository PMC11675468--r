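test_that("rehydration ratio computes (Wt - W0)/W0 and rejects bad masses", {
  expect_equal(rehydration_ratio(2, 2), 0)
  expect_equal(rehydration_ratio(2, 6), 2.0)
  # the maximum uptake reported for ultrasound-treated SPI/KGM gel
  expect_equal(rehydration_ratio(1, 7.52), 6.52)
  expect_error(rehydration_ratio(0, 1), "W0")
  expect_error(rehydration_ratio(-1, 1), "W0")
})

test_that("water-holding capacity is the retained mass percentage", {
  expect_equal(water_holding_capacity(10, 10), 100)
  expect_equal(water_holding_capacity(10, 7.048), 70.48)
  expect_equal(water_holding_capacity(8, 4), 50)
  expect_error(water_holding_capacity(5, 6), "cannot add mass")
})

test_that("rehydration_curve validates its invariants", {
  cv <- rehydration_curve(c(0, 5, 10), c(0, 1, 2))
  expect_s3_class(cv, "rehydration_curve")
  expect_error(rehydration_curve(c(5, 5, 10), c(0, 1, 2)), "increasing")
  expect_error(rehydration_curve(c(-1, 5), c(0, 1)), ">= 0")
  expect_error(rehydration_curve(c(0, 5), c(0, -1)), "non-negative")
  expect_error(rehydration_curve(c(0, 5), c(0, NA)), "NA")
  expect_error(rehydration_curve(c(0, 5), 1), "equal length")
})
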