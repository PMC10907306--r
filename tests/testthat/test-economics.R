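test_that("production value increase is the four-factor product", {
  expect_equal(production_value_increase(crop_scenario(1, 1, 1, 1)), 1)
  expect_equal(production_value_increase(crop_scenario(74e6, 173.3, 0, 6.44)), 0)
  maize <- corn_belt_maize()
  v <- production_value_increase(maize)
  expect_equal(v, 74e6 * 173.3 * 0.12 * 6.44)
  expect_gt(v, 7e9)
  expect_lt(v, 11e9)

  # exact linearity in every factor
  double_area <- crop_scenario(2 * 74e6, 173.3, 0.12, 6.44)
  expect_equal(production_value_increase(double_area), 2 * v)
  double_price <- crop_scenario(74e6, 173.3, 0.12, 2 * 6.44)
  expect_equal(production_value_increase(double_price), 2 * v)

  expect_error(crop_scenario(-1, 173.3, 0.12, 6.44), "non-negative")
})

test_that("price band sweep rescales the point value monotonically", {
  maize <- corn_belt_maize()
  v <- production_value_increase(maize)
  flat <- price_band_sweep(maize, 0, 0)
  expect_equal(unname(flat), c(v, v))

  band <- price_band_sweep(maize, -0.03, 0.26)
  expect_equal(unname(band), c(v * 0.97, v * 1.26))
  expect_lt(band[["low"]], band[["high"]])

  soy <- corn_belt_soybean()
  expect_equal(production_value_increase(soy), 74e6 * 49.5 * 0.16 * 15.12)
  expect_error(price_band_sweep(maize, 0.3, 0.1), "must not exceed")
})
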