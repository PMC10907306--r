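test_that("nutrient pools follow the concentration x biomass arithmetic", {
  expect_equal(nutrient_pool(0, 12000), 0)
  expect_equal(nutrient_pool(1000, 10000), 10)
  expect_equal(nutrient_pool(2500, 8000), 20)

  pools <- c(root = 3, stem = 12, leaf = 8, grain = 40)
  expect_equal(vegetative_pool(pools), 23)
  expect_equal(total_pool(pools), 63)
  # total is exactly the sum of the per-tissue pools
  expect_equal(total_pool(pools), sum(pools))
})

test_that("N mineralization rate converts soil N decline to kg/ha/yr, signed", {
  expect_equal(n_mineralization_rate(0.20, 0.20, 3600, 4), 0)
  # 0.01 percentage points of 3,600 t soil is 0.36 t N over 4 y = 90 kg/ha/yr
  expect_equal(n_mineralization_rate(0.20, 0.19, 3600, 4), 90)
  expect_equal(n_mineralization_rate(0.19, 0.20, 3600, 4), -90)
  expect_error(n_mineralization_rate(0.2, 0.19, 3600, 0))
})

test_that("NUE follows (grain N - mineralized N) / fertilizer N", {
  expect_equal(nue(19, 19, 202), 0)
  expect_equal(nue(120, 19, 202), 50)
  expect_equal(nue(221, 19, 202), 100)
  expect_error(nue(120, 19, 0), "undefined")
  # invariant under simultaneous scaling of all three terms
  expect_equal(nue(120 * 3, 19 * 3, 202 * 3), nue(120, 19, 202))
})

test_that("element release from immobile-ratio depletion is linear in f and rate", {
  expect_equal(as.numeric(element_release_from_ratio(0.3, 0.3, 700, 50)), 0)
  r <- element_release_from_ratio(0.30, 0.24, 700, 50)
  expect_equal(as.numeric(r), 7)
  expect_equal(attr(r, "loss_fraction"), 0.2)
  expect_true(attr(r, "lower_bound"))
  expect_equal(as.numeric(element_release_from_ratio(0.30, 0.15, 700, 50)), 17.5)
  # f = 1 releases the entire applied element mass (700 mg/kg x 50 t = 35 kg)
  expect_equal(as.numeric(element_release_from_ratio(0.30, 0, 700, 50)), 35)
  # linear in application rate
  expect_equal(as.numeric(element_release_from_ratio(0.30, 0.24, 700, 100)), 14)
  gain <- element_release_from_ratio(0.30, 0.36, 700, 50)
  expect_true(attr(gain, "apparent_gain"))
  expect_lt(as.numeric(gain), 0)
  expect_error(element_release_from_ratio(0, 0.2, 700, 50), "ratio_fresh")
})

test_that("grain export fraction reports the treated-control pool difference", {
  expect_equal(grain_export_fraction(10, 10, 100), 0)
  expect_equal(grain_export_fraction(10.3, 10.0, 100), 0.3)
  expect_equal(grain_export_fraction(12, 10, 100), 2)
  expect_equal(grain_export_fraction(9, 10, 100), -1)  # signed
  expect_error(grain_export_fraction(10.3, 10, 0), "must be > 0")
})
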