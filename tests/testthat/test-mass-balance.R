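test_that("basalt fraction recovers the mixing ratio and flags out-of-range", {
  expect_equal(as.numeric(basalt_fraction(3417, 2693, 10899)),
               (3417 - 2693) / (10899 - 2693))
  expect_equal(as.numeric(basalt_fraction(2693, 2693, 10899)), 0)
  expect_equal(as.numeric(basalt_fraction(10899, 2693, 10899)), 1)

  under <- basalt_fraction(2500, 2693, 10899)
  expect_true(attr(under, "out_of_range"))
  expect_lt(as.numeric(under), 0)  # signed, not clamped

  expect_error(basalt_fraction(3000, 2693, 2693), "degenerate tracer contrast")
  expect_error(basalt_fraction(3000, 2693, 2800,
                               min_contrast = tracer_contrast_floor(196)),
               "degenerate tracer contrast")
})

test_that("mixing round-trip is an identity for any p in [0, 1]", {
  set.seed(11)
  for (i in 1:50) {
    p <- runif(1)
    ti_s <- runif(1, 500, 5000)
    ti_b <- runif(1, 6000, 20000)
    mix <- expected_cation(ti_b, ti_s, p)
    expect_equal(as.numeric(basalt_fraction(mix, ti_s, ti_b)), p,
                 tolerance = 1e-12)
  }
})

test_that("soil and basalt mass follow the layer geometry", {
  expect_equal(soil_mass(soil_layer_geometry(0.1, 10000, 1.2)), 1200)
  expect_equal(soil_mass(soil_layer_geometry(0.2, 10000, 1.2)), 2400)
  # per-hectare basis is independent of the sampled area
  expect_equal(soil_mass(soil_layer_geometry(0.1, 100, 1.2)), 1200)
  expect_error(soil_layer_geometry(0.1, 10000, 0), "strictly positive")

  expect_equal(basalt_mass(1200, 0), 0)
  expect_equal(basalt_mass(1200, 0.5), 1200)
  expect_equal(basalt_mass(1200, 0.0881), 1200 * 0.0881 / 0.9119)
  expect_error(basalt_mass(1200, 1), "p_basalt must be < 1")
})

test_that("depth partition splits applied mass and flags over-recovery", {
  part <- depth_partition(116, 200)
  expect_equal(c(part[["in_layer"]], part[["below"]]), c(0.58, 0.42))
  expect_false(attr(part, "over_recovered"))
  full <- depth_partition(200, 200)
  expect_equal(c(full[["in_layer"]], full[["below"]]), c(1, 0))
  none <- depth_partition(0, 200)
  expect_equal(c(none[["in_layer"]], none[["below"]]), c(0, 1))
  expect_warning(over <- depth_partition(230, 200), "over-recovery")
  expect_gt(over[["in_layer"]], 1)
  expect_warning(capped <- depth_partition(230, 200, cap = TRUE))
  expect_equal(capped[["in_layer"]], 1)
})

test_that("expected cation interpolates between the endmembers", {
  expect_equal(expected_cation(70000, 5000, 0), 5000)
  expect_equal(expected_cation(70000, 5000, 1), 70000)
  expect_equal(expected_cation(70000, 5000, 0.1), 11500)
  set.seed(12)
  p <- runif(200)
  cb <- runif(200, 0, 1e5)
  cs <- runif(200, 0, 1e4)
  v <- expected_cation(cb, cs, p)
  expect_true(all(v >= pmin(cb, cs) - 1e-9 & v <= pmax(cb, cs) + 1e-9))
})

test_that("weathered concentration and proportion are signed, never clamped", {
  expect_equal(as.numeric(weathered_cation(11500, 11500)), 0)
  expect_equal(as.numeric(weathered_cation(11500, 10000)), 1500)
  gain <- weathered_cation(11500, 12000)
  expect_equal(as.numeric(gain), -500)
  expect_true(attr(gain, "apparent_gain"))

  expect_equal(weathered_proportion(0, 70000, 0.1), 0)
  expect_equal(weathered_proportion(2240, 70000, 0.1), 0.32)
  expect_equal(weathered_proportion(7000, 70000, 0.1), 1)
  expect_error(weathered_proportion(100, 70000, 0), "zero basalt-derived")
})

test_that("CDR potential is linear and matches a mole-counting oracle", {
  fs <- rock_feedstock(c(Ca = 0.040078, Mg = 0, Ti = 0.011))
  expect_equal(cdr_potential(0, 0, fs, 50), 0)
  expect_equal(cdr_potential(1, 0, fs, 100), 8.8018, tolerance = 1e-6)
  expect_equal(theoretical_max_cdr(fs, 100), cdr_potential(1, 0, fs, 100))

  # independent oracle: explicit unit-by-unit mole counting, no shared code
  oracle <- function(p_ca, p_mg, ca_mg_kg, mg_mg_kg, m_t_ha) {
    rock_g <- m_t_ha * 1e6
    mol_ca <- rock_g * (ca_mg_kg / 1e6) * p_ca / 40.078
    mol_mg <- rock_g * (mg_mg_kg / 1e6) * p_mg / 24.305
    2 * (mol_ca + mol_mg) * 44.009 / 1e6
  }
  set.seed(13)
  for (i in 1:1000) {
    p_ca <- runif(1); p_mg <- runif(1)
    ca <- runif(1, 1e3, 2e5); mg <- runif(1, 1e3, 2e5)
    m <- runif(1, 1, 500)
    f <- rock_feedstock(c(Ca = ca / 1e6, Mg = mg / 1e6, Ti = 0.01))
    got <- cdr_potential(p_ca, p_mg, f, m)
    expect_equal(got, oracle(p_ca, p_mg, ca, mg, m), tolerance = 1e-12)
  }

  # exact linearity in applied mass and in each proportion
  f <- synthetic_feedstock()
  expect_equal(cdr_potential(0.3, 0.1, f, 100), 2 * cdr_potential(0.3, 0.1, f, 50))
  expect_equal(cdr_potential(0.6, 0, f, 50), 2 * cdr_potential(0.3, 0, f, 50))
  expect_equal(cdr_potential(0.3, 0.1, f, 50),
               cdr_potential(0.3, 0, f, 50) + cdr_potential(0, 0.1, f, 50))

  # stoichiometric conservation: t CO2 / M_CO2 = 2 x (mol Ca + mol Mg)
  cdr <- cdr_potential(0.32, 0.12, f, 200)
  mol_cations <- 0.32 * f$element_mass_fraction[["Ca"]] * 200 / 40.078 +
    0.12 * f$element_mass_fraction[["Mg"]] * 200 / 24.305
  expect_equal(cdr / 44.009, 2 * mol_cations, tolerance = 1e-14)

  expect_warning(cdr_potential(1.2, 0.1, f, 50), "outside \\[0, 1\\]")
  no_mg <- rock_feedstock(c(Ca = 0.04, Mg = 0, Ti = 0.01))
  no_mg$element_mass_fraction <- no_mg$element_mass_fraction[c("Ca", "Ti")]
  expect_error(cdr_potential(1, 1, no_mg, 50), "Ca and Mg")
})

test_that("cumulative CDR series accumulates additively", {
  sched <- c(`2017` = 50, `2018` = 50, `2019` = 50, `2020` = 50)
  empty <- cumulative_cdr_series(data.frame(year = integer(), cdr_pot = numeric()),
                                 sched)
  expect_equal(nrow(empty), 0)

  one <- cumulative_cdr_series(data.frame(year = 2017, cdr_pot = 3.8), sched)
  expect_equal(one$cum_cdr_pot, 3.8)

  four <- cumulative_cdr_series(
    data.frame(year = 2017:2020, cdr_pot = rep(2.625, 4), sd = rep(0.5, 4)),
    sched)
  expect_equal(four$cum_cdr_pot, cumsum(rep(2.625, 4)))
  expect_equal(four$cum_cdr_pot[4], 10.5)
  expect_equal(four$cum_sd, sqrt(cumsum(rep(0.25, 4))))
  expect_equal(four$cum_applied_t_ha, c(50, 100, 150, 200))
  # monotone non-decreasing under non-negative increments
  expect_true(all(diff(four$cum_cdr_pot) >= 0))

  expect_error(cumulative_cdr_series(data.frame(year = 2021, cdr_pot = 1), sched),
               "missing year")
})
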