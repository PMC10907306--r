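test_that("trial config validates its inputs", {
  expect_s3_class(trial_config(), "trial_config")
  expect_error(trial_config(true_loss_fraction = list(Ca = c(`2020` = 1.2),
                                                      Mg = c(`2020` = 0.1))),
               "loss fractions")
  expect_error(trial_config(application_t_ha = c(`2016` = -5)),
               "non-negative")
  expect_error(trial_config(soil_baseline = c(Ca = 5000, Mg = 3000)),
               "tracer Ti")
})

test_that("simulation is byte-identical under the same seed", {
  cfg <- trial_config(seed = 7)
  s1 <- simulate_trial(cfg)
  s2 <- simulate_trial(cfg)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$feedstock_measured, s2$feedstock_measured)
  s3 <- simulate_trial(trial_config(seed = 8))
  expect_false(identical(s1$samples, s3$samples))
})

test_that("zero-noise forward-inverse identity holds exactly", {
  cfg <- zero_noise_config()
  sim <- simulate_trial(cfg)
  # treated Ti is exactly the mixing value
  t2020 <- sim$samples[sim$samples$treatment == "basalt" &
                         sim$samples$year == 2020, ]
  expect_equal(unique(round(t2020$Ti, 9)),
               round(sim$truth$ti_treated[sim$truth$year == 2020], 9))

  fit <- estimate_weathering(sim$samples, sim$feedstock_measured,
                             schedule = cfg$application_t_ha,
                             uncertainty = "sem")
  truth <- sim$truth
  for (y in as.character(2017:2020)) {
    r <- fit$results[[y]]
    i <- match(as.integer(y), truth$year)
    expect_equal(r$p_basalt$value, truth$p_basalt[i], tolerance = 1e-10)
    expect_equal(r$cations$proportion[r$cations$element == "Ca"],
                 truth$loss_Ca[i], tolerance = 1e-9)
    expect_equal(r$cations$proportion[r$cations$element == "Mg"],
                 truth$loss_Mg[i], tolerance = 1e-9)
    expect_equal(r$cdr_pot_t_co2_ha$value, truth$cdr_pot[i], tolerance = 1e-9)
  }
  # per-sample aggregation agrees at zero noise (no spread to differ under)
  fit_ps <- estimate_weathering(sim$samples, sim$feedstock_measured,
                                schedule = cfg$application_t_ha,
                                years = 2020, aggregation = "per_sample")
  expect_equal(fit_ps$results[["2020"]]$p_basalt$value,
               truth$p_basalt[truth$year == 2020], tolerance = 1e-10)
})

test_that("study-like configuration recovers p_basalt near the study scale", {
  sim <- simulate_trial(trial_config(seed = 123))
  fit <- estimate_weathering(sim$samples, sim$feedstock_measured,
                             schedule = trial_config()$application_t_ha,
                             years = 2020)
  p <- fit$results[["2020"]]$p_basalt
  expect_equal(p$value, 0.088, tolerance = 0.35)  # within noise of the truth
  expect_equal(sim$truth$p_basalt[sim$truth$year == 2020], 0.0881,
               tolerance = 1e-3)
})

test_that("truth CDR series rises to the configured endpoint", {
  truth <- simulate_trial(trial_config())$truth
  expect_true(all(diff(truth$cdr_pot) >= 0))
  expect_equal(truth$cdr_pot[truth$year == 2017], 3.8, tolerance = 0.01)
  expect_equal(truth$cdr_pot[truth$year == 2020], 10.5, tolerance = 0.01)
})

test_that("doubling analytical noise doubles the spread of p_basalt estimates", {
  est_sd <- function(cv_scale, n_rep = 120) {
    cfg <- trial_config(analytical_cv = cv_scale * c(Ti = 0.066, Ca = 0.06,
                                                     Mg = 0.06),
                        block_sd_rel = 0, seed = 500)
    est <- numeric(n_rep)
    for (r in seq_len(n_rep)) {
      cfg_r <- cfg; cfg_r$seed <- cfg$seed + r
      sim <- simulate_trial(cfg_r)
      fit <- estimate_weathering(sim$samples, sim$feedstock_measured,
                                 schedule = cfg$application_t_ha,
                                 years = 2020, uncertainty = "sem")
      est[r] <- fit$results[["2020"]]$p_basalt$value
    }
    sd(est)
  }
  s1 <- est_sd(1)
  s2 <- est_sd(2)
  expect_equal(s2 / s1, 2, tolerance = 0.3)
})

test_that("recovery study is unbiased with calibrated interval coverage", {
  rec <- recovery_study(trial_config(seed = 2024), n_replicates = 500)
  expect_setequal(rec$parameter, c("p_basalt", "loss_Ca", "loss_Mg"))
  loss <- rec[grepl("^loss_", rec$parameter), ]
  expect_true(all(abs(loss$bias) < 0.02))
  expect_true(all(rec$coverage_95 >= 0.90 & rec$coverage_95 <= 0.98))
  # reported SDs track the empirical spread of the estimates
  expect_equal(rec$mean_reported_sd, rec$empirical_sd, tolerance = 0.25)
})
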