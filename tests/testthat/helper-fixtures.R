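# n values with exactly the requested mean and SD (for fixtures whose sample
# moments must reproduce published summary statistics)
values_with_moments <- function(n, mean, sd) {
  v <- seq_len(n)
  z <- (v - base::mean(v)) / stats::sd(v)
  mean + sd * z
}

# a noise-free trial configuration: exact mixing, no block structure, no
# feedstock measurement error
zero_noise_config <- function(...) {
  cfg <- trial_config(analytical_cv = c(Ti = 0, Ca = 0, Mg = 0),
                      block_sd_rel = 0,
                      feedstock = synthetic_feedstock(ti_sd_mg_kg = 0),
                      ...)
  cfg$feedstock$sd <- NULL
  cfg
}

# sample table whose year means reproduce the reference trial's Ti summary
# statistics exactly, with cation concentrations from the forward model
study_mean_samples <- function(n_base = 19, n_treated = 19,
                               loss = c(Ca = 0.32, Mg = 0.12)) {
  fs <- synthetic_feedstock()
  conc <- fs$element_mass_fraction * 1e6
  p <- basalt_fraction(3417, 2693, 10899)
  base_conc <- c(Ti = 2693, Ca = 5000, Mg = 3000)
  base_sd <- c(Ti = 196, Ca = 300, Mg = 180)
  mk <- function(n, year, treatment, el_means, el_sds) {
    out <- data.frame(block = rep(paste0("B", 1:4), length.out = n),
                      plot = "P", treatment = treatment, year = year,
                      depth = "0-10cm")
    for (e in names(el_means))
      out[[e]] <- values_with_moments(n, el_means[[e]], el_sds[[e]])
    out
  }
  treated_means <- c(Ti = 3417,
                     Ca = unname(expected_cation(conc[["Ca"]], base_conc[["Ca"]], p) -
                                   loss[["Ca"]] * conc[["Ca"]] * p),
                     Mg = unname(expected_cation(conc[["Mg"]], base_conc[["Mg"]], p) -
                                   loss[["Mg"]] * conc[["Mg"]] * p))
  treated_sds <- c(Ti = 279, Ca = 350, Mg = 250)
  rbind(mk(n_base, 2016, "control", base_conc, base_sd),
        mk(n_treated, 2020, "basalt", treated_means, treated_sds))
}

study_feedstock <- function() synthetic_feedstock(ti_sd_mg_kg = 420)

study_schedule <- c(`2016` = 50, `2017` = 50, `2018` = 50, `2019` = 50)
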