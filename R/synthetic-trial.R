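#' Configuration of a synthetic enhanced-weathering field trial
#'
#' Defines the truth of a simulated randomized-block trial: design (blocks,
#' years, application schedule), feedstock and baseline soil chemistry, the
#' imposed per-cation cumulative dissolution fractions, and the noise model.
#' Defaults emulate the reference trial conditions: four 0.7-ha blocks plus one large
#' plot (effective n = 5), a 2016 pretreatment baseline, 50 t/ha of rock
#' applied each autumn 2016-2019 (so cumulative loads of 50-200 t/ha at the
#' 2017-2020 samplings), baseline soil Ti of 2,693 mg/kg with a total
#' between-sample spread near the observed 196 mg/kg, feedstock Ti of
#' 10,899 mg/kg, 58% of the applied rock residing in the sampled 0-10 cm
#' layer, and endpoint cumulative loss fractions of 0.32 (Ca) and 0.12 (Mg).
#'
#' @param n_blocks Number of small blocks.
#' @param include_large_plot Add a large plot sampled like a block
#'   (effective replication n_blocks + 1)?
#' @param years Trial years; the first is the pretreatment baseline year.
#' @param application_t_ha Named numeric, rock applied (t/ha) keyed by year of
#'   (autumn) application; a year's sampling sees all applications of earlier
#'   years.
#' @param feedstock A [rock_feedstock()].
#' @param soil_baseline Named numeric, baseline soil concentrations (mg/kg)
#'   for every simulated element; must include Ti and the cations.
#' @param true_loss_fraction List keyed by cation of named numerics: the true
#'   cumulative fraction of the basalt-derived cation pool lost by each
#'   sampling year. Fractions must lie in [0, 1].
#' @param layer_fraction Fraction of the applied rock residing in the sampled
#'   layer (the rest is below sampling depth).
#' @param geometry [soil_layer_geometry()] of the sampled layer.
#' @param analytical_cv Named numeric, relative analytical SD per element.
#' @param block_sd_rel Relative SD of the additive per-block shift on baseline
#'   concentrations (spatial heterogeneity), drawn once per block per element.
#' @param samples_per_plot Soil samples per treatment plot per year.
#' @param noise_model "lognormal" (multiplicative, mean-corrected; default —
#'   concentrations are positive and right-skewed) or "normal".
#' @param seed Integer; fixes all randomness of [simulate_trial()].
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(n_blocks = 4,
                         include_large_plot = TRUE,
                         years = 2016:2020,
                         application_t_ha = c(`2016` = 50, `2017` = 50,
                                              `2018` = 50, `2019` = 50),
                         feedstock = synthetic_feedstock(),
                         soil_baseline = c(Ti = 2693, Ca = 5000, Mg = 3000),
                         true_loss_fraction = list(
                           Ca = c(`2017` = 0.55, `2018` = 0.42,
                                  `2019` = 0.37, `2020` = 0.32),
                           Mg = c(`2017` = 0.15, `2018` = 0.135,
                                  `2019` = 0.125, `2020` = 0.12)),
                         layer_fraction = 0.58,
                         geometry = soil_layer_geometry(0.1, 10000, 1.2),
                         analytical_cv = c(Ti = 0.066, Ca = 0.06, Mg = 0.06),
                         block_sd_rel = 0.03,
                         samples_per_plot = 4,
                         noise_model = c("lognormal", "normal"),
                         seed = 42L) {
  noise_model <- match.arg(noise_model)
  stopifnot(inherits(feedstock, "rock_feedstock"),
            inherits(geometry, "soil_layer_geometry"),
            n_blocks >= 1, samples_per_plot >= 1,
            layer_fraction > 0, layer_fraction <= 1,
            block_sd_rel >= 0)
  if (any(application_t_ha < 0))
    stop("application rates must be non-negative", call. = FALSE)
  fr <- unlist(true_loss_fraction)
  if (any(fr < 0) || any(fr > 1))
    stop("true loss fractions must lie in [0, 1]", call. = FALSE)
  elements <- names(soil_baseline)
  if (!"Ti" %in% elements)
    stop("soil_baseline must include the tracer Ti", call. = FALSE)
  cations <- names(true_loss_fraction)
  if (!all(cations %in% elements))
    stop("every cation with a loss fraction needs a soil baseline", call. = FALSE)
  if (!all(elements %in% names(feedstock$element_mass_fraction)))
    stop("feedstock must record every simulated element", call. = FALSE)
  if (!all(elements %in% names(analytical_cv)))
    stop("analytical_cv must cover every simulated element", call. = FALSE)
  structure(list(n_blocks = n_blocks,
                 include_large_plot = include_large_plot,
                 years = sort(years),
                 application_t_ha = application_t_ha,
                 feedstock = feedstock,
                 soil_baseline = soil_baseline,
                 true_loss_fraction = true_loss_fraction,
                 layer_fraction = layer_fraction,
                 geometry = geometry,
                 analytical_cv = analytical_cv,
                 block_sd_rel = block_sd_rel,
                 samples_per_plot = samples_per_plot,
                 noise_model = noise_model,
                 seed = as.integer(seed)),
            class = "trial_config")
}

# cumulative rock applied before the (summer) sampling of each year
cumulative_applied <- function(config) {
  sapply(config$years, function(y) {
    prior <- as.integer(names(config$application_t_ha)) < y
    sum(config$application_t_ha[prior])
  }, USE.NAMES = FALSE)
}

# noise-free truth of the forward model, per year
trial_truth <- function(config) {
  m_soil <- soil_mass(config$geometry)
  cum <- cumulative_applied(config)
  m_layer <- config$layer_fraction * cum
  p <- m_layer / (m_soil + m_layer)
  fs <- config$feedstock$element_mass_fraction * 1e6  # mg/kg
  cations <- names(config$true_loss_fraction)

  truth <- data.frame(year = config$years,
                      cum_applied_t_ha = cum,
                      m_basalt_layer_t_ha = m_layer,
                      p_basalt = p)
  truth$ti_treated <- expected_cation(fs[["Ti"]],
                                      config$soil_baseline[["Ti"]], p)
  loss_by_year <- function(ca) {
    f <- numeric(length(config$years))
    idx <- match(names(config$true_loss_fraction[[ca]]),
                 as.character(config$years))
    f[idx] <- config$true_loss_fraction[[ca]]
    f
  }
  for (ca in cations) {
    f <- loss_by_year(ca)
    expd <- expected_cation(fs[[ca]], config$soil_baseline[[ca]], p)
    truth[[paste0("loss_", ca)]] <- f
    truth[[paste0(ca, "_expected")]] <- expd
    truth[[paste0(ca, "_observed")]] <- expd - f * fs[[ca]] * p
  }
  # cumulative CDR under the equal-rate-below-layer assumption: the loss
  # fractions apply to the full cumulative applied mass
  f_ca <- if ("Ca" %in% cations) loss_by_year("Ca") else 0
  f_mg <- if ("Mg" %in% cations) loss_by_year("Mg") else 0
  truth$cdr_pot <- cdr_potential_num(f_ca, f_mg, fs[["Ca"]], fs[["Mg"]], cum)
  truth
}

#' Simulate a randomized-block enhanced-weathering trial
#'
#' Runs the mass-balance forward model in reverse: imposes the configured
#' cumulative basalt load and per-cation loss fractions, mixes tracer and
#' cation concentrations accordingly, adds per-block spatial shifts and
#' multiplicative analytical noise, and emits a per-sample table in the same
#' CSV dialect the estimation pipeline consumes, alongside the noise-free
#' truth. Fully reproducible from `config$seed`.
#'
#' @param config A [trial_config()].
#' @return List with components:
#'   * `samples`: data frame `block, plot, treatment, year, depth` plus one
#'     column per element (mg/kg);
#'   * `truth`: per-year noise-free truth (p_basalt, expected/observed
#'     concentrations, loss fractions, cumulative CDR potential);
#'   * `feedstock_measured`: a [rock_feedstock()] as "measured" in this
#'     replicate — the true composition perturbed by its recorded measurement
#'     SDs, which is what an analyst would have in hand.
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  truth <- trial_truth(config)
  elements <- names(config$soil_baseline)
  cations <- names(config$true_loss_fraction)
  fs <- config$feedstock$element_mass_fraction * 1e6
  blocks <- paste0("B", seq_len(config$n_blocks))
  if (config$include_large_plot) blocks <- c(blocks, "L")

  out <- withr_seed(config$seed, {
    block_shift <- vapply(elements, function(e)
      stats::rnorm(length(blocks), 0,
                   config$block_sd_rel * config$soil_baseline[[e]]),
      numeric(length(blocks)))
    rownames(block_shift) <- blocks

    grid <- expand.grid(sample = seq_len(config$samples_per_plot),
                        treatment = c("control", "basalt"),
                        block = blocks,
                        year = config$years,
                        stringsAsFactors = FALSE)
    yi <- match(grid$year, truth$year)
    p <- ifelse(grid$treatment == "basalt", truth$p_basalt[yi], 0)

    samples <- data.frame(block = grid$block,
                          plot = paste0(grid$block, "-",
                                        substr(grid$treatment, 1, 1)),
                          treatment = grid$treatment,
                          year = grid$year,
                          depth = "0-10cm",
                          stringsAsFactors = FALSE)
    for (e in elements) {
      base_e <- config$soil_baseline[[e]] + block_shift[grid$block, e]
      conc <- expected_cation(fs[[e]], base_e, p)
      if (e %in% cations) {
        f <- truth[[paste0("loss_", e)]][yi]
        conc <- conc - f * fs[[e]] * p
      }
      cv <- config$analytical_cv[[e]]
      conc <- if (config$noise_model == "lognormal") {
        sigma <- sqrt(log(1 + cv^2))
        conc * exp(stats::rnorm(nrow(grid), -sigma^2 / 2, sigma))
      } else {
        conc * (1 + stats::rnorm(nrow(grid), 0, cv))
      }
      samples[[e]] <- conc
    }

    fs_meas <- config$feedstock$element_mass_fraction
    if (!is.null(config$feedstock$sd)) {
      for (e in names(config$feedstock$sd))
        fs_meas[[e]] <- max(0, fs_meas[[e]] +
                              stats::rnorm(1, 0, config$feedstock$sd[[e]]))
    }
    list(samples = samples, fs_meas = fs_meas)
  })

  feedstock_measured <- rock_feedstock(out$fs_meas,
                                       name = paste0(config$feedstock$name,
                                                     " (measured)"),
                                       sd = config$feedstock$sd,
                                       p80_um = config$feedstock$p80_um)
  list(samples = out$samples, truth = truth,
       feedstock_measured = feedstock_measured)
}

#' Parameter-recovery study
#'
#' Repeatedly simulates a trial and runs the full estimation pipeline,
#' reporting bias of the point estimates and empirical coverage of the
#' propagated 95% intervals against the configured truth, for the basalt mass
#' fraction and the per-cation cumulative loss fractions in the final trial
#' year. Estimation uses SEM-basis uncertainty of sample means and the
#' correlated (plain delta-method) propagation, the statistically faithful
#' convention for interval coverage.
#'
#' @param config A [trial_config()]; replicate r uses seed `config$seed + r`.
#' @param n_replicates Number of simulated trials, at least 100 (zero-noise
#'   sanity checks aside).
#' @param year Analysis year; default the final trial year.
#' @return Data frame with one row per parameter: `parameter, truth,
#'   mean_estimate, bias, empirical_sd, mean_reported_sd, coverage_95,
#'   n_replicates`.
#' @export
recovery_study <- function(config, n_replicates = 500, year = NULL) {
  stopifnot(inherits(config, "trial_config"), n_replicates >= 1)
  if (is.null(year)) year <- max(config$years)
  truth <- trial_truth(config)
  ti <- match(year, truth$year)
  if (is.na(ti)) stop("year ", year, " is not a trial year", call. = FALSE)
  cations <- names(config$true_loss_fraction)
  params <- c("p_basalt", paste0("loss_", cations))
  true_vals <- vapply(params, function(pp) truth[[pp]][ti], numeric(1))

  est <- matrix(NA_real_, n_replicates, length(params),
                dimnames = list(NULL, params))
  sds <- est
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- config$seed + r
    sim <- simulate_trial(cfg)
    fit <- estimate_weathering(sim$samples, sim$feedstock_measured,
                               geometry = config$geometry,
                               schedule = config$application_t_ha,
                               cations = cations,
                               years = year,
                               uncertainty = "sem",
                               correlated_b = TRUE)
    res <- fit$results[[as.character(year)]]
    est[r, "p_basalt"] <- res$p_basalt$value
    sds[r, "p_basalt"] <- res$p_basalt$sd
    for (ca in cations) {
      est[r, paste0("loss_", ca)] <-
        res$cations$proportion[res$cations$element == ca]
      sds[r, paste0("loss_", ca)] <-
        res$cations$proportion_sd[res$cations$element == ca]
    }
  }
  z <- stats::qnorm(0.975)
  data.frame(parameter = params,
             truth = unname(true_vals),
             mean_estimate = colMeans(est),
             bias = colMeans(est) - true_vals,
             empirical_sd = apply(est, 2, stats::sd),
             mean_reported_sd = colMeans(sds),
             coverage_95 = vapply(params, function(pp)
               mean(abs(est[, pp] - true_vals[[pp]]) <= z * sds[, pp]),
               numeric(1)),
             n_replicates = n_replicates,
             row.names = NULL)
}
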