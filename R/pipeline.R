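# mean of a sample vector as a measured quantity, on SD or SEM basis
mean_mq <- function(x, basis = c("sd", "sem")) {
  basis <- match.arg(basis)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 finite values to form a mean with spread",
                  call. = FALSE)
  s <- stats::sd(x)
  mq(mean(x), if (basis == "sem") s / sqrt(n) else s, n)
}

#' Estimate basalt weathering and CDR potential from a soil sample table
#'
#' The full immobile-tracer accounting chain: basalt mass fraction from Ti
#' mixing, basalt mass in the sampled layer, partition of the applied rock
#' between the layer and below, expected/observed/weathered cation
#' concentrations, per-cation loss proportions, and the cumulative CDR
#' potential — each with first-order propagated uncertainty.
#'
#' Aggregation follows the mean-of-samples convention by default (means of
#' treated-year and baseline samples are plugged into the accounting
#' equations); `aggregation = "per_sample"` instead computes the chain per
#' treated sample and averages the estimates, which differs under the
#' nonlinearity of the basalt-mass equation.
#'
#' @param samples Sample table as returned by [read_sample_table()] or
#'   [simulate_trial()]: columns `block, plot, treatment, year, depth` plus
#'   one column per element in mg/kg.
#' @param feedstock A [rock_feedstock()] (with measurement SDs where known).
#' @param geometry [soil_layer_geometry()] of the sampled layer.
#' @param schedule Named numeric: rock applied (t/ha) by application year.
#'   A year's sampling sees all applications of strictly earlier years.
#' @param cations Cations to account; default Ca and Mg.
#' @param years Analysis years; default every sampled year with rock already
#'   applied.
#' @param baseline `"pretreatment"` (default): baseline concentrations are the
#'   mean of all samples of `baseline_year`, before any application;
#'   `"control"`: contemporaneous control-plot samples of each analysis year.
#' @param baseline_year Pretreatment year; default the earliest sampled year.
#' @param aggregation `"mean"` (default) or `"per_sample"`.
#' @param uncertainty Spread basis for sample means: `"sd"` (default; the
#'   between-sample spread, as reported alongside published mixing ratios) or
#'   `"sem"` (uncertainty of the mean, appropriate for interval coverage).
#' @param depth_below_factor Weathering rate of the below-layer rock relative
#'   to the sampled layer, in [0, 1]. 1 (default) is the equal-rate
#'   assumption; 0 credits no weathering below the sampled layer.
#' @param correlated_b Propagation convention for shared terms: FALSE
#'   (default) treats repeated occurrences of a mean as independent when
#'   chaining ("standard rules" convention); TRUE uses the plain delta method
#'   on the composed estimator (statistically faithful; used by
#'   [recovery_study()]).
#' @param min_contrast Tracer-contrast floor; default
#'   [tracer_contrast_floor()] of the baseline Ti between-sample SD.
#' @return An object of class `ew_fit`: `results` (named list of
#'   `weathering_result` by year), `series` (per-year cumulative CDR data
#'   frame), and the settings used. `as.data.frame()` flattens to one row per
#'   year and cation.
#' @export
estimate_weathering <- function(samples, feedstock,
                                geometry = soil_layer_geometry(0.1, 10000, 1.2),
                                schedule,
                                cations = c("Ca", "Mg"),
                                years = NULL,
                                baseline = c("pretreatment", "control"),
                                baseline_year = NULL,
                                aggregation = c("mean", "per_sample"),
                                uncertainty = c("sd", "sem"),
                                depth_below_factor = 1,
                                correlated_b = FALSE,
                                min_contrast = NULL) {
  baseline <- match.arg(baseline)
  aggregation <- match.arg(aggregation)
  uncertainty <- match.arg(uncertainty)
  stopifnot(is.data.frame(samples), inherits(feedstock, "rock_feedstock"),
            inherits(geometry, "soil_layer_geometry"),
            depth_below_factor >= 0, depth_below_factor <= 1)
  needed <- c("treatment", "year", "Ti", cations)
  if (!all(needed %in% names(samples)))
    stop("sample table lacks column(s): ",
         paste(setdiff(needed, names(samples)), collapse = ", "),
         call. = FALSE)
  if (is.null(baseline_year)) baseline_year <- min(samples$year)

  cum_before <- function(y)
    sum(schedule[as.integer(names(schedule)) < y])
  if (is.null(years)) {
    years <- sort(unique(samples$year[samples$treatment == "basalt"]))
    years <- years[vapply(years, cum_before, numeric(1)) > 0]
  }
  if (!length(years)) stop("no analysis years with rock applied", call. = FALSE)

  m_soil <- soil_mass(geometry)
  results <- list()
  for (y in years) {
    treated <- samples[samples$treatment == "basalt" & samples$year == y, ]
    base <- if (baseline == "pretreatment")
      samples[samples$year == baseline_year, ]
    else
      samples[samples$treatment == "control" & samples$year == y, ]
    if (nrow(treated) < 2 || nrow(base) < 2)
      stop("year ", y, ": need at least 2 treated and 2 baseline samples",
           call. = FALSE)
    cum <- cum_before(y)
    if (cum <= 0) stop("year ", y, ": no rock applied yet", call. = FALSE)

    ti_t <- mean_mq(treated$Ti, uncertainty)
    ti_s <- mean_mq(base$Ti, uncertainty)
    ti_b <- feedstock_conc(feedstock, "Ti", as_mq = TRUE)
    floor_ <- if (is.null(min_contrast))
      tracer_contrast_floor(stats::sd(base$Ti)) else min_contrast

    if (aggregation == "mean") {
      res <- account_from_means(treated, ti_t, ti_s, ti_b, floor_, cations,
                                feedstock, m_soil, base, uncertainty,
                                correlated_b)
    } else {
      res <- account_per_sample(treated, ti_s, ti_b, floor_, cations,
                                feedstock, m_soil, base, uncertainty)
    }

    part_vals <- depth_partition(res$m_basalt$value, cum)
    part_sd <- res$m_basalt$sd / cum
    m_eff <- mq(cum * (part_vals[["in_layer"]] +
                         depth_below_factor * part_vals[["below"]]),
                cum * abs(1 - depth_below_factor) * part_sd)
    cb_ca <- if ("Ca" %in% cations) feedstock_conc(feedstock, "Ca", as_mq = TRUE)
             else mq(0, 0)
    cb_mg <- if ("Mg" %in% cations) feedstock_conc(feedstock, "Mg", as_mq = TRUE)
             else mq(0, 0)
    p_of <- function(el) {
      i <- match(el, res$cations$element)
      if (is.na(i)) mq(0, 0)
      else mq(res$cations$proportion[i], res$cations$proportion_sd[i])
    }
    cdr <- propagate_through("cdr_potential",
                             list(p_of("Ca"), p_of("Mg"), cb_ca, cb_mg, m_eff))

    results[[as.character(y)]] <- structure(
      list(year = y,
           n_treated = nrow(treated),
           cum_applied_t_ha = cum,
           m_soil_t_ha = m_soil,
           p_basalt = res$p_basalt,
           m_basalt_t_ha = res$m_basalt,
           partition = part_vals,
           partition_sd = part_sd,
           cations = res$cations,
           m_applied_effective_t_ha = m_eff,
           depth_below_factor = depth_below_factor,
           cdr_pot_t_co2_ha = mq(cdr$value, cdr$sd),
           aggregation = aggregation,
           uncertainty = uncertainty),
      class = "weathering_result")
  }

  series <- data.frame(
    year = as.integer(names(results)),
    cum_applied_t_ha = vapply(results, `[[`, numeric(1), "cum_applied_t_ha"),
    cum_cdr_pot = vapply(results, function(r) r$cdr_pot_t_co2_ha$value,
                         numeric(1)),
    cum_sd = vapply(results, function(r) r$cdr_pot_t_co2_ha$sd, numeric(1)),
    row.names = NULL)

  structure(list(results = results, series = series,
                 settings = list(baseline = baseline,
                                 baseline_year = baseline_year,
                                 aggregation = aggregation,
                                 uncertainty = uncertainty,
                                 depth_below_factor = depth_below_factor,
                                 correlated_b = correlated_b)),
            class = "ew_fit")
}

# mean-of-samples accounting for one year
account_from_means <- function(treated, ti_t, ti_s, ti_b, floor_, cations,
                               feedstock, m_soil, base, uncertainty,
                               correlated_b) {
  p_val <- basalt_fraction(ti_t$value, ti_s$value, ti_b$value,
                           min_contrast = floor_)
  p_pr <- propagate_ratio_of_differences(ti_t, ti_s, ti_b,
                                         correlated_b = correlated_b)
  p_mq <- mq(as.numeric(p_val), p_pr$sd, ti_t$n)
  m_basalt <- propagate_through("basalt_mass", list(mq(m_soil, 0), p_mq))

  rows <- lapply(cations, function(ca) {
    obs <- mean_mq(treated[[ca]], uncertainty)
    cs <- mean_mq(base[[ca]], uncertainty)
    cb <- feedstock_conc(feedstock, ca, as_mq = TRUE)
    expd <- propagate_through("expected_cation", list(cb, cs, p_mq))
    wthd <- propagate_through("weathered_cation",
                              list(mq(expd$value, expd$sd), obs))
    prop <- if (correlated_b)
      propagate_through("loss_fraction", list(ti_t, ti_s, ti_b, obs, cs, cb))
    else
      propagate_through("weathered_proportion",
                        list(mq(wthd$value, wthd$sd), cb, p_mq))
    data.frame(element = ca,
               conc_basalt = cb$value,
               conc_soil = cs$value, conc_soil_sd = cs$sd,
               observed = obs$value, observed_sd = obs$sd,
               expected = expd$value, expected_sd = expd$sd,
               weathered = wthd$value, weathered_sd = wthd$sd,
               apparent_gain = wthd$value < 0,
               proportion = prop$value, proportion_sd = prop$sd)
  })
  list(p_basalt = mq(as.numeric(p_val), p_pr$sd, ti_t$n),
       m_basalt = mq(m_basalt$value, m_basalt$sd, ti_t$n),
       cations = do.call(rbind, rows))
}

# per-sample accounting: the chain evaluated per treated sample, then averaged
account_per_sample <- function(treated, ti_s, ti_b, floor_, cations,
                               feedstock, m_soil, base, uncertainty) {
  p_i <- basalt_fraction(treated$Ti, ti_s$value, ti_b$value,
                         min_contrast = floor_)
  p_i <- as.numeric(p_i)
  p_sum <- mean_mq(p_i, uncertainty)
  mb_i <- basalt_mass(m_soil, pmin(p_i, 0.999999))
  mb_sum <- mean_mq(mb_i, uncertainty)

  rows <- lapply(cations, function(ca) {
    cs <- mean_mq(base[[ca]], uncertainty)
    cb <- feedstock_conc(feedstock, ca)
    exp_i <- expected_cation(cb, cs$value, pmin(pmax(p_i, 0), 1))
    wthd_i <- as.numeric(weathered_cation(exp_i, treated[[ca]]))
    prop_i <- wthd_i / (cb * p_i)
    obs <- mean_mq(treated[[ca]], uncertainty)
    expd <- mean_mq(exp_i, uncertainty)
    wthd <- mean_mq(wthd_i, uncertainty)
    prop <- mean_mq(prop_i, uncertainty)
    data.frame(element = ca,
               conc_basalt = cb,
               conc_soil = cs$value, conc_soil_sd = cs$sd,
               observed = obs$value, observed_sd = obs$sd,
               expected = expd$value, expected_sd = expd$sd,
               weathered = wthd$value, weathered_sd = wthd$sd,
               apparent_gain = wthd$value < 0,
               proportion = prop$value, proportion_sd = prop$sd)
  })
  list(p_basalt = p_sum, m_basalt = mb_sum, cations = do.call(rbind, rows))
}

#' @export
print.weathering_result <- function(x, ...) {
  cat("Weathering accounting, year ", x$year,
      " (", x$cum_applied_t_ha, " t/ha applied to date; ",
      x$aggregation, " aggregation, ", x$uncertainty, " basis)\n", sep = "")
  cat("  p_basalt:   ", format(x$p_basalt), "\n", sep = "")
  cat("  m_basalt:   ", format(x$m_basalt_t_ha), " t/ha of ",
      x$m_soil_t_ha, " t/ha soil\n", sep = "")
  cat("  partition:  ", round(100 * x$partition[["in_layer"]], 1),
      "% in layer / ", round(100 * x$partition[["below"]], 1),
      "% below (sd ", round(100 * x$partition_sd, 1), "%)\n", sep = "")
  for (i in seq_len(nrow(x$cations))) {
    r <- x$cations[i, ]
    cat("  ", r$element, ": expected ", round(r$expected, 1),
        ", observed ", round(r$observed, 1),
        ", weathered ", round(r$weathered, 1), " mg/kg -> loss ",
        round(100 * r$proportion, 1), " ± ",
        round(100 * r$proportion_sd, 1), " %",
        if (r$apparent_gain) "  [apparent gain]" else "", "\n", sep = "")
  }
  cat("  CDR_pot:    ", format(x$cdr_pot_t_co2_ha), " t CO2/ha (cumulative; ",
      "below-layer factor ", x$depth_below_factor, ")\n", sep = "")
  invisible(x)
}

#' @export
print.ew_fit <- function(x, ...) {
  for (r in x$results) { print(r); cat("\n") }
  invisible(x)
}

#' Flatten a weathering fit to a result table
#'
#' One row per analysis year and cation, value and SD side by side, plus the
#' shared per-year quantities — the CSV-ready external result format.
#'
#' @param x An `ew_fit` from [estimate_weathering()].
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.ew_fit <- function(x, ...) {
  rows <- lapply(x$results, function(r) {
    cbind(data.frame(year = r$year,
                     cum_applied_t_ha = r$cum_applied_t_ha,
                     p_basalt = r$p_basalt$value,
                     p_basalt_sd = r$p_basalt$sd,
                     m_basalt_t_ha = r$m_basalt_t_ha$value,
                     m_basalt_sd = r$m_basalt_t_ha$sd,
                     frac_in_layer = r$partition[["in_layer"]],
                     frac_in_layer_sd = r$partition_sd),
          r$cations,
          data.frame(cdr_pot_t_co2_ha = r$cdr_pot_t_co2_ha$value,
                     cdr_pot_sd = r$cdr_pot_t_co2_ha$sd))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
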