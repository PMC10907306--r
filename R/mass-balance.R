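#' Stoichiometric constants for CDR accounting
#'
#' Atomic weights of the divalent base cations, the molecular weight of CO2,
#' and the 2:1 CO2-to-cation ratio of the Urey reaction between silicate
#' minerals and carbonic acid. These are exact accounting constants, not
#' tunables.
#'
#' @return A list with `atomic_weight` (g/mol, named Ca/Mg), `m_co2` (g/mol)
#'   and `co2_per_cation` (mol CO2 converted to bicarbonate per mol divalent
#'   cation weathered).
#' @export
stoich_constants <- function() {
  list(atomic_weight = c(Ca = 40.078, Mg = 24.305),
       m_co2 = 44.009,
       co2_per_cation = 2)
}

#' Basalt mass fraction from immobile-Ti mixing
#'
#' Two-endmember mixing on an immobile trace element: the fraction of a
#' treated soil sample's mass that is basalt feedstock is
#' `(Ti_treated - Ti_soil) / (Ti_basalt - Ti_soil)`. Noise can push the
#' estimate slightly below 0 or above 1; such values are returned as-is with
#' an `out_of_range` attribute set, never silently clamped — clamping is the
#' caller's choice.
#'
#' @param ti_treated Ti concentration of treated soil, mg/kg.
#' @param ti_soil Baseline (pretreatment) soil Ti, mg/kg.
#' @param ti_basalt Feedstock Ti, mg/kg.
#' @param min_contrast Tracer-contrast floor: if `|ti_basalt - ti_soil|` is at
#'   or below this, the tracer method is unusable and an error is thrown. A
#'   practical floor is ~10x the Ti analytical SD (see [tracer_contrast_floor()]).
#' @return Mass fraction (vectorized over `ti_treated`), with attribute
#'   `out_of_range` (logical) flagging estimates outside [0, 1].
#' @examples
#' basalt_fraction(3417, 2693, 10899)  # ~0.088
#' @export
basalt_fraction <- function(ti_treated, ti_soil, ti_basalt, min_contrast = 0) {
  stopifnot(all(ti_treated >= 0), ti_soil >= 0, ti_basalt >= 0,
            min_contrast >= 0)
  contrast <- ti_basalt - ti_soil
  if (abs(contrast) <= min_contrast || contrast == 0)
    stop("degenerate tracer contrast: |ti_basalt - ti_soil| = ",
         format(abs(contrast)),
         " is at or below the floor (", format(min_contrast),
         "); the immobile-tracer method is unusable here", call. = FALSE)
  p <- (ti_treated - ti_soil) / contrast
  attr(p, "out_of_range") <- p < 0 | p > 1
  p
}

#' Default tracer-contrast floor
#'
#' Ten times the tracer's analytical SD: below this contrast the mixing ratio
#' is dominated by noise rather than feedstock accumulation.
#'
#' @param ti_sd Analytical SD of the tracer concentration, mg/kg.
#' @export
tracer_contrast_floor <- function(ti_sd) 10 * ti_sd

#' Soil layer geometry
#'
#' @param depth_m Layer thickness in metres.
#' @param area_m2 Ground area in square metres; default one hectare.
#' @param bulk_density_t_m3 Dry bulk density, t per cubic metre.
#' @return An object of class `soil_layer_geometry`.
#' @export
soil_layer_geometry <- function(depth_m, area_m2 = 10000, bulk_density_t_m3) {
  vals <- c(depth_m, area_m2, bulk_density_t_m3)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("depth, area and bulk density must all be strictly positive",
         call. = FALSE)
  structure(list(depth_m = depth_m, area_m2 = area_m2,
                 bulk_density_t_m3 = bulk_density_t_m3),
            class = "soil_layer_geometry")
}

#' Mass of soil in a layer, per hectare
#'
#' depth x area x bulk density. With the default one-hectare area the result
#' reads directly in t/ha (e.g. 0.1 m x 10,000 m2 x 1.2 t/m3 = 1,200 t/ha).
#'
#' @param geometry A [soil_layer_geometry()].
#' @return Soil mass in t per ha.
#' @export
soil_mass <- function(geometry) {
  stopifnot(inherits(geometry, "soil_layer_geometry"))
  geometry$depth_m * geometry$area_m2 * geometry$bulk_density_t_m3 *
    (10000 / geometry$area_m2)
}

#' Basalt mass in a soil layer
#'
#' `m_soil * p / (1 - p)`: the basalt mass that, mixed into `m_soil` of
#' original soil, gives a bulk sample with basalt mass fraction `p`.
#'
#' @param m_soil Soil mass in the layer, t/ha.
#' @param p_basalt Basalt mass fraction of the bulk sample.
#' @return Basalt mass, t/ha.
#' @export
basalt_mass <- function(m_soil, p_basalt) {
  if (any(p_basalt >= 1))
    stop("p_basalt must be < 1: soil cannot be more than pure basalt",
         call. = FALSE)
  m_soil * p_basalt / (1 - p_basalt)
}

#' Partition of applied rock between the sampled layer and below
#'
#' Splits the cumulative applied rock mass into the share recovered (by the
#' tracer) in the sampled layer and the remainder attributed to deeper soil.
#' Tracer over-recovery (layer mass above the applied total) is possible under
#' noise; it is flagged and only capped at 1 on request.
#'
#' @param m_basalt_layer Basalt mass found in the sampled layer, t/ha.
#' @param m_applied_total Cumulative rock applied, t/ha.
#' @param cap Cap the layer fraction at 1 when over-recovered? Default FALSE.
#' @return Named numeric `c(in_layer =, below =)`, with attribute
#'   `over_recovered` when the tracer found more rock than was applied.
#' @examples
#' depth_partition(116, 200)  # 58% / 42%
#' @export
depth_partition <- function(m_basalt_layer, m_applied_total, cap = FALSE) {
  stopifnot(m_basalt_layer >= 0, m_applied_total > 0)
  f <- m_basalt_layer / m_applied_total
  over <- f > 1
  if (over) {
    warning("tracer over-recovery: layer basalt mass exceeds the applied total",
            call. = FALSE)
    if (cap) f <- 1
  }
  out <- c(in_layer = f, below = 1 - f)
  attr(out, "over_recovered") <- over
  out
}

#' Expected cation concentration under two-endmember mixing
#'
#' The concentration a treated sample would show if no weathering had
#' occurred: `conc_basalt * p + (1 - p) * conc_soil`.
#'
#' @param conc_basalt Cation concentration of the feedstock, mg/kg.
#' @param conc_soil Baseline soil concentration, mg/kg.
#' @param p_basalt Basalt mass fraction in [0, 1].
#' @return Expected concentration, mg/kg.
#' @export
expected_cation <- function(conc_basalt, conc_soil, p_basalt) {
  stopifnot(all(p_basalt >= 0), all(p_basalt <= 1))
  conc_basalt * p_basalt + (1 - p_basalt) * conc_soil
}

#' Weathered (lost) cation concentration
#'
#' Difference between the mixing expectation and the observed concentration.
#' Negative values (apparent gain) are returned signed with an
#' `apparent_gain` attribute — clamping them would bias cumulative CDR upward.
#'
#' @param expected Expected concentration, mg/kg.
#' @param observed Observed concentration in treated soil, mg/kg.
#' @return Weathered concentration, mg/kg (signed).
#' @export
weathered_cation <- function(expected, observed) {
  w <- expected - observed
  attr(w, "apparent_gain") <- w < 0
  w
}

#' Proportion of the basalt-derived cation pool lost to weathering
#'
#' Attributes the whole loss to the feedstock (not native soil): the
#' denominator is the basalt-derived pool `conc_basalt * p_basalt` in the
#' bulk sample.
#'
#' @param weathered Weathered concentration, mg/kg.
#' @param conc_basalt Feedstock cation concentration, mg/kg.
#' @param p_basalt Basalt mass fraction.
#' @return Loss proportion (signed; >1 means more than the pool was lost,
#'   which only noise can produce).
#' @export
weathered_proportion <- function(weathered, conc_basalt, p_basalt) {
  pool <- conc_basalt * p_basalt
  if (any(pool <= 0))
    stop("zero basalt-derived cation pool: conc_basalt * p_basalt must be > 0",
         call. = FALSE)
  weathered / pool
}

#' Time-integrated CDR potential from cation loss
#'
#' Converts the proportions of Ca and Mg lost from the applied rock into
#' tonnes of CO2 converted to bicarbonate, per hectare:
#' each mole of divalent cation weathered converts 2 moles of CO2. The 1e-6
#' converting mg/kg feedstock concentrations to mass fractions is owned here;
#' callers pass concentrations in mg/kg via the feedstock record.
#'
#' @param p_ca_weathered,p_mg_weathered Proportions of the basalt Ca and Mg
#'   pools lost. Values outside [0, 1] are accepted with a warning (noise can
#'   produce them).
#' @param feedstock A [rock_feedstock()] with Ca and Mg.
#' @param m_applied Rock mass the proportions apply to, t/ha.
#' @param constants [stoich_constants()].
#' @return CDR potential, t CO2 per ha. Exactly linear in `m_applied` and in
#'   each proportion.
#' @export
cdr_potential <- function(p_ca_weathered, p_mg_weathered, feedstock,
                          m_applied, constants = stoich_constants()) {
  stopifnot(inherits(feedstock, "rock_feedstock"), m_applied >= 0)
  fr <- feedstock$element_mass_fraction
  if (!all(c("Ca", "Mg") %in% names(fr)))
    stop("feedstock must record Ca and Mg mass fractions", call. = FALSE)
  if (any(c(p_ca_weathered, p_mg_weathered) < 0) ||
      any(c(p_ca_weathered, p_mg_weathered) > 1))
    warning("weathered proportion outside [0, 1]; result extrapolates linearly",
            call. = FALSE)
  cdr_potential_num(p_ca_weathered, p_mg_weathered,
                    fr[["Ca"]] * 1e6, fr[["Mg"]] * 1e6, m_applied, constants)
}

# numeric core: feedstock concentrations in mg/kg, no container — this is the
# function registered for uncertainty propagation
cdr_potential_num <- function(p_ca, p_mg, ca_basalt_mg_kg, mg_basalt_mg_kg,
                              m_applied, constants = stoich_constants()) {
  aw <- constants$atomic_weight
  k <- constants$co2_per_cation * constants$m_co2
  (p_ca * ca_basalt_mg_kg * 1e-6 * m_applied / aw[["Ca"]] +
   p_mg * mg_basalt_mg_kg * 1e-6 * m_applied / aw[["Mg"]]) * k
}

#' Theoretical maximum CDR potential of a feedstock
#'
#' [cdr_potential()] with both loss proportions at 1: complete dissolution of
#' the rock's Ca and Mg.
#'
#' @inheritParams cdr_potential
#' @return t CO2 per ha.
#' @export
theoretical_max_cdr <- function(feedstock, m_applied,
                                constants = stoich_constants()) {
  cdr_potential(1, 1, feedstock, m_applied, constants)
}

#' Cumulative CDR series over a multi-year trial
#'
#' Accumulates per-year CDR increments additively. Input rows give the CDR
#' potential attributable to each year (already computed against the
#' cumulative rock mass applied to date); SDs combine in quadrature under the
#' independence assumption used throughout.
#'
#' @param yearly Data frame with columns `year`, `cdr_pot` and optionally
#'   `sd`; one row per year, any order.
#' @param schedule Named numeric: rock applied (t/ha) keyed by year (names);
#'   must cover every result year.
#' @return Data frame `year, applied_t_ha, cum_applied_t_ha, cdr_pot, sd,
#'   cum_cdr_pot, cum_sd`, sorted by year. Empty input gives an empty frame.
#' @export
cumulative_cdr_series <- function(yearly, schedule) {
  stopifnot(is.data.frame(yearly))
  cols <- c("year", "applied_t_ha", "cum_applied_t_ha",
            "cdr_pot", "sd", "cum_cdr_pot", "cum_sd")
  if (nrow(yearly) == 0)
    return(stats::setNames(data.frame(matrix(numeric(0), ncol = 7)), cols))
  stopifnot(all(c("year", "cdr_pot") %in% names(yearly)))
  if (is.null(yearly$sd)) yearly$sd <- 0
  yearly <- yearly[order(yearly$year), ]
  missing <- setdiff(as.character(yearly$year), names(schedule))
  if (length(missing))
    stop("application schedule missing year(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  applied <- unname(schedule[as.character(yearly$year)])
  data.frame(year = yearly$year,
             applied_t_ha = applied,
             cum_applied_t_ha = cumsum(applied),
             cdr_pot = yearly$cdr_pot,
             sd = yearly$sd,
             cum_cdr_pot = cumsum(yearly$cdr_pot),
             cum_sd = sqrt(cumsum(yearly$sd^2)))
}
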