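#' Nutrient pool from tissue concentration and dry biomass
#'
#' `concentration (mg/kg) x biomass (kg/ha) x 1e-6` gives kg of the element
#' per hectare. Vectorized.
#'
#' @param concentration mg element per kg dry biomass.
#' @param biomass kg dry biomass per ha.
#' @return kg element per ha.
#' @examples
#' nutrient_pool(1000, 10000)  # 10 kg/ha
#' @export
nutrient_pool <- function(concentration, biomass) {
  stopifnot(all(concentration >= 0), all(biomass >= 0))
  concentration * biomass * 1e-6
}

#' Tissue pool sums
#'
#' Vegetative pool = root + stem + leaf; total peak-biomass pool adds the
#' floral (or grain) pool. `pools` is a named numeric vector of per-tissue
#' pools in kg/ha.
#'
#' @param pools Named numeric; names among root, stem, leaf, floral, grain.
#' @return kg element per ha.
#' @export
vegetative_pool <- function(pools) {
  sum(pools[names(pools) %in% c("root", "stem", "leaf")])
}

#' @rdname vegetative_pool
#' @export
total_pool <- function(pools) {
  sum(pools[names(pools) %in% c("root", "stem", "leaf", "floral", "grain")])
}

#' Net nitrogen mineralization rate from soil N decline
#'
#' Loss of soil N (percentage points of soil mass) over the trial, converted
#' to kg N per ha per year against the soil mass of the sampled profile.
#' Negative results (N accumulation) are returned signed.
#'
#' @param soil_n_start_pct,soil_n_end_pct Soil N content, % of dry soil mass.
#' @param soil_mass Soil mass of the profile, t/ha.
#' @param years Number of years elapsed, >= 1.
#' @return kg N per ha per year (signed).
#' @examples
#' n_mineralization_rate(0.20, 0.19, 3600, 4)  # 9 kg N/ha/yr
#' @export
n_mineralization_rate <- function(soil_n_start_pct, soil_n_end_pct,
                                  soil_mass, years) {
  stopifnot(years >= 1, soil_mass > 0)
  (soil_n_start_pct - soil_n_end_pct) / 100 * soil_mass * 1000 / years
}

#' Nitrogen use efficiency
#'
#' `NUE% = (N_grain - N_mineralization) / N_fertilizer x 100`. The
#' mineralization term is an annual rate applied over one cropping season, so
#' its kg/ha/yr units match the kg/ha grain pool over a single year.
#' Undefined in unfertilized (e.g. soybean) years.
#'
#' @param n_grain Total grain biomass N pool, kg/ha.
#' @param n_mineralization Treatment-specific N mineralization rate, kg/ha/yr.
#' @param n_fertilizer N application rate, kg/ha; must be > 0. The reference
#'   trial applies 202 kg N/ha to maize as 28% urea ammonium nitrate.
#' @return NUE in percent.
#' @examples
#' nue(120, 19, 202)  # 50%
#' @export
nue <- function(n_grain, n_mineralization, n_fertilizer = 202) {
  if (any(n_fertilizer <= 0))
    stop("NUE is undefined without fertilizer input (n_fertilizer must be > 0)",
         call. = FALSE)
  (n_grain - n_mineralization) / n_fertilizer * 100
}

#' Element release from immobile-ratio depletion in recovered rock grains
#'
#' Rock grains recovered from treated soil show depleted element/Ti ratios
#' relative to fresh rock; with Ti immobile in the grains, the loss fraction
#' is `f = 1 - ratio_weathered / ratio_fresh`, and the annual release is `f`
#' times the element mass applied each year. These are lower-bound estimates:
#' grains without magnetic minerals and fully dissolved fines are not
#' recovered. Negative `f` (apparent enrichment) is flagged, not clamped.
#'
#' @param ratio_fresh,ratio_weathered Element/Ti mass ratios in fresh and
#'   field-weathered grains; `ratio_fresh` must be > 0.
#' @param element_conc_basalt Element concentration of the rock, mg/kg.
#' @param application_rate Rock applied per year, t/ha/yr.
#' @return kg element per ha per year, with attributes `loss_fraction` and
#'   `apparent_gain`, and `lower_bound = TRUE` metadata.
#' @examples
#' element_release_from_ratio(0.30, 0.24, 700, 50)  # 7 kg P/ha/yr
#' @export
element_release_from_ratio <- function(ratio_fresh, ratio_weathered,
                                       element_conc_basalt, application_rate) {
  if (any(ratio_fresh <= 0))
    stop("ratio_fresh must be > 0", call. = FALSE)
  stopifnot(all(ratio_weathered >= 0), all(element_conc_basalt >= 0),
            all(application_rate >= 0))
  f <- 1 - ratio_weathered / ratio_fresh
  release <- f * element_conc_basalt * 1e-6 * application_rate * 1000
  attr(release, "loss_fraction") <- f
  attr(release, "apparent_gain") <- f < 0
  attr(release, "lower_bound") <- TRUE
  release
}

#' Share of released cations exported in harvested grain
#'
#' The treatment-minus-control grain cation pool as a percentage of the total
#' cation mass released by weathering. Signed; a small value justifies
#' neglecting grain export in the soil mass balance.
#'
#' @param grain_pool_treated,grain_pool_control Grain cation pools, kg/ha.
#' @param total_weathered_cation_mass Total cation release from the rock,
#'   kg/ha; must be > 0.
#' @return Percent (signed).
#' @examples
#' grain_export_fraction(10.3, 10.0, 100)  # 0.3%
#' @export
grain_export_fraction <- function(grain_pool_treated, grain_pool_control,
                                  total_weathered_cation_mass) {
  if (any(total_weathered_cation_mass <= 0))
    stop("total weathered cation mass must be > 0", call. = FALSE)
  (grain_pool_treated - grain_pool_control) / total_weathered_cation_mass * 100
}
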