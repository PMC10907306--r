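#' Crop production scenario
#'
#' Inputs of the regional yield-value extrapolation: planted area, base
#' yield, fractional yield increase under enhanced weathering, and spot
#' price.
#'
#' @param area_acres Planted area in acres.
#' @param base_yield_bu_per_acre Base yield, bushels per acre.
#' @param yield_increase_fraction Fractional yield increase (0.12 for 12%).
#' @param price_usd_per_bu Price in USD per bushel.
#' @param crop Label, e.g. "corn" or "soybean".
#' @return An object of class `crop_scenario`.
#' @export
crop_scenario <- function(area_acres, base_yield_bu_per_acre,
                          yield_increase_fraction, price_usd_per_bu,
                          crop = "crop") {
  vals <- c(area_acres, base_yield_bu_per_acre,
            yield_increase_fraction, price_usd_per_bu)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all scenario fields must be finite and non-negative", call. = FALSE)
  structure(list(area_acres = area_acres,
                 base_yield_bu_per_acre = base_yield_bu_per_acre,
                 yield_increase_fraction = yield_increase_fraction,
                 price_usd_per_bu = price_usd_per_bu,
                 crop = crop),
            class = "crop_scenario")
}

#' Corn Belt scenarios at the reference trial values
#'
#' 30 Mha (74 million acres) each of corn and soybean, 2022 base yields of
#' 173.3 and 49.5 bu/acre, Feb-2023 prices of $6.44 and $15.12 per bushel,
#' and the trial's observed yield increases (12% maize, 16% soybean).
#'
#' @param yield_increase_fraction Override the default yield response.
#' @return A [crop_scenario()].
#' @export
corn_belt_maize <- function(yield_increase_fraction = 0.12) {
  crop_scenario(74e6, 173.3, yield_increase_fraction, 6.44, crop = "corn")
}

#' @rdname corn_belt_maize
#' @export
corn_belt_soybean <- function(yield_increase_fraction = 0.16) {
  crop_scenario(74e6, 49.5, yield_increase_fraction, 15.12, crop = "soybean")
}

#' Value of the yield increase
#'
#' `area x base yield x fractional increase x price`, in USD. Exactly linear
#' in every factor.
#'
#' @param scenario A [crop_scenario()].
#' @return USD.
#' @examples
#' production_value_increase(corn_belt_maize())  # ~$9.9 billion
#' @export
production_value_increase <- function(scenario) {
  stopifnot(inherits(scenario, "crop_scenario"))
  scenario$area_acres * scenario$base_yield_bu_per_acre *
    scenario$yield_increase_fraction * scenario$price_usd_per_bu
}

#' Value under a price band
#'
#' Re-evaluates the scenario with the price scaled by `1 + frac` at each band
#' edge (e.g. the year's observed price range of +26%/-3% for corn).
#'
#' @param scenario A [crop_scenario()].
#' @param price_low_frac,price_high_frac Fractional price changes,
#'   `price_low_frac <= price_high_frac`.
#' @return Named numeric `c(low =, high =)` in USD; monotone in price.
#' @export
price_band_sweep <- function(scenario, price_low_frac, price_high_frac) {
  if (price_low_frac > price_high_frac)
    stop("price_low_frac must not exceed price_high_frac", call. = FALSE)
  v <- production_value_increase(scenario)
  c(low = v * (1 + price_low_frac), high = v * (1 + price_high_frac))
}
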