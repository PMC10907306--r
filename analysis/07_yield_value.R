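#!/usr/bin/env Rscript
# Corn Belt yield-value extrapolation: the value of the trial's observed yield
# increases (12% maize, 16% soybean) over 74 million acres of each crop at
# recent prices, with the year's observed price bands. Writes
# results/yield_value.csv.

library(ewcdr)

maize <- corn_belt_maize()
soy <- corn_belt_soybean()

v_maize <- production_value_increase(maize)
v_soy <- production_value_increase(soy)
band_maize <- price_band_sweep(maize, -0.03, 0.26)
band_soy <- price_band_sweep(soy, -0.12, 0.11)

bn <- function(x) round(x / 1e9, 2)
cat("maize: $", bn(v_maize), "B (price band $", bn(band_maize[["low"]]),
    "-", bn(band_maize[["high"]]), "B)\n", sep = "")
cat("soybean: $", bn(v_soy), "B (price band $", bn(band_soy[["low"]]),
    "-", bn(band_soy[["high"]]), "B)\n", sep = "")

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(
  crop = c("corn", "soybean"),
  yield_increase = c(maize$yield_increase_fraction, soy$yield_increase_fraction),
  value_usd = c(v_maize, v_soy),
  value_price_low = c(band_maize[["low"]], band_soy[["low"]]),
  value_price_high = c(band_maize[["high"]], band_soy[["high"]])),
  "results/yield_value.csv", row.names = FALSE)
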