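---
title: "Immobile-tracer accounting of enhanced weathering: model, uncertainty and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immobile-tracer accounting of enhanced weathering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewcdr)
```

## The accounting problem

When crushed basalt is spread on farmland, its dissolution releases Ca²⁺ and
Mg²⁺ that are charge-balanced by bicarbonate formed from CO₂ — the basis of
enhanced-weathering (EW) carbon dioxide removal. Measuring that removal in
the field is hard: drainage-water chemistry is confounded by high and
variable background alkalinity and by retardation of solutes on exchange
sites. `ewcdr` implements the solid-soil alternative: account for the rock
itself, in the soil, using titanium as an immobile tracer.

The chain has four steps, each exported as a plain function and also
registered with the propagation machinery:

1. **Mixing.** Ti accumulates with the rock, so the basalt mass fraction of
   a treated sample is `p = (Ti_treated − Ti_soil)/(Ti_basalt − Ti_soil)`
   (`basalt_fraction()`). The method needs tracer contrast: the feedstock
   here carries ~4× the soil's Ti.
2. **Mass.** `m_basalt = m_soil · p/(1 − p)` (`basalt_mass()`), with
   `m_soil` from layer depth × area × bulk density (`soil_mass()`;
   0.1 m × 1 ha × 1.2 t m⁻³ = 1,200 t ha⁻¹ for the reference layer).
   Against the cumulative mass applied this yields the depth partition
   (`depth_partition()`): in the reference configuration ~58% of the rock
   resides in the sampled 0–10 cm, 42% below, consistent with chisel
   plowing to ~18 cm.
3. **Cation loss.** For each divalent cation, the mixing expectation minus
   the observation is the weathered concentration; dividing by the
   basalt-derived pool `conc_basalt · p` gives the loss proportion
   (`expected_cation()`, `weathered_cation()`, `weathered_proportion()`).
   The attribution assumption — losses come from the rock, not native soil —
   is supported in such trials by stable control-plot concentrations, and is
   an assumption, not a measurement.
4. **Stoichiometry.** Each mole of divalent cation weathered converts
   2 moles of CO₂ to bicarbonate (Urey reaction), so
   `CDR_pot = Σ p_X · X_frac · m_applied / A_X · 2 · M_CO2`
   (`cdr_potential()`, with A_Ca = 40.078, A_Mg = 24.305,
   M_CO2 = 44.009 g mol⁻¹ fixed in `stoich_constants()`). CDR_pot is
   *potential*, time-integrated removal: it counts cations destined for
   export as bicarbonate and says nothing about transport time.

## Key assumptions and the knobs that control them

- **Depth extrapolation** (`depth_below_factor`, default 1): the rock below
  the sampled layer is assumed to weather at the sampled layer's rate.
  Higher pCO₂ and similar-or-lower pH at depth make this mildly
  conservative-to-fair; setting the factor to 0 gives strictly
  sampled-layer-only accounting. Anything in [0, 1] is allowed.
- **Baseline** (`baseline`): pretreatment-year samples by default (all plots
  before any application), or contemporaneous controls.
- **Aggregation** (`aggregation`): means of samples are plugged into the
  equations by default, matching how such accounting is usually reported;
  `"per_sample"` computes the chain per sample and averages, which differs
  under the nonlinearity of `p/(1 − p)` and is less stable when individual
  `p` estimates approach 0.
- **Signed losses**: apparent gains (negative weathered concentrations) are
  flagged and retained. Clamping at zero would bias cumulative CDR upward,
  particularly for slowly weathering Mg whose loss estimate can fluctuate
  negative.
- **Tracer-contrast floor** (`min_contrast`, default 10× the baseline Ti
  between-sample SD): below this contrast the mixing denominator is noise
  and the method refuses to return a fraction rather than returning an
  unstable one.

## Uncertainty propagation

All reported SDs are first-order ("standard rules") Gaussian propagation
with all covariances taken as zero — the only information such tables carry
is mean ± SD. `propagate_through()` works for any registered operation using
central-difference gradients (step `max(1e−6·|x|, 1e−9)`); the value it
reports is always the plain operation's output, exactly. `monte_carlo()` is
the independent oracle: normal draws per input, deterministic under its
seed, erroring if more than 1% of draws violate an operation's domain
(e.g. `p ≥ 1`).

One convention deserves care. In the mixing ratio `(a − b)/(c − b)` the
baseline `b` appears twice. Treating the two occurrences as independent —
relative variances of numerator and denominator simply add — is the
convention under which published SDs of such ratios are reproduced here
(0.0418 for the reference inputs, against roughly 0.0406 for the correlated
treatment), so it is the default in
`propagate_ratio_of_differences()`. The statistically faithful treatment of
the shared term is one flag away (`correlated_b = TRUE`), and each
convention is checked against its own Monte-Carlo counterpart: a
four-argument split op `(a − b₁)/(c − b₂)` for the independent convention,
the shared three-argument op for the correlated one. Collapsing these two
checks onto one oracle would silently test the wrong convention.

A related note: first-order propagation of the reference SDs through
`m_soil · p/(1 − p)` gives an SD near 60 t ha⁻¹ for the basalt mass
(derivative `m_soil/(1 − p)²`). A much tighter spread can only describe the
variability of per-sample mass estimates around their mean, not the
propagated SD of the printed inputs; both routes are available
(`propagate_through("basalt_mass", ...)` and the per-sample aggregation
mode) and neither is forced to agree with the other.

SD versus SEM: everything internal is SD; `sem()` derives `sd/√n` at report
time, and `estimate_weathering(uncertainty = "sem")` bases the means'
uncertainty on SEM where inference about the mean (e.g. interval coverage)
is the goal.

## The synthetic trial generator

`trial_config()` defaults encode the reference trial conditions: four
blocks plus a large plot (effective n = 5), years 2016–2020 with the first
year as pretreatment baseline, 50 t ha⁻¹ applied each autumn 2016–2019
(cumulative 50–200 t ha⁻¹ at the summer samplings), soil baseline Ti of
2,693 mg kg⁻¹, feedstock Ti of 10,899 mg kg⁻¹, and 58% of the applied rock
in the sampled 0–10 cm layer. Noise has two parts chosen to reproduce the
observed total between-sample Ti spread of ~196 mg kg⁻¹ (CV ≈ 7.3%): an
additive per-block shift (relative SD 0.03, drawn once per block per
element — minimal spatial heterogeneity without geostatistics) and
multiplicative analytical noise (CV 0.066 for Ti, 0.06 for cations),
lognormal and mean-corrected because concentrations are positive and
right-skewed (a normal alternative sits behind `noise_model`). The
generator also emits a "measured" feedstock — the true composition
perturbed by its recorded measurement SDs — because that is what an analyst
actually has.

The bundled `synthetic_feedstock()` is a constructed record, not a rock
analysis: Ti is set to the tracer value above, and the Ca (3.10 wt%) and Mg
(7.07 wt%) fractions are solved from two anchors — a theoretical maximum
CDR of 16.2 t CO₂ ha⁻¹ per 50 t of rock at complete Ca+Mg dissolution, and
an endpoint cumulative CDR of ~10.5 t CO₂ ha⁻¹ when the endpoint loss
fractions (0.32 Ca, 0.12 Mg) act on 200 t ha⁻¹. The default per-year
cumulative loss fractions (Ca 0.55 → 0.32, Mg 0.15 → 0.12) decline with
time, as expected when the finest, fastest-weathering grains dissolve
first; their intermediate values are a modelling choice, since yearly
accounting points are generally not recoverable from endpoint aggregates.
The truth CDR series they produce runs 3.8 → 6.3 → 8.6 → 10.5 t CO₂ ha⁻¹.

What the generator does *not* emulate — and hence what passing tests cannot
show about real data: within-plot spatial correlation, secondary mineral
formation or cation retention on exchange sites, time-varying bulk density,
tillage redistribution between layers beyond the fixed 58/42 split, and
grain export feedback on the soil budget (of order 0.3% of release, so
neglected). Forward-inverse identity at zero noise validates the algebra;
recovery under noise validates the statistics; neither validates the
geochemical assumptions themselves.

## Validation results computed by this package

The test suite and `analysis/` scripts compute (not quote): exact
forward-inverse recovery at zero noise; across 500 simulated trials under
study-like noise, |bias| < 0.01 on the final-year loss fractions with 95%
interval coverage between 0.93 and 0.97; agreement of analytic and
Monte-Carlo SDs within 3 Monte-Carlo standard errors across randomized
inputs; and agreement of `cdr_potential()` with an independent
mole-counting oracle to 1e−12 relative over 1,000 random inputs. The
500-replicate recovery runs in a few seconds on one CPU; Monte-Carlo
oracles use 10⁶ draws where a published SD is being checked and 2×10⁴ in
the randomized property tests.

## Agronomy and economics modules

The side budgets follow the same spirit — plain arithmetic, explicit units:

- `nutrient_pool()` (mg kg⁻¹ × kg ha⁻¹ × 10⁻⁶ → kg ha⁻¹) with vegetative
  (root+stem+leaf) and total sums.
- `n_mineralization_rate()`: soil-N decline (percentage points) × soil mass
  / years, signed. `nue()` is `(N_grain − N_mineralization)/N_fertilizer ×
  100`; the mineralization rate is applied over one cropping season so the
  units close, and NUE is refused (error) in unfertilized soybean years.
- `element_release_from_ratio()`: P/Ti and K/Ti depletion of recovered rock
  grains → release per year, labelled a lower bound because non-magnetic
  and fully dissolved grains escape recovery.
- `grain_export_fraction()`: the treated-minus-control grain pool as a
  percentage of total release — the quantity that justifies ignoring
  harvest export in the soil balance.
- `production_value_increase()` / `price_band_sweep()`: area × base yield ×
  fractional increase × price, a deliberately cost-free upper-level
  extrapolation (no rock, transport or spreading costs).

## Numerical and degenerate-input policy

Division-adjacent preconditions are errors, not NaNs: zero tracer contrast,
`p ≥ 1`, zero basalt-derived pool, zero fertilizer N, zero fresh ratio.
Out-of-range but finite results that noise can legitimately produce
(negative `p`, loss proportion outside [0, 1], tracer over-recovery) are
returned signed with attribute flags and, where a hard cap exists
physically, capped only on request. Monte-Carlo draws may optionally be
truncated at zero for concentrations; the default leaves them untruncated
to match the plain Gaussian convention. All randomness is seeded and scoped
(the caller's RNG stream is never disturbed).

## Known limitations

First-order propagation understates skew for strongly nonlinear steps at
large CVs (the basalt-mass step is the worst). Covariances among reported
means are unavailable and assumed zero, except where the composed estimator
(`"loss_fraction"`) makes shared terms explicit. The depth partition treats
the sampled layer as homogeneous. And the economics module prices yield
only — it is not a cost-benefit analysis of EW deployment.
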