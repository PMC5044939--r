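---
title: "Estimating regional biomass potentials from soil evaluation and climate data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating regional biomass potentials from soil evaluation and climate data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yieldscape)
library(dplyr)
```

`yieldscape` estimates per-crop biomass yield potentials for a region from
two ubiquitous German data sources: soil-evaluation records
(Bodenschätzung: a dominant texture class plus a 1–100 quality number per
parcel) and daily station climate. The pipeline has five stages, each a
module of the package:

1. **Pedotransfer** — soil type + soil number → plant-available field
   capacity (nFK, mm), both as discrete reference classes and as fitted
   continuous curves.
2. **Climate preparation** — daily station records → the monthly values the
   crop engine consumes, plus long-term normals and anomaly measures.
3. **Crop engine** — a water- and temperature-limited monthly growth model
   run on a small grid of *data units* (soil type × nFK class × climate
   region) instead of every parcel.
4. **Calibration and validation** — simulated regional yields against
   observed harvest statistics: adjustment factor, per-year errors, RMSE,
   correlation, Willmott index of agreement.
5. **Potential mapping** — period-averaged unit yields → polynomial
   nFK-to-yield interpolation curves → per-parcel potential surfaces in
   yield bands.

A seeded synthetic-data generator produces a complete artificial region so
the whole chain is testable end to end without any external download.

## Pedotransfer: from soil evaluation to nFK

The reference table (`nfk_reference()`) assigns one of seven nFK classes
{50, 90, 140, 200, 250, 270, 300} mm to each soil type and soil-number
interval. Interval predicates are lower-exclusive/upper-inclusive: a soil
number equal to a printed upper bound belongs to that interval, and the
top interval of every type is open-ended upward (sandy loam's final
interval is `>92`, like the parallel rows of the other types).

Continuous estimates come from least-squares polynomials through anchor
points placed at the interval midpoints; the open-ended top interval is
anchored at its lower bound plus half the width of the preceding interval
(`fit_nfk_curve()`). Midpoints are the unbiased representative of an
interval when nothing further is known about the within-interval
distribution of soil numbers.

The polynomial degree is chosen adaptively: the smallest degree (up to 4)
whose fit reproduces *every* anchor within 5 mm. This matters because the
class spacing is far from linear — for the narrow-span sands degree 2
suffices, while loam, with seven classes over a 50–300 mm span, needs
degree 4; a global cap at degree 2 would leave anchor residuals of 7–9 mm
for the loamy types, which is more than a tenth of a class step.
Monotonicity is physically required (more quality never means less water
storage), so if a raw fit dips anywhere on the integer soil-number grid it
is repaired by isotonic projection onto non-decreasing values. Evaluation
is clamped: outside the anchor domain the curve holds its end values, and
estimates are always confined to the type's class range, reaching exactly
`nfk_min` at soil number 1 and `nfk_max` at 100.

Non-integer soil numbers are floored (with a warning) — the quality index
is integer-valued by convention.

## Climate preparation

`aggregate_daily_to_monthly()` averages temperatures and carries
precipitation **both** as the monthly total and as the daily mean. "Monthly
mean values" is ambiguous for rain; the water balance of the engine needs
totals, so `precip_sum` is what downstream code consumes, but the daily
mean is emitted alongside so either convention is recoverable from the
output. Months missing more than 5 days are flagged (a quality gate, not
fatal); empty months are simply absent. The long-term normal window
defaults to 1981–2010 but is an argument.

Climate regions are discrete: each region has exactly one representative
station. Because the package works in planar coordinates (no GIS stack is
required), region extents are rectangles with a nearest-centroid fallback;
units carrying an explicit region id keep it.

## The surrogate crop engine

The engine (`simulate_yield()`) is deliberately transparent: a monthly
bucket model, and it is labelled a surrogate — a stand-in with a stable
interface, not a reimplementation of any published crop model. Per season
month:

- the soil water store `W` (capacity nFK, starting full) is refilled by the
  month's precipitation and capped at capacity;
- demand is `kc × 5.5 mm/°C × max(0, T)`, a temperature-linear
  evapotranspiration proxy (5.5 mm per month per degree puts July demand
  near 100 mm, a typical mid-latitude reference value);
- the growth increment is `G_max × f_T × min(1, W/demand)`, where `f_T`
  rises piecewise-linearly from 0 at `T_base` to 1 at `T_opt`;
- yield is the harvest index times the summed increments, capped at a
  generous crop ceiling.

Parameters per crop (YAML files under `inst/extdata/crops/`):

| crop | season | G_max (t DM/ha/mo) | T_base (°C) | T_opt (°C) | kc | HI |
|---|---|---|---|---|---|---|
| maize | May–Sep | 6.0 | 8 | 16 | 1.10 | 1.0 |
| winter wheat | Oct–Jul | 4.8 | 3 | 15 | 0.90 | 1.0 |
| triticale | Oct–Jun | 6.3 | 3 | 15 | 0.85 | 1.0 |
| cup plant | Apr–Sep | 4.9 | 5 | 16 | 1.15 | 1.0 |

Harvest indices are 1.0 because all four crops are harvested whole-plant
for biogas; winter-wheat grain is obtained downstream by the unit
conversion, not by the engine. Winter crops span the year boundary: the
harvest year indexes the season, so "wheat 1995" consumes October–December
1994 and January–July 1995. The growth rates were calibrated **once**
against the synthetic region so that region-scale adjusted means land in
realistic bands (maize 12–19, triticale 14–17, cup plant 12–19 t DM/ha)
and the qualitative structure is right: the C4 crop leads under warm,
watered conditions; the early-maturing winter cereal, which exploits
winter soil moisture, shows the flattest response across nFK classes; the
water-demanding perennial suffers most on sand.

What the engine does *not* model: radiation, CO₂ response, phenology by
thermal time, nutrients, pests, water-logging. Its contract is monotone,
saturating water response and deterministic arithmetic — the properties the
tests pin down — not physiological fidelity.

The aggregation grid (`build_data_units()`) defaults to 35 (type, class)
pairs × 5 regions = 175 units. Which 3–5 classes per type compose the
canonical 35 is not recorded anywhere, so the default — all classes for S,
Sl, lS, LC; the five highest for SL, sL, L; the three highest for C — is a
documented, configurable guess.

## Unit conversions and the breeding trend

Model output is t dry matter/ha; harvest statistics are dt fresh mass/ha
(silage maize, assuming 35% dry-matter content) or dt grain/ha (winter
wheat, via the affine whole-plant-to-grain regression
`grain = (DM × 10 + 51.377)/2.5188`). The grain regression has a positive
intercept, so it is restricted to a 4–30 t DM/ha validity window — below
that the intercept dominates and the conversion is meaningless.

Observed winter-wheat statistics embed breeding progress; a model
calibrated on recent varieties does not. `breeding_trend_deduct()` fits an
OLS line to the observed yields over the pre-pivot years (default pivot
2000, after which no significant gains are assumed) and subtracts
`slope × (pivot − year)` from pre-pivot predictions. The regression window
is deliberately the pre-pivot years: the trend exists only there, and
fitting across the full series would dilute the slope with the flat
post-pivot regime. Maize yields stagnate over the period, so maize gets no
deduction by default.

## Calibration and validation

The adjustment factor is `mean(observed)/mean(predicted)` — regional
practice yields run well below trial-calibrated potential (up to 30%), and
this single multiplicative factor absorbs the gap. With the full-precision
factor, `mean(adjusted) = mean(observed)` holds as an algebraic identity;
with a two-decimal reported factor the residual is exactly
`mean(predicted) × (rounding delta)` — both are asserted in the tests.
`build_validation_report()` supports a fixed externally-given factor as
well as the computed one, because reported tables are typically printed
with the rounded factor.

Error statistics: RMSE, the overall percent error `100 × RMSE / mean(obs)`,
Pearson correlation (affine-invariant, so identical before and after
adjustment) and Willmott's 1981 index of agreement
`d = 1 − Σ(Pᵢ−Oᵢ)² / Σ(|Pᵢ−Ō|+|Oᵢ−Ō|)²`. The basis for RMSE and d —
observed vs adjusted (default) or vs raw predictions — is configurable,
since reported values do not always say which was used. Comparison
pre-filters mirror actual cropping: winter cereals only on units with
nFK > 90 mm, maize everywhere above 40 mm (`validation_filter_rules()`).

Reporting precision follows the conventions of printed harvest statistics:
yields and RMSE to one decimal, factors, r and d to two.

## Potential mapping

Unit yields are averaged over a climate period (default 1991–2007, the
recent, warmer half of the record; the period is an argument since the
first year of such windows is often quoted inconsistently). Per crop ×
soil type × region, a least-squares polynomial of degree ≤ 2 maps nFK
class → mean yield; these are pure interpolation curves, evaluated clamped
to their fitted nFK domain so no extrapolated or negative potential can
occur (values are additionally floored at zero). Degree 2 captures the
observed single-bend shape: strong gains over the first 50 mm of
additional storage, declining gains after.

`join_potentials()` transfers curves onto every soil-map record via its
continuous nFK estimate, optionally multiplies by per-crop adjustment
factors, and classifies into half-open, lower-inclusive yield bands
(default edges 12, 14, 16, 17, 19 t DM/ha, the ranges in which regional
potentials are typically discussed). Cardinality is conserved exactly; a
record that cannot be resolved (unknown type, no curve) keeps its row with
an `NA` potential and a reason code, and strict mode aborts above 10%
unresolvable.

## The synthetic region

The generator emulates the statistical structure the analysis assumes,
not a real landscape:

- **Soil map**: units uniform over a 100 × 100 area; north of the midline
  the texture mixture is dominated by sands (S/Sl/lS), south of it by
  loams (sL/L/LC); soil numbers are drawn per type within realistic
  quality spans. This produces the north–south nFK gradient that the
  mapped potentials must reproduce.
- **Climate**: five stations, daily records from one spin-up year before
  the first harvest year through 2007. Temperatures are monthly normals of
  a temperate maritime lowland plus N(0, 2.5 °C) daily noise and a small
  fixed station offset; precipitation is an intermittent gamma process
  (wet-day probability 0.5, shape 0.8) whose monthly expectations equal
  the normals — May 56 mm, June 65 mm, July 67 mm.
- **Observed statistics**: `observed = (gap × predicted_regional_mean −
  trend) × lognormal noise`, with defaults gap 0.75 (inside the "up to
  30% below trials" range), trend 0.9 dt/ha/yr before 2000 for the
  winter-cereal analogue, and noise CV 0.07 (the year-to-year scatter of
  real regional series). The noise is multiplicative lognormal with mean
  one: yields are positive and right-skewed.

All generators are pure functions of `(config, seed)`; the tests assert
bit-identical replay. What the generator does **not** emulate — spatially
correlated weather, radiation, real geomorphology, reporting artefacts in
statistics — bounds what passing tests show: they demonstrate that the
pipeline recovers parameters *it itself planted* under its own noise
model, not that the engine predicts real yields.

## Problem sizes and numerical choices

The shipped tests run the full 175-unit grid over all 27 years and four
crops (the complete aggregation, about two seconds) but keep the soil map
at 600 records; the full-scale 114,357-record map is a configuration
choice (`synthetic_config(n_units = 114357)`) and changes only the join
stage, which is linear in records. Parameter-recovery checks use 30 seeds
for the gap factor and 8 for the trend slope.

Other fixed numerical choices: anchor tolerance 5 mm (a tenth of the
smallest class step); engine determinism is exact (no stochastic terms);
curve evaluation uses piecewise-linear interpolation of the (possibly
isotonically repaired) integer-grid values, which keeps monotonicity
guarantees trivial at a worst-case interpolation error far below the
anchor tolerance; band edges are half-open lower-inclusive so every value
has exactly one band.

## Known limitations

- The engine is a surrogate; absolute potentials inherit its one-time
  calibration and should be read as relative surfaces.
- One station per climate region ignores within-region climate gradients.
- Homogeneous soil profiles: no horizons, no groundwater influence.
- The reported wheat comparison series contains adjusted values
  (2000–2006) that are not reproducible as `predicted × factor`; the
  package reproduces the stated definition and documents the discrepancy
  rather than emulating it.
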