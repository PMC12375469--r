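---
title: "Water-driven potato simulation: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Water-driven potato simulation: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(potatosim)
```

`potatosim` is a daily, water-driven simulation of a potato season in the
AquaCrop tradition: the crop's transpiration, normalized by reference
evapotranspiration, drives biomass; a harvest index converts biomass to
tuber yield; and every water flux is tracked through a discretized soil
profile so that deficit-irrigation policies can be compared on yield and
crop water productivity (WPc) across multi-year weather scenarios.  This
vignette explains the model equations, the parameters that matter, what
the synthetic weather generator does and does not emulate, and the design
decisions taken where the problem was genuinely open.

## The water balance

The profile is a stack of 0.05 m compartments whose hydraulic constants
(saturation, field capacity `θ_fc`, wilting point `θ_wp`, air-dry =
`θ_wp / 2`) come from a texture-class pedotransfer lookup: sandy loam
0.41 / 0.22 / 0.10, loamy sand 0.38 / 0.16 / 0.08 (m³ m⁻³).  The two
packaged site profiles carry measured textures and bulk densities but no
measured water-retention data, so the class values are used and kept
editable via the layer table.  Profiles are discretized to 0.60 m so they
cover the 0.47 m maximum root depth.

Each day applies, in order:

1. **Infiltration** of rain plus irrigation, filling compartments to
   saturation top-down; inflow beyond total pore space leaves as
   saturation-excess runoff.  No curve-number runoff is modelled — the
   sandy sites give no basis for one.
2. **Cascade drainage**: each compartment releases a fraction
   `τ = 0.5 d⁻¹` of its water above field capacity into the compartment
   below (sandy soils drain fast; `τ` is a profile argument); bottom
   outflow is deep drainage.  Capillary rise is zero — the water table at
   the sites lies far below the root zone.
3. **Soil evaporation** from the top 0.05 m, floored at air-dry.  The
   evaporating skin is deliberately thin: it holds ~8.5 mm of readily
   evaporable water for the sandy loam, in line with the conventional
   thin-surface-layer treatment.  A thicker layer lets evaporation alone
   push the shallow emergence-stage root zone past the senescence
   threshold — an artifact, not crop physiology.
4. **Transpiration extraction** from four equal root-zone quarters with
   the 40–30–20–10 weighting, floored at wilting point.  Unmet quarter
   demand is *not* redistributed to wetter quarters; realized
   transpiration simply falls short.

Storage change closes against the fluxes to ≤ 1 × 10⁻⁹ mm every day; this
is asserted on every traced simulation in the test suite.

Root-zone stored water is reported as
`Wr = 1000 · θ̄ · Zr · (1 − gravel/100)` mm with `θ̄` the
thickness-weighted mean over the rooting depth.

## The crop

Thermal time is `GDD = max(0, min((Tmax + Tmin)/2, 26) − 2)` °C·d.
Canopy cover (CC, %) grows from `CC₀ = 0.6 %` at emergence as
`CC₀·e^{CGC·τ}` until half of `CCₓ = 92 %`, then approaches `CCₓ` as
`CCₓ − 0.25·CCₓ²/CC₀·e^{−CGC·τ}`.  **Units of CGC/CDC:** the calibrated
values (1.80, 0.80 % day⁻¹) cannot close the canopy inside the observed
phenology if read per calendar day; both are therefore interpreted as
fractional rates per growing degree day (0.018, 0.008 GDD⁻¹), which
closes the canopy three to four weeks after emergence, consistent with
tuber initiation at 43 days after planting (DAP).  Both remain arguments
of `crop_params()`.

Water stress acts through `Ks = 1 − (e^{D·s} − 1)/(e^{s} − 1)` on the
relative depletion `D` of plant-available water, with shape `s = 3` and
process-specific thresholds: canopy expansion 0.26–0.66, stomatal closure
0.65–1, early senescence 0.69–1.  Expansion stress scales the day's
canopy increment; stomatal stress scales transpiration demand
`Ks·KcTr·CC*·ET₀` (with the micro-advection adjustment
`CC* = 1.72c − c² + 0.3c³`); depletion at or beyond the senescence
threshold for five consecutive days latches the canopy into its decline
curve `CC_sen·[1 − 0.05(e^{rate·τ_s} − 1)]`, `rate = CDC/(CC_sen/100)`.
The latch is one-way: a crop forced into senescence does not regrow when
rain returns, which makes prolonged drought unambiguously terminal and is
the main reason rainfed yields collapse on these low-retention sands.
Vine kill at DAP 112 forces cover to zero within three days.

Roots deepen from 0.15 m at emergence (a conventional planting-depth
value; not site-measured) to 0.47 m at mid-tuber bulking along a power
curve with exponent 1.5.  Biomass accumulates as `ΔB = WP·Tr/ET₀` with
`WP = 19 g m⁻²`; yield is `Y = f_HI·HI·B` with the harvest index building
linearly from 0 at tuber initiation (DAP 43) to `HI₀ = 0.75` at vine
kill.  The stress multiplier `f_HI` and the cold-stress coefficient are
fixed at 1: no calibrated values exist for them, and fixing them keeps
the yield equation exact and testable.  Yields are on the model's
dry-matter scale; `yield_fresh_t_ha` divides by a 0.20 dry-matter
fraction for comparison with field-style numbers.  All internal
comparisons and trade-off ratios are scale-invariant to this choice.

## Irrigation policies

A threshold policy irrigates 15.24 mm (one dose per day at most,
minimum-interval respected) when the root zone holds less than the
threshold fraction of its plant-available water, i.e. when
`θ̄ < θ_wp + f·(θ_fc − θ_wp)`.  We read "irrigate at f % of field
capacity" as a fraction of *available* water rather than of `θ_fc`
itself: on these soils `θ_wp/θ_fc` is 0.45–0.50, so a literal `θ̄/θ_fc`
trigger below ~50 % can never fire (transpiration stops at wilting
point), which would collapse the 20–50 % policies — including the 50 %
control that field practice actually irrigates — onto rainfed.  The
available-water reading keeps all eight thresholds operative and
reproduces the expected monotone rise of event counts from 20 % to 90 %.
The trigger is evaluated after the day's rain has infiltrated, so rain
days do not double-count.

`fixed` mode replays a prescribed schedule (used to mirror the field
experiment's 3 × 16 mm and 5 × 16 mm treatments), `rainfed` never
irrigates, and `full` refills every root-zone compartment to field
capacity daily plus the day's potential surface evaporation — a
net-irrigation-requirement schedule that provably satisfies transpiration
demand every day and anchors the dominance property (full irrigation
yields at least as much as any deficit policy).  A discrete-dose 95 %
threshold policy does not have that guarantee: between events the dry
surface quarter can cap realized transpiration, and event timing can then
let an 80–90 % policy edge it by a fraction of a percent.

## Synthetic weather

`season_spec()`/`synthesize_season()` generate a 135-day season (planting
10 May, latitude 43.35°, elevation 290 m): rainfall occurrence from a
first-order two-state chain (P(wet|dry) = 0.25, P(wet|wet) = 0.55),
wet-day amounts from a gamma distribution (shape 0.8, scale 6 mm), then a
multiplicative rescale so the season total equals the target *exactly* —
season class is therefore a controlled input.  Temperatures follow an
annual cosine peaking at day-of-year 220 (the late-tuber-bulk window)
whose baseline is calibrated per season window so the deterministic
season means equal the targets (25.7 / 12.9 °C) exactly, plus ±1.5 °C
uniform noise.  Humidity, wind (2 m) and solar radiation are bounded
noise around humid-temperate values, wetter and dimmer on rain days;
ET₀ is FAO-56 Penman–Monteith (grass reference, daily soil heat flux 0,
net longwave from the clear-sky ratio, result clipped at 0).  Station
wind measured at 3 m can be converted with `wind_to_2m()` (logarithmic
profile, factor 0.921).

What the generator does *not* emulate: multi-day synoptic persistence
beyond the first-order chain, heat waves correlated with dry spells,
within-season trends, or any spatial structure.  Passing scenario tests
therefore demonstrate the *machinery* (classification, grid, trade-off,
correlations) under controlled rainfall totals, not a reproduction of any
particular historical decade; absolute yields and WPc under real station
records will differ.

## Scenario analysis

Seasons classify as wet / normal / dry by a ±10 % band around the
284.5 mm long-term season mean (boundaries 312.95 and 256.05 mm, printed
as 312.9 and 256 at truncated precision; the band boundaries themselves
are "normal").  `run_grid()` simulates every (year × soil × policy)
combination plus rainfed and sorts deterministically.  Trade-offs use the
log response ratio `ln(x_i/x_c)` of *group-mean* yield and WPc against
the 50 %-FC control — one point per treatment per group, matching
single-point quadrant plots — with ties (LnRR exactly 0) assigned to the
"win" half so the control reads as the origin reference.  WPc is
`yield / (10·(rain + irrigation))` kg m⁻³ on the dry-matter yield scale.

The stage-correlation heat map needs a definition of what is correlated;
the source material leaves it ambiguous.  We correlate, per policy and
developmental stage, the irrigation depth applied within the stage window
against seasonal yield, across years (Pearson's r; cells with zero
variance, such as rainfed, are flagged undefined).  This is an
interpretation, recorded here deliberately: other readings (e.g. rainfall
instead of irrigation) are possible.

## Evaluation metrics

`compute_metrics()` implements RMSE, MBE, the index of agreement and
Nash–Sutcliffe efficiency.  With one pair, or a constant measured series,
the IA/NSE denominators vanish; these are returned as `NA` with a reason
rather than any imputed value — published skill scores quoted for single
simulated values cannot be reproduced from the printed information and
are not targeted.  Composite available water (CAW), plotted but never
defined in the source material, is taken as water above wilting point
summed over the three monitored 0.15 m sensor intervals.

## Numerical choices and degenerate inputs

Mass closure is enforced by construction and tested at 1 × 10⁻⁹ mm.
Extraction weights must sum to 1 within 1 × 10⁻⁹.  A rainfall target > 0
with an all-dry draw is retried up to 10 fresh draws (deterministically,
within the seeded stream) and then fails.  `lnrr()` refuses non-positive
inputs; `crop_water_productivity()` refuses zero total water; zero-ET₀
days with positive transpiration skip the biomass increment with a
warning.  Seeded generation saves and restores the caller's RNG state, so
identical specs give bitwise-identical series regardless of surrounding
code.

## Problem sizes used in the tests

The property suite runs 20 seeded full seasons for closure, 20 seasons ×
2 soils × 9 policies for the monotonicity/dominance sweep, a 11-year
synthetic decade (4 wet / 4 normal / 3 dry targets) × 9 policies ×
2 soils for the trade-off reproduction, and 1,000 random series for the
metric identities — sizes chosen to exercise every code path across both
packaged soils while keeping a full check of the package interactive.

## Known limitations

Absolute yield and soil-water magnitudes are not calibrated against any
field record: the hydraulic constants are class values, the senescence
latch is irreversible, fertility, salinity, pests, CO₂ response and
cold stress are out of scope, and the prescribed calendar means phenology
does not respond to temperature.  The package is a scenario-comparison
engine: differences *between* policies under identical weather are the
quantity of interest, not any individual season's absolute output.
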