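---
title: "Cropland change and national yield potential: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cropland change and national yield potential: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cropshift)
```

## The question

Urbanization converts cropland near cities to other uses while crop area
expands elsewhere, often at agricultural frontiers with different soils and
climate. Whether a country's capacity to produce a staple crop rises or falls
under this exchange depends on the *annual yield potential* of the land lost
versus the land gained — yield potential, not current farm yield, because
current yields confound land quality with management and input access. The
headline statistic is the national yield ratio

$$
R \;=\; \frac{\bar{Y}_{\mathrm{contracting}}}{\bar{Y}_{\mathrm{expanding}}},
$$

the area-change-weighted national annual yield potential of contracting
(converted) cropland divided by that of expanding (new) cropland. $R > 1$
means each hectare lost must be replaced by more than one hectare of new
land. Yield stability is summarised by the inter-annual coefficient of
variation of annual yield potential.

`cropshift` implements the full chain on synthetic landscapes: landscape
generation, agro-climatic zonation, a weather-station buffer framework with
sequential site selection, daily crop simulation, epoch-based change
detection, and two-stage spatial upscaling.

## Pipeline anatomy

`run_pipeline()` wires the stages together; each stage is also exported on
its own.

1. **Synthetic landscape** (`generate_area_grids()`): an equal-area lattice
   (10 × 10 km cells, 0-based row-major indexing, row 0 = north) carrying
   harvested hectares per cell, for two 3-year epochs a decade apart.
   Contraction is an exponential kernel around urban centers
   (`contraction_kernel()`, support truncated at three decay radii,
   normalised to the configured total loss); expansion is a uniform gain over
   a frontier region. Within an epoch, years differ only by small
   multiplicative noise, which the 3-year epoch means damp by design.
2. **Climate zonation** (`climate_metrics_grid()`, `delimit_zones()`): three
   metrics per cell — growing degree days (base 0 °C, cap 30 °C),
   temperature seasonality (population SD of the 12 climatological monthly
   means), and the aridity index (annual precipitation / annual Hargreaves
   PET). Cells sharing a bin triple share a zone; zone ids follow the
   lexicographic order of occupied triples, so labels depend only on the
   metric values.
3. **Buffer framework** (`make_clipped_buffer()`, `select_buffers()`):
   100-km discs around stations, clipped to the station's climate zone.
   Selection is greedy by harvested area, accepting a buffer only if it
   holds > 1% of national harvested area and overlaps every accepted buffer
   by < 20%, stopping at 50% national coverage (unique cells).
4. **Crop simulation** (`simulate_season()`, `site_yield_potential()`): a
   simplified daily model (below) run over 10–15 weather years for every
   soil × crop-sequence combination, averaged with their area shares.
5. **Change detection** (`net_change()`, `classify_change()`,
   `flag_significant()`): per-cell epoch-2 minus epoch-1 means; cells with
   ≥ 50 ha cropland are displayed and classified at the ±250 ha per-cell
   threshold; buffers are flagged at a decadal net balance beyond 15 000 ha
   (rice) or 10 000 ha (maize). All comparisons are strict, so values exactly
   at a threshold classify as "none".
6. **Upscaling and report** (`cz_weighted_yield()`,
   `national_weighted_yield()`, `build_report()`): within each zone, sites
   are weighted by the absolute net balance of their buffers; across zones,
   by national area shares renormalised over the zones present on each side.
   The same two-stage weights aggregate crop intensity, irrigation
   proportion and CV.

## The crop model

The simulator is a deliberate simplification in the radiation-use-efficiency
tradition, not a re-implementation of the specialised models used for
national assessments. Its job is to produce yield-potential surfaces with the
right *qualitative* structure — crop-intensity effects, water limitation,
inter-annual variance — for exercising the spatial machinery.

Daily, from sowing:

* **Phenology**: thermal time $\sum \max(0, T - T_b)$ advances to the
  cultivar's `gdd_to_maturity` (the single genotype parameter that dominates
  yield-potential simulation).
* **Canopy**: LAI follows a logistic rise in thermal-time fraction $f$,
  $L = L_{\max} / (1 + e^{-12(f - 0.3)})$, intercepted by Beer's law with
  extinction coefficient 0.5; there is no senescence phase, a documented
  simplification.
* **Growth**: $\Delta B = \mathrm{RUE} \cdot f_{\mathrm{PAR}} \cdot
  (0.5\,S) \cdot f_T \cdot f_W$ with $S$ global radiation (PAR taken as half,
  the conventional constant) and $f_T$ a trapezoid (0 at $T_b$, 1 between
  `t_opt_lo` and `t_opt_hi`, 0 at `t_lethal`).
* **Water**: irrigated crops have $f_W = 1$. Rainfed crops draw on a
  single-layer bucket of capacity equal to the soil's plant-available water:
  rain in, overflow beyond capacity out, crop demand
  $f_{\mathrm{PAR}} \cdot \mathrm{PET}$ supplied at up to 10% of current
  storage per day ($f_W$ = supply/demand, capped at 1), plus bare-soil
  evaporation $0.5 (1 - f_{\mathrm{PAR}}) \mathrm{PET}$. The budget closes
  exactly by construction and storage stays in $[0, \mathrm{PAW}]$ — both
  are asserted over a thousand random scenarios in the test suite.
* **Yield**: biomass × harvest index, converted to commercial moisture
  (15.5% maize, 14% rice).

Sequences with two or three crops per year sum their season yields into an
annual yield potential, carrying soil water between seasons through a fallow
spin-up (bucket with evaporation only). Soil water at sowing can also be a
fixed fraction of capacity.

Useful exact properties follow from this structure and anchor the tests:
irrigated yield dominates rainfed yield; rainfed yield is monotone in
water-holding capacity; unstressed biomass is exactly linear in RUE; with a
forced-full canopy and on-optimum temperatures the season yield has the
closed form $\mathrm{HI} \cdot \mathrm{RUE} \cdot \sum 0.5 S / (1 - m)$.

Default cultivars (rice: 1600 °C-days above 8 °C, RUE 2.2 g/MJ, HI 0.45;
maize: 1500 °C-days above 10 °C, RUE 3.2 g/MJ, HI 0.50) are synthetic but
sit in the agronomically plausible range; base temperatures are the common
defaults for the two crops and every parameter is overridable.

## The synthetic landscape: what it emulates, what it does not

The generator reproduces the *structure* the analysis needs: urban-adjacent
loss with a documented, integrable kernel; frontier gain; smooth
north–south climate gradients (temperature, rainfall, latitude for solar
geometry); station networks thinned toward high-area cells; 2–3 soils per
buffer with shares summing to one; warmer zones double-cropped (default mix
0.7 double + 0.3 single, crop intensity 1.7).

It does not emulate: spatially correlated weather between nearby stations
(each station's series is independent); daily temperature stochasticity
(temperature varies by season and year, not day to day); realistic rainfall
depth distributions (all rain days in a year share one depth chosen so the
expected annual total matches the configured value); land-cover classes
other than the target crop; or any calibration to observed area-change
magnitudes, for which no statistical description was available. Passing
tests therefore demonstrate that the machinery is correct and internally
consistent, not that the generator's landscapes are distributionally
realistic.

Rain-day occurrence is Bernoulli per day; year-level factors with SD
`interannual_sd` scale rainfall and radiation and shift temperature
(4 °C of offset per unit of the fraction). Setting `interannual_sd = 0`
with every day a rain day makes all years identical, a property the tests
use as a degenerate-variance check.

## Numerical and design choices

Open choices were settled once, as follows:

* **Overlap denominator**: the overlap rule is stated as "< 20%" without a
  denominator; we use the cell count of the candidate under test —
  the stricter, order-consistent reading (a small candidate swallowed by a
  big accepted buffer is rejected even though the union-relative overlap
  would be small).
* **"Approximately half" coverage**: implemented as the first crossing of
  exactly 0.50, for determinism. Ties in the area ordering break by station
  id ascending.
* **Display mask epoch**: the ≥ 50 ha cropland mask is evaluated on the
  epoch-1 mean (the pre-conversion map); documented and configurable.
* **Zone shares**: national area shares per climate zone come from the
  epoch-1 grid — the converted side's weights logically predate conversion.
* **Renormalisation within side**: each side of the comparison rarely
  touches every zone, so zone shares are renormalised over the zones present
  on that side (required for a weighted mean).
* **Aggregating intensity/irrigation/CV**: the same absolute-balance and
  share weights as yields; the source tables do not state their weighting,
  and this keeps all columns of the report consistent.
* **Strict thresholds**: every classification threshold (±250 ha cell
  change, 15 000 / 10 000 ha buffer significance, > 1% buffer share,
  > 5% zone share) is a strict inequality; boundary values do not qualify.
* **Seasonality SD**: population (n) SD over the 12 climatological monthly
  means — a fixed-size set of descriptive statistics, not a sample.
* **Stability CV**: sample (n−1) SD, because the yearly series are short
  (10–15 years).
* **PET**: Hargreaves–Samani, chosen for minimal data needs (temperature
  plus solar geometry); the station latitude maps linearly from the grid
  row.
* **Seeding**: one master seed fans out through a multiplicative string
  hash (`child_seed()`) to per-component seeds, so regenerating one
  component never perturbs another, and every result is reproducible
  byte-for-byte.

Two pipeline-level steps sit outside the core selection rule, mirroring how
national assessments in this tradition handle sparse station networks: if
weighted sampling leaves a change region without a station, one is placed at
the region's highest-|change| cell (`ensure_region_stations`); and after the
coverage-based selection, candidate buffers whose net balance is significant
are appended so that flagged change regions are always represented
(`include_flagged`). These additions are tagged in the selection trace
(`significant_net_balance`) and are exempt from the pairwise-overlap
guarantee, which continues to hold among sequentially selected buffers. Both
steps can be switched off.

Cultivar and sequence overrides (`expansion_cultivar`,
`contraction_sequences`, `expansion_sequences`) key on a buffer's change
flag: sites on expanding cropland may grow different genotypes or systems
than sites on contracting cropland. Because unstressed yield is linear in
RUE, scaling the expansion-side RUE by $1/k$ engineers a landscape whose
expected national yield ratio is exactly $k$ — the package's end-to-end
parameter-recovery check (it recovers $k = 1.3$ within 5% averaged over 20
seeds). Giving the contracting side two crops per year and the expanding
side one, under a constant climate where a season yields the same whenever
it is sown, recovers a ratio of ≈ 2 — the crop-intensity effect that, if
ignored, can reverse the conclusion about which side is more productive.

## Problem sizes and degenerate inputs

The test and demonstration configurations use 24 × 24 to 30 × 30 grids,
6–8 stations, 8–10 weather years, and two soils per buffer — small enough to
iterate comfortably, large enough that selection, clipping, flagging and
both weighting stages are all non-trivially exercised. The property suites
run 1000 random simulator scenarios and 50 random selection problems against
independent oracles.

Degenerate inputs are defined, not accidental: an empty candidate list
selects nothing with zero coverage; a landscape without change produces a
report with the ratio explicitly flagged undefined rather than an error; a
season that cannot reach maturity before the weather ends is flagged
incomplete and its yield-to-date reported with a warning (cool-margin sites
can genuinely fail to ripen a second crop).

## Limitations

The crop model omits senescence, cold sterility, flooding and submergence,
pests, diseases and nutrient limitation; the last three are standard
yield-potential assumptions, while the first three mean the model is *more*
optimistic about marginal environments (cold northern frontiers, tidal
lowlands) than specialised models would be — so engineered yield contrasts
here are conservative relative to what those processes would add. Buffers
are Euclidean discs on an equal-area lattice, not geodesic; grids are
abstract, with georeferencing treated as metadata and CSV as the
interchange format. The generator's change magnitudes are plausible rather
than calibrated. None of these affect the algebra of zonation, selection,
change detection or weighting, which is what the package is for.
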