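# pape — personal air pollution exposure from wearable body sensor networks

Fixed monitoring stations measure the air of a city block, not the air a
person actually breathes. `pape` implements a pipeline for estimating
**personal air pollution exposure (PAPE)** — the inhaled pollutant dose — from
a wearable body sensor network (BSN): an environmental monitor sampling
PM1/PM2.5/PM10, CO₂, tVOC, CO and NO₂ every 24 s alongside GPS, plus
physiological nodes streaming pulse rate (PR) and respiratory rate (RR) at
10 Hz. It is written for exposure scientists and biomedical engineers who
want to compare such personalized dose estimates against the conventional
fixed-station approach.

## The model

The dose over a period *p* is

> PAPE(p) = SZ(p) · V′m,  with  SZ(p) = Σᵢ ½ (Z(tᵢ₊₁) + Z(tᵢ)) (tᵢ₊₁ − tᵢ)

the trapezoidal time integral of the pollutant concentration Z (valid only
while consecutive samples are less than 10 min apart), and V′m the minute
ventilation converted from L/min to m³/min. Ventilation is personalized
through a power model driven by the wearables,

> V′m = e⁻⁸·⁷⁵ · HR¹·⁷² · RR⁰·⁶¹¹ · age⁰·²⁹⁸ · sex⁻⁰·²⁰⁶ · FVC⁰·⁶¹⁴

with pulse rate standing in for heart rate, sex coded 1 (men) / 2 (women)
and FVC the forced vital capacity in litres. The comparator **Standard
Method** instead multiplies a fixed station's daily concentration by a
sex/activity tabulated ventilation (activity level 3: 15.14 L/min men,
13.26 L/min women) over the same exposure time.

The pipeline stages are: seeded synthetic-session generation (no raw study
recordings are public) → 1 Hz resampling and timestamp segmentation into 7
static + 7 dynamic microenvironment arrays, length-normalized at 3 samples
per minute → node-wise ventilation modelling → per-segment and session doses
for both methods → paired and nonparametric comparison statistics.

## Worked example

The packaged 20-participant PM2.5 dose table (one row per participant:
modelled vs tabulated ventilation, personal vs fixed-station concentration,
and both dose estimates) reproduces the headline comparison:

```r
library(pape)
rt <- reproduce_dose_table()
rt$comparison
#> Paired dose comparison over 20 participants
#>   Standard Method : mean 13.31 (SD 4.16) ug
#>   Wearable system : mean 16.27 (SD 9.78) ug
#>   Mean difference (new - std): 2.96 ug (22.2% of standard mean)
#>   95% CI (std - new): -6.55 to 0.63  [mirrored: -0.63 to 6.55]
#>   Paired t = -1.725, p = 0.1007
#>   Pearson r = 0.665, p = 0.0014
rt$max_abs_dev
#> [1] 0
```

The Standard Method *underestimates* the wearable-derived dose by 2.96 μg on
average (22% of its own mean) while the two methods remain strongly
correlated (r = 0.665) — and every Standard-Method dose in the table is
recovered exactly (`max_abs_dev = 0`) from its closed form
`C_std × V′m/1000 × 35 min`.

A fully synthetic cohort runs end to end in one call:

```r
res <- run_pipeline(run_config(
  standard_inputs = standard_inputs(c(pm2_5 = 28), 15.14),
  n_participants = 20, seed = 42))
res$comparison
```

The numbered scripts under `analysis/` (`01_simulate.R` … `05_compare.R`)
walk the same pipeline stage by stage, writing streams, segments,
ventilation series, dose tables, a GeoJSON track and the statistical
reports under `results/`.

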