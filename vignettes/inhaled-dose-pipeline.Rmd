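---
title: "Estimating inhaled pollutant dose from wearable sensor streams"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating inhaled pollutant dose from wearable sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pape)
```

## The problem and the model

Exposure assessment from fixed monitoring stations assigns every resident of
an area the same concentration, and tabulated breathing rates assign every
person of the same sex and activity level the same ventilation. A body
sensor network (BSN) — a wearable environmental monitor plus pulse-oximeter
and respiratory-rate nodes — measures both factors where they matter: at the
person. This package implements the full chain from such multi-rate streams
to an inhaled dose, together with the conventional comparator.

The dose over a period $p$ is

$$\mathrm{PAPE}(p) = SZ(p)\cdot V'_m, \qquad
SZ(p) = \sum_i \tfrac12\,(Z_{t_{i+1}} + Z_{t_i})\,(t_{i+1}-t_i),$$

a trapezoidal time integral of the concentration $Z$ multiplied by minute
ventilation converted from L/min to m$^3$/min. The trapezoid is only a
sensible exposure approximation while samples are close together, so
`aggregate_sz()` refuses any sampling gap of 10 minutes or more — an error,
not a warning, because silently bridging such a gap fabricates exposure.

Ventilation is personalized with a published power model,

$$V'_m = e^{-8.75}\,\mathrm{HR}^{1.72}\,\mathrm{RR}^{0.611}\,
\mathrm{age}^{0.298}\,\mathrm{sex}^{-0.206}\,\mathrm{FVC}^{0.614},$$

with pulse rate used verbatim as the heart-rate proxy (no correction
factor), sex coded 1 for men and 2 for women, and FVC in litres. The model
is implemented exactly as the closed form; the test suite asserts exact
log-linearity in the five covariates and the forced $2^{-0.206}$ sex ratio.
The *Standard Method* comparator uses activity-level-3 tabulated values
(15.14 L/min for men, 13.26 L/min for women) and a fixed station's daily
concentration over the same 35 static minutes.

## Pipeline stages and their conventions

**Resampling.** Environmental records arrive every 24 s and are linearly
interpolated to 1 Hz. The interpolation flavour is a design choice made
consistent with the later, explicitly linear, length normalization; the 1 Hz
grid starts at the stream's first timestamp, which makes resampling an
already-1 Hz series the identity.

**Segmentation.** Arrive/leave timestamps at the seven static acquisition
points A–G cut each channel into 7 static and 7 dynamic (walking) arrays.
Windows are half-open $[\mathrm{arrive}, \mathrm{leave})$ so adjacent
segments never double-count a sample: a 5-minute dwell at 1 Hz yields
exactly 300 samples.

**Length normalization.** Each segment is linearly interpolated onto
`round(duration_min × 3)` evenly spaced nodes *including both endpoints*
(15 nodes per 5-minute dwell). Whether the 3-per-minute grid should include
the endpoints is underdetermined; the endpoint-inclusive convention was
chosen so a segment's extremes survive normalization, and the tests check
that the trapezoidal integral of a smooth segment is conserved within 2%.
The 10 Hz physiological channels are block-averaged to 1 Hz first, then
follow the same segment/normalize path, giving a single downstream
representation for every channel.

**The environmental factor.** Within each static point the 15 nodes are
collapsed to five per-minute means. Integrating five values spaced one
minute apart with a bare trapezoid would cover only four minutes, so the
per-minute means are treated as a step function over the full dwell
(implemented as a trapezoid on a boundary-padded minute-centre grid). This
makes the constant-input reduction exact: constant concentration $c$ and
constant ventilation $v$ give a session total of exactly
$c\,(v/1000)\,35\,\mu g$ — the same closed form as the Standard Method. A
single 5-minute mean per point is available as an alternative
(`env_factor = "segment_mean"`), since the distinction between the two
readings of "a mean of the values acquired during 1 minute … for all 5
minutes" is genuinely ambiguous.

**Ventilation granularity.** By default $V'_m$ is evaluated at every
normalized node and the *product* $Z(t)V'_m(t)$ is integrated
(`ventilation = "integral"`), which degenerates to $SZ \cdot V'_m$ when
ventilation is constant; a per-segment-median mode exists for sensitivity
checks. The integral default was chosen because both streams genuinely vary
within a 5-minute dwell and aggregating them separately discards their
covariance.

**Session totals.** `id_new` sums the seven static-point doses of the dose
pollutant (PM2.5 by default). Dynamic segments carry no physiological data
in the underlying study design and are never mixed into the total. Gas-phase
doses keep gas units (ppm·m³ for CO₂, ppb·m³ for tVOC); converting them to
mass would require molar assumptions the pipeline does not make. CO and NO₂
are excluded from dose tables altogether: they sit below the 20 ppb
detection limit throughout.

## The synthetic-data generator

No raw study recordings are public, so the generator is a first-class,
tested module that emulates the study conditions: 20 participants at a 14:6
male:female ratio, ages centred near 25.5 y with occasional older outliers,
seven 5-minute static points joined by walking transits (a ~4.5 km loop,
~66 min), environmental records every 24 s, physiological streams at 10 Hz,
and morning/afternoon session slots.

Channel regimes default to the published per-point medians and IQRs: the
indoor point A has high CO₂ (median 1010.4 ppm) and tVOC and low PM, the six
outdoor points the reverse. Within a segment, values fluctuate as
first-order autoregressive lognormal noise around the configured median —
the study reports only medians and IQRs, so the AR(1) choice is a documented
stand-in with its correlation exposed in the configuration
(`ar_env`, `ar_physio`). The log-scale spread is matched to the configured
IQR by a small-sigma approximation; with `noise_scale = 0` every sample
equals its segment's median exactly, which several tests exploit. PM size
fractions share one fluctuation path scaled by the configured median ratios,
so PM1 ≤ PM2.5 ≤ PM10 holds at every record by construction. CO and NO₂ are
drawn at low levels and left-censored at the 20 ppb detection floor
(reported at the floor with a censored flag), matching a campaign in which
neither gas ever exceeded the limit. Afternoon sessions multiply PM and tVOC
medians up and shift CO₂ down — the directions found in the study; the
magnitudes are configuration, not claims. Between-participant variability
enters as a lognormal random level on RR and PR (`between_subject_sd`,
log-SD 0.12). GPS follows straight lines between waypoint coordinates.

What the generator does **not** emulate: sensor drift and calibration error,
atmospheric dispersion, gaps and dropouts in transmission, the IMU-to-RR
signal-processing chain (RR is generated directly as a stream), or real
spatial concentration fields. Tests passing on synthetic sessions therefore
validate the *pipeline arithmetic and statistics*, not the field accuracy of
any sensor.

## Statistical comparison

`compare_methods()` mirrors the published analysis: sample means and SDs
(n − 1), the mean difference oriented new − std with its percentage of the
Standard-Method mean, the paired $t$ 95% CI computed on the std − new
differences (the published orientation; the mirrored interval is also
returned to avoid sign confusion), and the Pearson correlation.
`location_battery()` bundles the nonparametric tests: Shapiro–Wilk per
point, Friedman across the seven points with participants as complete
blocks, pairwise Wilcoxon signed-rank post hocs under Bonferroni over all
$\binom{7}{2} = 21$ pairs (the post hoc family is unnamed in the source;
pairwise signed-rank with Bonferroni is this package's documented choice,
applied uniformly), a day-paired morning-vs-afternoon Wilcoxon signed-rank,
and Kruskal–Wallis for between-participant respiratory rate.

Calibration of this battery is tested at summary level:
`simulate_point_summaries()` draws participants × points matrices (the
battery's actual input) so that 1000 null replicates and 100
injected-effect replicates run in seconds. Under exchangeable points the
Friedman rejection rate must sit inside the binomial 95% band around
α = 0.05; under the configured indoor CO₂ regime the omnibus must reject
with every indoor-vs-outdoor post hoc surviving Bonferroni in ≥ 95% of
replicates.

## Numerical choices and degenerate inputs

* All internal computation is at full precision; 2-decimal rounding happens
  only at report boundaries (matching the printed tables).
* Zero-variance paired differences (identical dose vectors, or an exact
  constant offset) collapse the $t$ CI onto the observed difference instead
  of erroring, with $p = 1$ (no difference) or $0$ (constant non-zero
  difference).
* All-zero paired differences in a Wilcoxon signed-rank contribute $p = 1$.
* Non-positive inputs to the ventilation power model are errors — the model
  is undefined there, and a zero pulse rate is a sensor fault, not a datum.
* Interpolation never overshoots: every interpolated value lies within its
  bracketing inputs (asserted as a property test).

## Problem sizes

The shipped analysis and test suite use the study-scale cohort (20
participants, full 24 s/10 Hz cadences, ~66-minute sessions) for the
pipeline stages, 50 seeded sessions for regime-recovery checks, and
1000/100 summary-level replicates for the statistical calibration. The
packaged 20-row dose table drives the published-comparison reproduction.

## Known limitations

* The FVC reference shipped for profile generation is a classic linear
  spirometry equation, clearly labelled a stand-in — not the GLI-2012
  spline reference used for the real cohort. FVC is a direct input
  everywhere downstream.
* The Standard-Method comparator uses a single daily fixed-station value
  per pollutant; sub-daily station series are out of scope.
* Dose units for gases are concentration-volume products; no deposition or
  uptake modelling is attempted.
* The AR(1) within-segment autocorrelation and the morning/afternoon shift
  magnitudes are configuration stand-ins, not estimates from data.
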