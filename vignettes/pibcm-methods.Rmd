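---
title: "Methods: physiology-integrated bioclimate modelling with pibcm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: physiology-integrated bioclimate modelling with pibcm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pibcm)
```

## The model

`pibcm` projects habitat range shifts for coastal marine ectotherms from
their metabolic thermal physiology rather than from correlative climate
envelopes alone. The chain has four stages.

**1. Metabolic physiology.** Routine metabolic rate follows the metabolic
theory of ecology (MTE) rate equation

$$B = b_0\, M^{3/4}\, e^{-E/kT},$$

with body mass $M$ (g), absolute temperature $T$ (K), Boltzmann constant
$k = 8.617\times10^{-5}$ eV/K, and the averaged enzyme activation energy
$E$ (eV). $E$ is the biologically interesting quantity: it is
population-specific and can shift through acclimation and local
adaptation. It is estimated from laboratory rate data by ordinary
least-squares (model I) regression of $\ln(\text{rate})$ on $1/T$, whose
slope is $-E/k$ (`fit_arrhenius()`). The rate equation is extraordinarily
sensitive to $E$: a 0.1 eV shift multiplies the rate by
$e^{0.1/kT}$, about `r round(fold_change(0.1, 0))`-fold at 0 °C and
`r round(fold_change(0.1, 40))`-fold at 40 °C (`fold_change()`), which is
why a population-specific $E$ matters more than refinements to the mass
term.

The habitat-level summary statistic is the **metabolic rate range**
(MRR): the difference between routine rates evaluated at a location's
climatological maximum and minimum habitat temperature
(`metabolic_rate_range()`). MRR is a proxy for the aerobic scope a
population can sustain at that location; there is no established closed
form for maximum metabolic rate as a function of temperature, so the
routine-rate range stands in for the scope itself. Because the rate is
convex in $T$ whenever $E > 2kT$ (about 0.054 eV at 40 °C),
consecutive-window MRR grows with temperature for all realistic fish
$E$ values (0.1 eV and above); `sensitivity_surface()` exposes this and
the one documented exception at $E = 0.01$ eV.

**2. Thermal envelopes.** Acclimation experiments measure rates on a
discrete temperature array (5, 10, ..., 30, plus 33 °C). A habitat
cell's climatological extremes are therefore snapped to the nearest
multiple of 5 °C and clamped to [5, 30] (`snap_to_envelope()`), and the
activation energy for that cell is fitted only on the acclimation
measurements inside the snapped envelope
(`build_envelope_E_table()`). Subpopulations split at a latitudinal
cline (default 40 °N, configurable over the 39–41 °N band to probe
hybrid-zone sensitivity): cells at or above the cline use northern fish,
below it southern fish.

**3. Climate fields.** Contemporary SST climatologies are monthly means
over all years of a fine (0.05°) daily product
(`monthly_climatology()`), upscaled to the half-degree habitat grid by
cos-latitude-weighted block averaging (`coarsen()`) and restricted to
the 0–10 m estuarine depth band (`depth_mask()`). Future fields come
from the additive **delta method**: the climate-model change signal
(future minus historical monthly climatology, per model) is interpolated
from the coarse model grid to the baseline grid with an exact
thin-plate spline and added to the observed baseline
(`delta_downscale()`); several downscaled models are averaged with
`ensemble_mean()`.

**4. Habitat projection.** Each occupied cell is classified by three
rules evaluated in order (`classify_cell()`), with
$T \equiv$ future maximum SST and a break temperature of 32 °C:

1. *stay*: $T \le 32$, $T \ge$ contemporary maximum, and future MRR
   $\le$ contemporary MRR — the population compensates by raising $E$;
2. *stay*: $T \le 32$ and ($T \le$ contemporary maximum or future MRR
   $\le$ contemporary MRR);
3. *move*: $T > 32$, or $T \ge$ contemporary maximum with future MRR
   $\ge$ contemporary MRR.

A moving population relocates to the nearest cell (haversine distance,
6371 km sphere) whose future maximum SST stays at or below the break and
whose future MRR does not exceed the mover's contemporary MRR
(`nearest_refuge()`). `project_habitat()` transfers each mover's
probability to its refuge, zeroes the source, reports populations with
no qualifying refuge as stranded, and finally caps every cell at
probability 1, recording the discarded overflow.

The comparison baseline is a single-variable AquaMaps-style trapezoidal
relative-environmental-suitability envelope (`res_suitability()`,
`project_res_map()`) with killifish SST thresholds 5.63 / 7.74 / 21.97 /
27.05 °C applied to the annual-mean SST.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `b0` | 14.47 | rate units | teleost metabolic normalization; purely multiplicative, cancels in rate ratios |
| mass exponent | 0.75 | — | canonical MTE allometry; killifish-specific estimates sit near 3/4 |
| reference mass | 10 | g | adult killifish scale used for all MRR maps |
| break temperature | 32 | °C | metabolic performance peaks at 30 °C and collapses by 33 °C |
| cline latitude | 40.0 | °N | Hudson River mouth; configurable 39–41 for robustness runs |
| depth band | [0, 10] | m | estuarine/salt-marsh habitat; closed interval, positive-down depths |
| acclimation array | 5–30 (+33) | °C | the envelope grid; bounds snap to multiples of 5 |
| RES envelope | 5.63/7.74/21.97/27.05 | °C | killifish SST suitability trapezoid |

## Design choices where the design was open

* **"Rounded up to the nearest 5 °C"** is self-contradictory for a
  minimum bound; nearest-multiple-of-5 rounding with ties upward is used
  because it reproduces the documented envelope set (5–10 through
  25–30). Degenerate snaps (both bounds equal) widen the envelope one
  step downward — upward only at the 5 °C floor — so cells with tiny
  seasonal range stay modellable.
* **33 °C assays** belong to no 5-degree bound. They are included in
  envelopes whose upper bound is 30 °C (using all warm-end information),
  and `include_33 = FALSE` turns this off. Envelope fits on
  two-temperature subsets are allowed (exact two-point fits, no
  inference), while standalone species fits require at least three
  measurements.
* **Refuge inequality.** The relocation rule compares the destination's
  *future* MRR against the mover's *contemporary* MRR by default — the
  reading consistent with "equal or lower MRR relative to their current
  habitat" — and `refuge_compare = "future"` switches to the other
  reading.
* **Transfer order and capping.** Movers are processed in ascending
  (lat, lon) order, each transferring its probability from the *input*
  map, so the result is order-independent; capping at 1 happens once,
  after all transfers, and the overflow is recorded and discarded rather
  than cascaded to neighbours. Stranded probability is zeroed and
  reported, not silently retained.
* **Distance ties** (e.g. the symmetric north/south neighbour pair)
  break deterministically to the lower latitude, then lower longitude.
  The haversine is coded in its symmetric `asin` form so mirror-image
  hops give bit-identical distances; general-purpose geodesic libraries
  can break such ties inconsistently at the 10⁻⁹ m level.
* **Thin-plate spline.** Exact interpolation (zero smoothing) with the
  $r^2\log r$ kernel plus affine part, solved as one dense symmetric
  system; a smoothing parameter exists but defaults to off because the
  delta method calls for interpolation, not smoothing. Exactness gives
  two checkable identities used throughout the tests: node values are
  reproduced exactly, and any affine delta field is reproduced exactly
  everywhere (hence a zero delta makes downscaling the identity).
* **Boundary equalities** in the classification ($T =$ break, future
  MRR $=$ contemporary MRR) resolve in favour of staying, following the
  placement of the inequalities in the three rules.

## What the synthetic generator emulates — and what it does not

`scenario_spec()` / `gen_coastal_sst()` / `gen_model_pair()` build every
input the pipeline consumes: daily 0.05° SST with a latitudinal mean
gradient, a seasonal cycle whose amplitude grows with latitude (as in
mid/high-latitude estuaries), interannual Gaussian noise and an optional
warming offset; a shelf bathymetry whose shallow band hugs the coast; a
smooth occupancy-probability field on the half-degree grid; and coarse
(~1°) model climatology pairs whose true warming delta (constant, affine
or Gaussian bump) is returned alongside for oracle checks. All
generators are pure functions of (spec, seed) and reproduce
bit-for-bit.

The default scenario is deliberately desk-scale: a 2° × 2° coastal box
(a 40 × 40 fine grid, 4 × 4 habitat cells) over three years, rather than
the 20–60 °N, 37-year domain of a production run. The generator keeps
the real resolutions (0.05° daily SST, 0.5° habitat grid, ~1° model
grid) so every interface is exercised at the true grid ratios. What it
does not emulate: tides, fronts, upwelling, estuarine micro-climates,
non-Gaussian SST variability, or any covariance between warming and
season beyond the optional monthly scaling. Passing tests therefore
demonstrate the *correctness of the algorithms* on data with the assumed
structure, not the realism of any particular coastal forecast; runs on
real Copernicus/CMIP SST and AquaMaps probability exports are needed for
substantive predictions.

## Numerical choices

* Temperatures convert as $T_K = T_C + 273.15$ everywhere; rates are
  whole-animal and used as provided (the Arrhenius regression involves
  only $\ln(\text{rate})$ and $1/T$, so mass-specific conversion would
  only shift the intercept).
* Slope inference uses the $t$ distribution with $n-2$ df; fits are
  reported, never rejected, whatever the p-value (non-significant E
  estimates are retained exactly like significant ones).
* A constant-rate dataset gives slope 0, $E = 0$; its undefined $R^2$
  (zero total sum of squares) is reported as `NA`.
* Masked grid cells are `NA` sentinels, never zeros; no operation
  unmasks a cell, and block means ignore masked children (a coarse cell
  is masked only if all its children are).
* Monthly climatologies average whatever days exist in a calendar
  month, so 365-day and Gregorian series both work; partial months
  average over available days.
* Probability conservation is exact by construction: pre-cap totals
  equal input totals minus stranded mass to 10⁻¹², which the test suite
  asserts.

## A small worked run

Warming graded from +3 °C at the southern edge to +0.2 °C at the
northern edge, with acclimation data whose thermal sensitivity rises in
the warm range (cold-range E 0.45 eV, warm-range E 0.85 eV, continuous
near 22.5 °C) — so cells whose envelope shifts upward can genuinely
lower their MRR by raising E:

```{r}
spec <- scenario_spec(seed = 42, gradient = -2.5, amp_per_deg = 0)
sc <- gen_coastal_sst(spec)
baseline <- coarsen(monthly_climatology(sc$sst, sc$dates, sc$lat, sc$lon), 10L)
pair <- gen_model_pair(spec, list(type = "affine", intercept = 56.2,
                                  b_lat = -1.4, b_lon = 0))
future <- delta_downscale(pair$hist, pair$future, baseline)

lnA_warm <- 2 + (0.85 - 0.45) / (8.617e-5 * 295.65)
acc <- rbind(
  gen_arrhenius_measurements(0.45, 2, c(5, 10, 15, 20), subpopulation = "south"),
  gen_arrhenius_measurements(0.85, lnA_warm, c(25, 30, 33), subpopulation = "south"),
  gen_arrhenius_measurements(0.45, 2, c(5, 10, 15, 20), subpopulation = "north"),
  gen_arrhenius_measurements(0.85, lnA_warm, c(25, 30, 33), subpopulation = "north"))
E_table <- build_envelope_E_table(acc)

states <- cell_states(extremes_and_range(baseline), extremes_and_range(future),
                      E_table, pibcm_config(), cells = sc$habitat[c("lat", "lon")])
proj <- project_habitat(sc$habitat, states)
proj
summary(proj)
head(probability_delta(proj$future, proj$contemporary))
```

Half the cells persist in place by envelope switching (condition 1);
the other half relocate to cooler refuges, two of which saturate at
probability 1 so the excess mass is capped and reported as overflow.

## Known limitations

Single environmental driver (SST); no dispersal kinetics, density
dependence, food availability or fishing pressure; a hard subpopulation
cline rather than a hybrid-zone gradient; envelope resolution limited by
the 5 °C acclimation grid; curvilinear (rotated-pole) climate-model
grids are out of scope — model inputs must already be on regular
lat/lon grids; and the MRR-as-aerobic-scope premise itself is a
hypothesis whose experimental validation is outside what this package
can test.
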