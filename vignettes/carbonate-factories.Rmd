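---
title: "Modelling carbonate factory distributions with fuzzy niche functions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carbonate factory distributions with fuzzy niche functions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carbfact)
library(dplyr)
library(ggplot2)
```

## The model and its assumptions

`carbfact` maps the susceptibility of occurrence of four shallow-water marine
carbonate factories — biochemical, photozoan-T, photo-C and heterozoan-C —
from gridded sea-surface fields. The model is deliberately minimal: it
assumes that, at the scale of a whole platform, factory occurrence is
controlled by a small set of extrinsic sea-surface parameters (seasonal
temperature, salinity class, primary productivity) plus bathymetry, with
terrigenous input acting as a hard exclusion. It predicts *where conditions
permit a factory*, not production rates, biota or within-platform facies.

Per cell, each factory scores

$$F = a\,f(z) + b\,f(\mathrm{SST}) + c\,f(\mathrm{SSS}) + d\,f(P),
\qquad a+b+c+d = 1,$$

with each $f$ a bounded fuzzy membership: Gaussian
$\exp(-S(x-MP)^2)$, near-Gaussian $1/(1+S(x-MP)^2)$, or large sigmoid
$1/(1+(x/MP)^{-S})$. Because memberships live in $[0,1]$ and the weights lie
on the simplex, $F \in [0,1]$ for any valid parameterization — a property the
test suite checks under randomly drawn parameter sets. Presence is declared
where $F$ strictly exceeds the factory's final threshold; the terrigenous
term is realized as an eligibility mask (equivalent to subtracting a binary
indicator and clamping), so inhibited cells carry `NA` susceptibility rather
than a diluted score.

Seasonality enters through per-factory aggregation rules rather than extra
parameters. The tropical factory sees the mean of the warm- and cool-season
composites; with the shipped mid-point and spread this places the 0.5
crossings of its SST membership at 20.9 and 30.5 degC and reproduces the
known exclusion of year-round-temperate coasts (mean SST between 18 and
24 degC never clears the 0.7 threshold, as the susceptibility worked example
in the tests shows: $F = 0.69$ at a 21 degC year-round cell with every other
membership at 1). The biochemical factory needs extreme warmth in *at least
one* season, so its sigmoid reads the warm-season field, and hypersalinity
all year round, so its salinity membership reads the cool-season class. The
warm-temperate factory is defined by seasonal contrast itself: a *production*
Gaussian (mid-point 25.25 degC) evaluated on the warm season is multiplied by
a *persistence* Gaussian (mid-point 12.325 degC) on the cool season. All
rules are configuration fields and can be overridden.

## Parameters that matter

`default_factory_params()` ships the full calibration; the table below gives
the shape parameters (mid-point in the parameter's units; spread
dimensionless):

```{r params}
purrr::imap_dfr(default_factory_params(), function(p, id) {
  tibble::tibble(factory = id,
                 threshold = p$threshold, depth_max = p$depth_max,
                 w_z = p$weights[["z"]], w_sst = p$weights[["sst"]],
                 w_sss = p$weights[["sss"]], w_prod = p$weights[["prod"]])
})
```

Notes on specific choices:

* **Bathymetry.** The depth interval (0–100 m for the shallow-light
  factories, 0–200 m for the deeper-reaching ones) is enforced by the
  eligibility mask, and the depth membership is flat inside it. No depth
  trend is imposed because the very low bathymetry weights (0.03–0.10, set as
  the simplex remainder of the published SST/SSS/P weights) make any
  within-interval curve shape immaterial to the output.
* **Salinity classes.** Practical salinity is reclassified into eight
  left-closed bins from 30 to 37.5 psu with an open top class;
  sub-30-psu water clamps to class 1 (with a message) rather than being
  masked, leaving brackish inhibition to the membership functions. Seasonal
  averaging of classes keeps fractional values: the memberships are
  continuous, so re-rounding would only discard information.
* **Productivity spreads** (565, 2450, 625 for photozoan-T, photo-C,
  heterozoan-C) imply 0.5-crossings near 0.055, 0.037 and 0.02–0.10 m$^{-1}$,
  consistent with the factories' stated productivity ranges; they are plain
  config values and trivially changeable.
* **Heterozoan background rule.** The heterozoan-C factory could not be
  discriminated numerically; it is assigned only where no other factory is
  present, its own susceptibility clears 0.5, and seasonal-mean productivity
  reaches a floor of 0.01 m$^{-1}$. The floor is kept as an explicit,
  configurable rule rather than folded into the membership: with the shipped
  spread the 0.5-crossing alone would imply a floor near 0.015 m$^{-1}$, and
  keeping the two mechanisms separate makes the rule auditable.

## Calibration chain

Calibration reverses prediction: sample the environmental fields under an
observed factory footprint (`extract_values()`), summarize them into
percentiles (`summarize_values()`; linear interpolation between order
statistics — the estimator is a package choice, stated here because percentile
conventions differ), derive tolerance thresholds (`derive_thresholds()`:
production = warm-season low percentile, persistence = cool-season low
percentile, upper = larger seasonal high percentile; 1st/99th percentiles for
temperature and salinity, 5th/95th for heavy-tailed productivity), average
the two lower thresholds, take the mid-point as the mean of lower and upper
bounds (`compute_midpoint()` — the mode is the fallback when only one
threshold exists), and solve the spread so the membership equals 0.5 at the
threshold (`calibrate_spread()`). The sigmoid spread, which has no symmetric
threshold pair, inverts through any reference point in closed form
(`fit_sigmoid_spread()`).

Two published mid-points (photo-C production 25.25 and persistence
12.325 degC) and the biochemical sigmoid spread 58 do not follow from any
stated derivation; they ship as fixed defaults, not calibration outputs.

## The synthetic world

`generate_env()` builds a seeded planet with the structure the model assumes:
a zonal SST gradient with mid-latitude-peaked seasonal amplitude, two
meridional continents with shelf ramps, subtropical salinity maxima, a
shallow hypersaline gulf (class-8 salinity, warm-season SST above 30.5 degC),
a low-productivity background with subtropical western-margin upwelling
stripes, and coastal terrigenous bands (high river-mouth patches, a low
fringe, an arctic band). Seasons are stored as local warm/cool composites so
one field pair serves both hemispheres. The upwelling stripes sit at
24–31 degrees latitude with 0.09 m$^{-1}$ absorption — the upper edge of the
heterozoan optimum — because that is the only regime in this idealized world
where upwelling actually transfers a cell from the tropical factory to the
background factory: weaker (0.06 m$^{-1}$) or higher-latitude stripes are
retained by the photozoan-T or photo-C temperature domains.

What the generator does *not* emulate matters for interpreting green tests:
real coastline geometry, within-platform topography, hydrodynamics,
calendar-month compositing, sensor dropouts and retrieval bias in coastal
waters, and any spatial autocorrelation structure beyond the smooth zonal
fields plus white noise. Tests passing on this world demonstrate the
*internal* consistency of the chain (prediction inverts generation;
calibration recovers generating parameters), not skill against real
observation maps, which would require the satellite rasters and bibliographic
database that are outside this package's scope.

## Recovery experiments

The parameter-recovery study (`calibration_world_config()` +
`calibration_truth_params()`) is designed so the observed footprint is
exactly the 0.5 superlevel set of the membership being recovered: full weight
on SST and a 0.5 presence threshold. Two further conditions are set by
analysis of the chain itself. First, the equatorial annual mean is raised to
32.5 degC: with the default 27.5 degC equator the planet never reaches the
upper 0.5-crossing (30.5 degC), the warm tail of the footprint is truncated,
and the upper threshold — hence mid-point and spread — cannot be recovered.
Second, the seasonal amplitude is a uniform 1 degC: the upper threshold is a
warm-season percentile, so an amplitude $A$ biases the recovered mid-point by
about $A/2$; gentle seasonality keeps that bias well inside the 5% (mid-point)
and 20% (spread) recovery tolerances at footprints of two thousand cells or
more. Recovery is demonstrated for the tropical SST Gaussian because that is
the only factory whose calibration the chain fully defines (the others
include fixed, non-derivable defaults).

## Numerical choices and degenerate inputs

* Presence uses a strict inequality; a cell exactly at threshold is absent.
* Competing non-background factories resolve by largest margin
  $F - \text{threshold}$, with exact ties broken in the fixed order
  biochemical, photozoan-T, photo-C. The rule matters only in transition
  bands (below).
* The large sigmoid is evaluated in log space for numerical stability at
  large spreads, returns 0 for non-positive abscissae (it is used only for
  SST, where sub-zero Celsius water is outside any factory's domain of
  interest), and `NA` for missing input. All memberships propagate `NA`;
  zero-weighted terms are skipped so a gap in an ignored field never masks a
  cell.
* Grids are validated as regular cell-centered lattices (uniform spacing to
  1e-9); latitude order is normalized to ascending on read. Bilinear
  resampling marks any target cell touching a missing source cell as missing
  rather than interpolating across the gap; categorical fields resample by
  nearest neighbour.
* AHP weights come from power iteration to 1e-12; the consistency ratio uses
  the standard random-index table, with size-2 matrices defined as perfectly
  consistent.

## Exclusive temperature domains: a known limitation

The three temperature-discriminated factories occupy distinct domains in
(warm-season, cool-season) SST space, but their *raw* presence regions are
not mathematically disjoint when every other membership is held at its
optimum. A short calculation shows why: with $f(\mathrm{SSS}) = 1$ the
biochemical score is $0.10 + 0.45 f_T + 0.45 > 0.6$ whenever
$f_T > 1/9$, i.e. for warm-season SST above about 29.4 degC — inside the
tropical factory's window. Similar warm-edge bands exist between the tropical
and warm-temperate factories. In real fields the factories' differing
salinity and productivity optima pull these scores apart, and the
combination step always assigns a single winner, so the final map is
exclusive; but exclusivity is a property of the *combined assignment*, not of
the per-factory threshold regions. The test suite asserts the partition
property and each factory's core domain; a stricter disjointness assertion
over the raw regions is retained in the acceptance tests and documents this
limitation by failing.

## Problem sizes

Shipped experiments use a 120 x 240 world for prediction/evaluation round
trips and a 240 x 480 world for calibration recovery (chosen so
single-factory footprints comfortably exceed 2000 cells); both run in
seconds, and all sizes are configuration parameters.

```{r map, fig.width = 7, fig.height = 3.5}
world <- generate_env(world_config())
autoplot(predict_factories(world$env))
```
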