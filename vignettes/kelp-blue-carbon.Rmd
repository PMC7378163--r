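---
title: "Methods: kelp forest blue-carbon accounting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kelp forest blue-carbon accounting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kelpcarbon)
```

## The accounting problem

Blue-carbon budgets have traditionally covered only sediment-accreting
coastal ecosystems — tidal marshes, mangrove forests and seagrass beds —
because those bury carbon locally. Kelp forests grow on rocky reef with
essentially no local burial, yet they hold large aboveground stocks and
export most of their production as detritus, part of which reaches the
deep ocean and stays out of exchange with the atmosphere. `kelpcarbon`
implements the accounting chain needed to put a kelp forest (here the
*Ecklonia radiata* forests of Australia's Great Southern Reef) into a
continental blue-carbon budget:

1. **Field upscaling.** Individual plant dry weights (kg plant⁻¹) and
   plot densities (plants m⁻²) combine into a standing carbon density
   (Mg C ha⁻¹); per-plant annual growth rates and the same densities
   combine into net primary production, NPP (Mg C ha⁻¹ yr⁻¹). Carbon is
   taken as 30 % of dry weight.
2. **Sequestration fraction.** Of all seaweed NPP, an estimated 11 %
   (range 4–18 %) is sequestered long-term. Burial on the continental
   shelf (0.9 % of NPP) is excluded — it could already be counted as
   allochthonous carbon in the sediment budgets of the other ecosystems —
   leaving a deep-export fraction of 10.1 % applied to NPP.
3. **Range scaling.** Habitat extent is an explicit min–max interval
   (3.2–7.1 Mha, from suitable reef area times mean percent cover ± SD).
   Stocks and fluxes are the area endpoints times the per-area point
   estimate; since 1 Mha × 1 Mg ha⁻¹ = 1 Tg, the unit conversion is an
   identity.
4. **Budget assembly.** The kelp row joins literature values for marshes,
   mangroves and seagrass; shares of the continental totals are reported
   under two conventions (below).
5. **Losses.** Historical loss events convert an affected area (reported
   directly, or coastline × an empirical coastline-to-reef ratio × the
   percent cover lost) into lost stock and lost annual sequestration;
   89 % of lost standing stock is taken to be remineralised to CO₂
   through marine food webs. Future range contractions (49 % under
   RCP 2.6, 71 % under RCP 6.0 by 2100) scale a convention point of the
   baseline ranges.

## The interval convention and what it omits

The published ranges carry **area uncertainty only**: the per-area density
(3.2 ± 0.5 Mg C ha⁻¹) and rate (0.39 ± 0.09 Mg C ha⁻¹ yr⁻¹) have SDs, but
those SDs are reported alongside the interval, never compounded into it.
Only that convention reconciles the printed tables (e.g. 7.1 Mha ×
3.2 Mg C ha⁻¹ = 22.7 Tg C), so `scale_stock()` and `scale_flux()`
reproduce it exactly. The `mc_propagate()` module quantifies what the
convention omits: sampling every input (zero-truncated normal by default,
lognormal for skewed biomass) and pushing draws through the same chain
gives a full predictive interval that is wider than the printed one. The
interval endpoints always lie inside the Monte Carlo support; the test
suite checks this.

## Uncertainty of the field aggregates

`standing_density()` and `npp_per_area()` combine two independent surveys
(plants and plots), so the SD of the product uses first-order (delta
method) propagation:

    sd ≈ mean × sqrt(cv_plant² + cv_density²)

This drops the cross term `cv_plant² × cv_density²` of the exact
product-of-independent-variables variance. The relative error of the
delta SD is therefore about `cv₁²cv₂² / (2(cv₁² + cv₂²))`: under 0.1 % at
the CVs of the default generator, about 3 % when the combined CV of the
aggregate reaches 0.5, and about 6 % in the extreme case where both input
CVs are 0.5 at once. The property tests compare the delta SD against a
10⁵-draw Monte Carlo oracle and hold the 5 % agreement bound throughout
the regime where the combined CV of the aggregate is at most 0.5, which
covers the survey data this package targets; beyond it the approximation
degrades as described and `mc_propagate()` should be preferred.

Two pooling modes are provided because the original surveys are
unbalanced across states (3 locations × 3 sites × 5–6 quadrats each): the
default pools every record with equal weight; `stratified = TRUE`
averages plot densities within regions first and weights regions equally.
The defaults were chosen for transparency — the grand mean is what the
simple product formula assumes — and the stratified mode is the
sensitivity check.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `carbon_fraction` | 0.30 | – | carbon content of kelp dry weight |
| `total_npp_frac` | 0.11 | – | fraction of NPP sequestered overall (range 0.04–0.18 usable for sensitivity) |
| `shelf_burial_frac` | 0.009 | – | NPP buried on the continental shelf, excluded |
| `area_lo_mha`, `area_hi_mha` | 3.2, 7.1 | Mha | habitat extent interval (an input: the cited reef-mapping product) |
| `reminer_frac` | 0.89 | – | lost stock remineralised to CO₂ |
| `coast_reef_ratio_ha_per_km` | 283.25 | ha km⁻¹ | reef area per km of affected coast |
| `rounding_sigfigs` | 3 | – | presentation rounding (computation is full precision) |

The coastline-to-reef ratio is not printed in the sources that use it; it
is back-calculated here from the one loss record that reports coastline,
percent loss and area together (97,438 ha ÷ (800 km × 0.43) = 283.25) and
exposed in the configuration rather than hard-coded.

## Share conventions

Published percentages mix two conventions, and both are implemented in
`share_of_total()`:

* **midpoint**: `100 × mid(component) / mid(total)` — a single number;
  reproduces the "31 % of sequestration" figure.
* **range**: ratios of matching endpoints, ordered ascending — an
  interval; reproduces the "11–13 % of standing stock" figure.

Shares are computed against the *published* totals, which carry more
precision than the printed per-row ranges: summing the printed rows gives
a low stock endpoint ≈ 78.5 Tg against a published 77 Tg (≈ 2 %), and
using row sums would shift the midpoint flux share from 31 % to 32 %.
`assemble_budget()` therefore reports its own row sums, and the fixture
keeps the published total row alongside as a literature value.

## Historical losses and projections

Per-event carbon losses are lost area × mean per-area density/rate. The
five bundled event records reproduce each published regional loss within
1 %; the residual traces to the sources' unrounded per-area constant
(≈ 3.19 Mg C ha⁻¹ versus the rounded 3.2). The published national totals
sit a uniform ≈ 1.9 % above the five-row sums in all three columns —
evidently additional unprinted records — so `aggregate_losses()` reports
the row sums as-is and the comparison is flagged, never forced.

Scenario losses use the **midpoint** of the baseline range by default
(the convention that reconciles the published RCP 2.6 stock loss of
8.1 Tg C = 0.49 × 16.5); `lo`/`hi` conventions are available for
sensitivity. The published scenario-table "area loss" cells do not
reconcile with any combination of the area range and loss fractions under
a hectare reading and are treated as a typesetting artifact; they are not
used.

## The synthetic-data generator

No public accession exists for the raw field tables, so the package ships
a seeded generator that emulates their statistical structure: lognormal
plant biomass and growth (strictly positive, right-skewed, as biological
size data are), zero-truncated normal plot densities, and percent-cover
series that follow a linear trend plus Gaussian noise clipped to
\[0, 100\]. Sample sizes default to the real surveys' (135 plants, 558
plots, 1,577 growth rates). The distributional families are this
package's choice — the sources state only sample sizes and resulting
moments — and the default means and CVs were back-solved once so the
aggregation chain recovers 3.2 ± 0.5 Mg C ha⁻¹ and
3.9 ± 0.9 Mg C ha⁻¹ yr⁻¹: biomass 0.5 kg (CV 0.110), density 2.133 m⁻²
(CV 0.110), growth 0.609 kg yr⁻¹ (CV 0.203).

What the generator deliberately does **not** emulate: spatial
autocorrelation among quadrats, depth and temperature structure in
growth, seasonality, site-level random effects, and correlation between
plant size and stand density. Passing the recovery tests therefore shows
the arithmetic and the uncertainty propagation are right under the
assumed independence structure — it does not validate those independence
assumptions against real reef data.

Each generator draws on its own sub-stream (`seed` plus a fixed offset),
so plants, plots, growth and cover series are mutually independent and
individually reproducible; all generation is bitwise deterministic given
the seed and restores the caller's RNG state.

## Numerical choices and degenerate inputs

* Internal computation is full double precision; rounding to 3
  significant figures happens only in rendered text tables, with CSV
  twins holding full precision.
* A cover SD larger than the mean clamps the lower extent to zero with a
  classed warning (patchy reefs make this plausible) instead of erroring.
* A single observation yields SD 0 rather than `NA`; zero mean density
  yields a degenerate 0 ± 0 estimate with a warning; a zero first-window
  cover baseline is an error (`loss` undefined).
* Cover-loss windows may overlap for series shorter than `2k` records
  (warning), since historical monitoring is sparse.
* Zero-truncated normal sampling uses rejection, cheap at the small CVs
  of carbon field data; lognormal parameters are moment-matched to the
  arithmetic mean and SD.

## Problem sizes

The test suite and the acceptance script run the generator at the real
survey sizes (2,270 field records per replicate), 100 replicates for
parameter recovery, and 10⁵ draws for Monte Carlo comparisons — a few
seconds end to end — which is ample for the ~0.1 % Monte Carlo standard
errors the comparisons need.

## Known limitations

* The deep-export fraction (10.1 % of NPP) is the weakest number in the
  chain, as its sources acknowledge; `total_npp_frac` accepts the 4–18 %
  range for sensitivity runs.
* Ranges propagate area uncertainty only (the published convention);
  treat the printed intervals as scenario bounds, not confidence
  intervals — `mc_propagate()` gives the latter.
* The marsh/mangrove/seagrass rows are literature values, never
  recomputed; GIS questions (habitat mapping, spatial overlap between
  ecosystems) are out of scope, and reef area is an input, not derived
  from bathymetry.
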