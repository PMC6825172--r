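---
title: "Assessing bottom-trawling impact on deep-sea sponge grounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing bottom-trawling impact on deep-sea sponge grounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spongeimpact)
```

## The problem

Dense aggregations of structure-forming demosponges (*Geodia* grounds) on
bathyal banks such as the Flemish Cap are vulnerable marine ecosystems: a
single bottom-trawl pass can remove most of the large sponges in its path,
and recovery takes decades. Assessing whether a trawl fleet causes a
significant adverse impact requires linking four quantities that are
usually studied separately: how much sponge is there (biomass surfaces),
where the fleet actually trawls (VMS footprints), how much sponge the
fleet removes (overlay accounting), and what that removal costs the
ecosystem and the economy (physiological upscaling and replacement-cost
valuation). `spongeimpact` implements that chain end to end, together
with a seeded synthetic-seascape generator so every stage can be tested
without access to confidential survey, VMS or catch data.

## The synthetic seascape

The generator works in planar, equal-area coordinates (km). All the
downstream mathematics needs areas, distances and depth only, so
geographic projections would add complexity without changing any result;
the planar convention is therefore used throughout and documented here
once.

A seascape consists of:

* **Bathymetry**: a Gaussian cap rising from a 3000 m basin to a 140 m
  summit, giving closed isobaths (needed for contour-following trawl
  simulation) and a bathyal ring.
* **True sponge density**: a sum of 25 Gaussian patches with
  log-normally distributed peak amplitudes, tapered by a Gaussian window
  in depth (peak 1100 m, sd 500 m) and hard-masked to the 50-2000 m window in which geodiid sponges are
  observed. The defaults were calibrated once so the habitable-area mean
  density is near 0.0017 kg m^-2^, closure-scale densities reach
  ~0.02 kg m^-2^ and single cells can reach ~0.1 kg m^-2^ — the density
  scales reported for these grounds.
* **Covariates**: depth, slope, a habitat-suitability field (the patch
  field itself) and an uninformative smooth "current" field. Because the
  habitat covariate is informative by construction, random-forest
  recovery tests demonstrate correct plumbing and calibration of the
  estimator, *not* predictive skill on real, noisier predictor stacks.
* **Closures**: rectangles centred on the patches with the highest
  realized peak density (amplitude times depth taper), emulating closures
  drawn around known dense grounds; divisions are four vertical strips
  (named after the NAFO 3LMNO divisions) that partition the extent.

Survey tows are point samples drawn uniformly over the extent: real
groundfish surveys are depth-stratified, but a uniform design suffices
for testing the estimators and keeps the generator free of tuning knobs.
The catch of a tow is `true_density x swept_area` with 100 % catchability
(39,000 m^2^ for the Lofoten gear, 67,000 m^2^ for the Campelen gear), so
`catch/swept_area` recovers the density exactly — the invariant the
training-table and grid estimators rely on. Tow length and speed of the
research gears are not modelled because no authoritative values were
available; tows are point observations carrying the printed swept areas.

Simulated vessels alternate steaming legs (9 ± 1 kn, truncated above
6.5 kn) and fishing legs (3 ± 0.3 kn, truncated below 5.9 kn) so the
6-knot classification threshold separates the two states cleanly — real
VMS data are messier, which is why the threshold itself is configurable.
An 18 nm fishing leg at 3 kn with hourly pings emits exactly 7 pings.

## Grid-cell biomass surface

The grid-cell estimator scales the mean sponge catch of the tows in each
5 x 5 km cell to the whole cell:

$$ B_{cell} = \overline{catch}\ \times\ \frac{A_{cell}}{A_{swept}} \ /\ 1000 \quad [t] $$

with $A_{cell}/A_{swept}$ = 373.13 (Campelen) or 641.03 (Lofoten) — the
factors are kept unrounded in the arithmetic; 373 and 641 are display
values. Cells are half-open intervals so a tow on a shared edge belongs
to exactly one cell.

Two grids are estimated — one from tows inside closure polygons, one
from tows outside — and merged geometrically: a cell bisected by a
closure boundary carries the inside-stratum estimate on its inside area
fraction and the outside-stratum estimate on the rest. This preserves
the sharp biomass transitions observed at closure borders instead of
smearing them across boundary cells.

Cells with no tows are filled by a focal statistic: the mean of the
observed (never previously filled) 8-neighbours in the same stratum, in
a single pass. A single pass was chosen over iteration-to-completion
because repeated passes propagate values arbitrarily far from any
observation; the window and the single-pass rule are the package's
documented convention. Totals over a region weight each cell by its
fractional area inside the region, computed by exact convex clipping.

## Random-forest biomass model

The modelling approach regresses tow-level sponge density on the
covariates with a random forest: 1000 trees, 2 candidate variables per
split, and the engine's regression default minimum node size (5), which
is echoed into the fit report. The response is standardized to density
(kg m^-2^ = catch / swept area) because the two survey gears sweep
different areas; a raw-catch mode is retained as an option since the
choice is not forced by the method.

Performance is summarized as the mean ± SD of out-of-sample R^2^
(1 − SSE/SST about the held-out mean) over all folds of a 10-fold
cross-validation repeated 10 times, fully seeded. Predictions are made
on every raster cell, converted to tonnes per cell, and masked outside
the 50-2000 m depth window; integration over regions is an
area-weighted sum over unmasked cells and is exactly additive over
disjoint regions.

## VMS footprint

Pings at speeds strictly below 6 kn are classified as fishing (a ping at
exactly 6.0 kn is steaming). Maximal runs of ≥ 2 consecutive fishing
pings of one vessel form a trawl track; a run also breaks when the time
between retained pings exceeds `max_gap` (default twice the median ping
interval — the data alone cannot say how long a silence still belongs to
one trawl, so the rule is explicit and configurable).

Tracks are buffered to a 100 m wingspread with flat end caps, built as
one rectangle per segment; a straight track's swath area is therefore
exactly `length x wingspread`, which anchors the geometry tests. The
footprint is the geometric union of all swaths, so repeated passes over
the same ground are counted once ("trawled at least once"); cumulative
swept-area ratios are deliberately out of scope.

All polygon arithmetic (convex clipping, union areas, cell overlays) is
implemented exactly in the package with a vertical slab sweep whose
breakpoints are all vertices plus all pairwise edge intersections;
within a slab the union cross-section is linear, so the midpoint rule
integrates it exactly. No raster discretization is involved anywhere in
the footprint or removal accounting.

## Removal accounting and closure simulation

Per cell, removal is `(trawled area fraction) x biomass x removal_rate`
with `removal_rate = 1` by default: each pass removes 100 % of the
sponges it covers, the worst case, matching the catchability assumption
on the survey side. Removal percentages always take an explicit
reference biomass, because the published percentages mix denominators
(the reported 4.4 % is not recoverable from the corresponding table,
whose figures give 4.1 %).

Closure trawling is simulated by placing non-overlapping
contour-following sets inside the closures (allocation proportional to
closure area, rejection sampling against overlap): 18 nm per set — 6 h
at 3 kn — except in the two smallest closures (7 and 8 nm). Paths
follow the local isobath direction with small angular jitter and turn
inward at closure boundaries; a closure that cannot host the requested
effort yields a shortened set with a warning. Trawls-to-depletion is
`ceiling(stock / mean removal per set)`: eliminating the *entire* stock
requires covering all of it, so a final partial trawl counts in full.

## Ecosystem-function upscaling

All functions are linear in biomass, per day, using *G. barretti* rates
per unit wet weight (WW):

| quantity | rate | activity factor |
|---|---|---|
| filtration | 347 ± 93 L kg^-1^ day^-1^ | × 0.70 |
| respiration | 7.68 ± 1.44 µmol O~2~ g^-1^ day^-1^ | none |
| NH~4~^+^ uptake | 0.02 ± 0.0026 µmol L^-1^ filtered | via filtration |
| NO~2~^-^ uptake | 0.16 ± 0.05 µmol L^-1^ filtered | via filtration |
| NO~3~^-^ release | 1.87 ± 0.23 µmol L^-1^ filtered | via filtration |

The 0.70 activity factor applies to filtration only: the filtration rate
is a maximum pumping rate measured on actively pumping individuals,
whereas only about 70 % of individuals pump at any one time; respiration
is a routine metabolic rate and carries no factor. This split is the
only reading that reproduces both reference totals (56,143 × 10^6^ L
day^-1^ and 56.80 t O~2~ day^-1^) from the same 231,136 t stock.

Carbon consumption applies the 0.9:1.0 carbon-to-oxygen conversion *on
the mass scale*: C tonnage = O~2~ tonnage / 0.9. Molar interpretations
of the ratio do not reproduce the published 63.11 t C day^-1^ from
56.80 t O~2~ day^-1^ and are rejected. Nitrogen fluxes convert litres
filtered × concentration × molar mass (O~2~ 32.00, NH~4~^+^ 18.04,
NO~2~^-^ 46.01, NO~3~^-^ 62.00 g mol^-1^). With the standard 46.01 the
nitrite flux runs ~1.7 % above the published division values (which
imply ~45 g mol^-1^); the standard mass is used and the discrepancy
noted here.

SDs of filtration, respiration and carbon scale the single rate SD
linearly (reproducing ± 15,047, ± 10.65 and ± 11.83); nitrogen SDs
combine the relative errors of filtration and concentration in
quadrature, with single-source bounds available via `sd_mode`, since no
propagation rule reproduces the published nitrogen SDs exactly.
`function_table()` reports a Total row computed directly from the summed
biomass and, as an attribute, the sum of 2-decimal-rounded region values
— published tables mix the two conventions (e.g. a carbon total of 63.11
is the rounded sum, while the filtration total 56,143 is direct).

## Economic valuation

Catch value is the sum over species-years of reported value (or catch ×
ex-vessel unit price), adjusted to 2018 by *compound* inflation —
compounding is the only rule consistent with all three published
adjusted totals at the printed rates (1.78 %, 1.58 %, 1.50 % for
2010-2012).

The lost filtration service is monetized by replacement cost against the
Ashbridges Bay Treatment Plant (average daily flow 598 × 10^6^ L
day^-1^; capital cost USD 182 M for the UV disinfection facility plus
USD 5.4 M operating cost over a 3-year horizon — held as a 3-year total,
the only reading consistent with the published USD 187 M). A loss whose
plant-equivalence ratio falls in (0.5, 1.5] counts as one substantially
equivalent plant; in general the plant count is the nearest integer to
the ratio with halves rounding down, the generalization consistent with
both the one-plant band and proportional scaling (a ratio of 2.0 needs
two plants, not three).

## Numerical choices and test scales

* Geometry is exact up to floating point; the union-area sweep is tested
  against an independent point-sampling oracle at 2 % and against closed
  forms at 10^-6^ relative.
* Tests and examples use a 60 × 40 km seascape at 2 km resolution with
  ~900-1500 tows, and cross-validation demonstrations use 400
  observations with 100-300 trees — sizes chosen so the full suite
  exercises every stage in well under a minute per file while leaving
  the statistical conclusions unchanged; package defaults remain at the
  full values (1000 trees, 10 × 10 CV, 300 × 200 km).
* Degenerate inputs fail loudly: zero-length tracks and zero wingspreads
  are rejected, empty regions warn and return 0, tows outside the grid
  or covariate extent are dropped with a message.

## Known limitations

* The synthetic world is planar and convex-polygon-based; real closure
  and division geometries are neither, and real analyses need a proper
  equal-area projection upstream.
* The habitat covariate makes the density field learnable by
  construction; passing recovery tests does not imply comparable skill
  (e.g. the published R^2^ = 0.40 ± 0.03) on real predictor stacks.
* Sediment-plume mortality adjacent to trawl lanes is not modelled —
  there is no quantitative basis for it — so removal estimates are
  direct-contact only.
* Cumulative-effort metrics (swept-area ratio > 1) and multi-pass
  depletion dynamics are out of scope; the footprint is strictly
  "trawled at least once".
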