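# spongeimpact

Quantifying the impact of bottom trawling on deep-sea sponge grounds.

Deep-sea *Geodia* grounds are vulnerable marine ecosystems whose dense,
filter-feeding sponge biomass couples the seafloor to the water column:
they pump enormous volumes of seawater, consume organic carbon and cycle
nitrogen nutrients. `spongeimpact` is an R package for marine spatial
ecologists and fisheries scientists that implements, as one tested
pipeline, the full chain of a fleet-scale impact assessment:

1. **Biomass surfaces** from research-vessel trawl catches, by two routes:
   - a *grid-cell estimator*: per 5 × 5 km cell,
     `B = mean(catch) × (cell area / gear swept area) / 1000` tonnes, with
     closure-aware strata merged geometrically and single-pass focal
     infilling of unsampled cells;
   - a *random-forest distribution model* (1000 trees, mtry = 2,
     10 × 10-fold cross-validated R²) of catch standardized to density
     (kg m⁻²), predicted over the seascape and masked to 50–2000 m depth.
2. **Fishing footprints** from vessel-monitoring-system pings: pings
   < 6 kn are fishing; runs of ≥ 2 consecutive fishing pings become trawl
   tracks; tracks are buffered to a 100 m wingspread (flat caps, so a
   straight swath is exactly `L × W`) and unioned into the area trawled
   at least once.
3. **Removal accounting**: per cell,
   `removal = trawled fraction × biomass × removal rate` (default 100 %
   removal per pass, the worst case), plus simulated contour-following
   trawl sets inside closures and a trawls-to-depletion count
   `⌈stock / mean removal per set⌉`.
4. **Ecosystem function**: daily filtration (347 ± 93 L kg⁻¹ × 0.70
   activity factor), respiration (7.68 ± 1.44 µmol O₂ g⁻¹), carbon
   consumption (C = O₂ / 0.9 by mass) and NH₄⁺/NO₂⁻/NO₃⁻ fluxes per litre
   filtered, all linear in wet-weight biomass with propagated SDs.
5. **Economic valuation**: ex-vessel catch value with compound inflation
   adjustment, and replacement cost of the lost filtration against a
   wastewater-treatment plant of equivalent daily flow.

A seeded synthetic-seascape generator (bathyal cap, patchy depth-tapered
density field, survey tows with 100 % catchability, steaming/fishing
vessel trajectories, closures and divisions) makes every stage testable
without confidential survey, VMS or catch data. All spatial overlay is
exact planar polygon geometry — no raster discretization in the
footprint or removal arithmetic.

## Worked example: function and valuation of a sponge stock

```r
library(spongeimpact)

f <- filtration(231136)            # total stock, tonnes wet weight
r <- respiration(231136)
cc <- carbon_consumption(r)
loss <- function_loss(2580)        # biomass removed by trawling
rc <- replacement_cost(round(loss$filtration_ML))
adj <- adjust_catch_value(catch_value(nafo_3m_catch()), inflation_rates_2018())
compare_values(adj$total_adjusted_usd, rc$cost_musd * 1e6)
```

prints (formatted):

```
filtration: 56143 +/- 15047 x 1e6 L/day
respiration: 56.80 +/- 10.65 t O2/day
carbon: 63.12 t C/day
pumping loss: 627 +/- 168 x 1e6 L/day
replacement cost: 1 plant(s), USD 187 M (ratio 1.05)
adjusted catch value 2010-2012: USD 125.8 M
catch/replacement ratio: 0.67
```

i.e. a 231,136 t sponge stock filters ~56 billion litres of seawater per
day; the 2,580 t removed by trawling in the most-impacted division
forfeits pumping capacity roughly equal to one metropolitan wastewater
plant (USD 187 M replacement cost), about twice the inflation-adjusted
value of the fish catch that caused it.

## Worked example: the synthetic pipeline

```r
sc    <- generate_seascape(seascape_config(seed = 42))
tows  <- sample_rv_tows(sc, 2000, seed = 7)
bg    <- focal_fill(cell_mean_biomass(tows, grid_for_extent(sc$extent_km, 5), sc$closures))
fit   <- fit_and_validate(make_training_table(tows, sc),
                          rf_config(n_trees = 300, cv_repeats = 2, seed = 5))
surf  <- predict_surface(fit, sc)
pings <- simulate_vms(sc, n_vessels = 12, n_tows_per_vessel = 8, seed = 3)
fp    <- union_footprint(lapply(build_tracks(pings), track_to_swath),
                         region = rect_poly(0, 0, 300, 200))
rem   <- removal_by_cell(fp, surf)
sim   <- simulate_closure_trawls(sc, surf, n = 30, seed = 11)
```

output from this run:

```
seascape: 300 x 200 km at 2 km, 6 closures, 4 divisions
  true biomass: 50285 t; habitable cells: 7426
biomass_grid: 40 x 60 cells (5 km), 2399 populated, total 49949 t
cross-validated R2: 0.98 +/- 0.01
model_surface: 100 x 150 cells, 7426 valid (50-2000 m), total 49615 t
true biomass: 50285 t | grid: 49949 t | model: 49615 t
footprint: 96 tracks, 321.15 km2 trawled at least once
removal: 530 t (1.1% of stock)
simulated closure trawls: 42 +/- 30 t per set
closure stock 34605 t -> 816 trawl sets to depletion
```

Both estimators recover the known 50,285 t synthetic stock to within
~1 %; the reconstructed footprint removes 530 t (1.1 %) of it, and the
closure simulation shows how many directed trawl sets would erase the
protected stock.

The methods vignette (`vignettes/spongeimpact-methods.Rmd`) documents
the models, the unit conversions, the uncertainty propagation and every
place where a convention had to be chosen.

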