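test_that("seascape generation is seeded, depth-masked and mass-consistent", {
  sc1 <- small_scape(seed = 42)
  sc2 <- small_scape(seed = 42)
  expect_identical(sc1$true_density, sc2$true_density)
  expect_identical(sc1$bathymetry, sc2$bathymetry)
  expect_false(identical(sc1$true_density, small_scape(seed = 43)$true_density))

  expect_true(all(sc1$true_density >= 0))
  expect_true(all(sc1$true_density[sc1$bathymetry > 2000] == 0))

  # zero patch amplitude gives an identically zero field
  sc0 <- small_scape(patch_amplitude_scale = 0)
  expect_true(all(sc0$true_density == 0))

  # divisions partition the extent: every point is in exactly one strip
  set.seed(1)
  x <- runif(200, 0, 60); y <- runif(200, 0, 40)
  hits <- sapply(sc1$divisions, function(p) point_in_convex(x, y, p))
  expect_true(all(rowSums(hits) >= 1))  # strips share boundary edges
  expect_equal(sum(sapply(sc1$divisions, poly_area)), 60 * 40)

  expect_error(generate_seascape(seascape_config(extent_km = c(0, 0, -5, 10))),
               "invalid extent")
})

test_that("a uniform density field integrates to density times area", {
  d <- 0.0017
  sc <- flat_uniform_scape(density = d)
  expect_equal(true_biomass_t(sc), d * 60 * 40 * 1e6 / 1000, tolerance = 1e-12)
})

test_that("tow sampling honours the 100 percent catchability contract", {
  sc <- small_scape()
  tows <- sample_rv_tows(sc, 300, seed = 9)
  dens <- raster_at(sc$grid, sc$true_density, tows$x, tows$y)
  expect_equal(tows$catch_kg / tows$swept_area_m2, dens)
  expect_true(all(tows$catch_kg >= 0))
  # gear is consistent with its swept area
  expect_true(all(tows$swept_area_m2[tows$gear == "Campelen"] == 67000))
  expect_true(all(tows$swept_area_m2[tows$gear == "Lofoten"] == 39000))
  # a hand-checked density: 0.0017 kg/m2 under a Campelen tow is 113.9 kg
  expect_equal(0.0017 * 67000, 113.9)
  expect_error(sample_rv_tows(sc, 10, gear_by_division = c("3L" = "Campelen")),
               "no gear mapped")
})

test_that("mean catch over many tows recovers density times swept area", {
  d <- 0.003
  sc <- flat_uniform_scape(density = d)
  tows <- sample_rv_tows(sc, 1000, seed = 5)
  # deterministic catch on a uniform field: every tow equals d * swept area
  expect_equal(mean(tows$catch_kg[tows$gear == "Campelen"]), d * 67000)
  expect_equal(mean(tows$catch_kg[tows$gear == "Lofoten"]), d * 39000)
})

test_that("simulated VMS has the promised leg structure", {
  sc <- small_scape()
  expect_equal(nrow(simulate_vms(sc, n_vessels = 0)), 0)

  pings <- simulate_vms(sc, n_vessels = 3, n_tows_per_vessel = 4, seed = 8)
  # timestamps strictly increasing per vessel
  for (v in unique(pings$vessel_id)) {
    tt <- pings$timestamp[pings$vessel_id == v]
    expect_true(all(diff(as.numeric(tt)) > 0))
  }
  expect_true(all(pings$speed_kn >= 0))
  # an 18 nm fishing leg at 3 kn with hourly pings emits 7 slow pings
  one <- simulate_vms(sc, n_vessels = 1, n_tows_per_vessel = 1, seed = 2)
  runs <- rle(one$speed_kn < 6)
  expect_equal(runs$lengths[runs$values], 7)
  # all-steaming vessels produce no tracks, hence an empty footprint
  steam <- simulate_vms(sc, n_vessels = 2, n_tows_per_vessel = 0, seed = 2)
  expect_true(all(steam$speed_kn >= 6))
  fp <- union_footprint(lapply(build_tracks(steam), track_to_swath))
  expect_equal(fp$area_km2, 0)
})

test_that("catch tables: fixture rows and seeded reproducibility", {
  tb <- make_catch_table(list(fixture = "table4"))
  cod10 <- tb[tb$species == "Atlantic cod" & tb$year == 2010, ]
  expect_equal(cod10$catch_t, 9564)
  expect_equal(sum(tb$catch_t[tb$year == 2010]), 23817)
  expect_equal(sum(tb$catch_t[tb$year == 2011]), 24879)
  expect_equal(sum(tb$catch_t[tb$year == 2012]), 18919)

  expect_equal(nrow(make_catch_table(list(species = character()))), 0)
  r1 <- make_catch_table(seed = 11)
  r2 <- make_catch_table(seed = 11)
  expect_identical(r1, r2)
  expect_true(all(r1$catch_t >= 0) && all(r1$unit_price_usd_per_t >= 0))
})
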