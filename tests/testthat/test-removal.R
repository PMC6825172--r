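uniform_surface <- function(density, extent = c(0, 0, 50, 25), cell_km = 5) {
  g <- grid_for_extent(extent, cell_km)
  b <- matrix(density * cell_km^2 * 1e6 / 1000, g$n_row, g$n_col)
  structure(list(grid = g, biomass_t = b, mask = b > -1), class = "model_surface")
}

test_that("per-cell removal is trawled fraction times biomass", {
  # a 1 km2 swath inside one 25 km2 cell holding 50 t removes 2 t
  surf <- uniform_surface(50 * 1000 / 25e6)   # 50 t per cell
  sw <- track_to_swath(rbind(c(1, 2.5), c(11, 2.5)), 100)  # 1 km2, cells 1-3
  rem <- removal_by_cell(union_footprint(list(sw)), surf)
  expect_equal(attr(rem, "total_removal_t"), 2.0, tolerance = 1e-9)
  one_cell <- rem[rem$col == 1, ]
  expect_equal(one_cell$trawled_frac, 0.4 / 25, tolerance = 1e-9)
  expect_equal(one_cell$removal_t, 0.04 * 50 * 0.4, tolerance = 1e-9)
  # halving the removal rate halves every cell's removal
  rem50 <- removal_by_cell(union_footprint(list(sw)), surf, removal_rate = 0.5)
  expect_equal(rem50$removal_t, rem$removal_t / 2)
  # a footprint disjoint from all biomass removes nothing
  far <- track_to_swath(rbind(c(100, 100), c(110, 100)), 100)
  expect_equal(attr(removal_by_cell(union_footprint(list(far)), surf), "total_removal_t"), 0)
})

test_that("removal conserves mass and matches the area x density oracle", {
  d <- 0.02
  surf <- uniform_surface(d)
  set.seed(17)
  swaths <- lapply(1:8, function(i) {
    x <- runif(1, 5, 40); y <- runif(1, 3, 22); a <- runif(1, 0, pi)
    len <- runif(1, 4, 12)
    track_to_swath(rbind(c(x, y), c(x + len * cos(a), y + len * sin(a))), 100)
  })
  fp <- union_footprint(swaths, region = rect_poly(0, 0, 50, 25))
  rem <- removal_by_cell(fp, surf)
  # per cell, removal never exceeds standing biomass
  expect_true(all(rem$removal_t <= rem$biomass_t + 1e-9))
  expect_lte(attr(rem, "total_removal_t"), attr(rem, "total_biomass_t"))
  # on a uniform field removal equals footprint area x density
  oracle_t <- fp$area_km2 * d * 1e6 / 1000
  expect_equal(attr(rem, "total_removal_t"), oracle_t, tolerance = 0.005)
  # linearity in biomass scaling
  surf2 <- surf; surf2$biomass_t <- surf$biomass_t * 3
  rem3 <- removal_by_cell(fp, surf2)
  expect_equal(attr(rem3, "total_removal_t"), 3 * attr(rem, "total_removal_t"),
               tolerance = 1e-9)
})

test_that("removal percentages use an explicit reference biomass", {
  expect_equal(removal_percent(2580, 116143), 2.2)
  expect_equal(removal_percent(661, 81169), 0.8)
  expect_equal(removal_percent(0, 1000), 0)
  expect_error(removal_percent(10, 0), "positive")
})

test_that("simulated closure trawls follow the length rules and sum exactly", {
  sc <- small_scape(seed = 7)
  surf <- structure(list(grid = sc$grid,
                         biomass_t = sc$true_density * sc$config$res_km^2 * 1e6 / 1000),
                    class = "model_surface")
  # lengths scaled to the small test closures so every set fits
  sim <- simulate_closure_trawls(sc, surf, n = 12, seed = 3,
                                 length_nm = 5, small_lengths_nm = c(2, 3))
  expect_equal(nrow(sim$trawls), 12)
  expect_true(all(sim$trawls$removal_t >= 0))
  # default length except in the two smallest closures
  areas <- vapply(sc$closures, function(cl) poly_area(cl$poly), 0)
  small_codes <- vapply(sc$closures, `[[`, 0L, "code")[order(areas)][1:2]
  lens <- sim$trawls$length_nm
  in_small <- sim$trawls$closure %in% small_codes
  expect_true(all(lens[in_small] < 3.5))
  expect_true(all(abs(lens[!in_small] - 5) < 0.01))
  # mean x n equals the total exactly
  expect_equal(sim$mean_removal_t * nrow(sim$trawls), sim$total_removal_t)
  # same seed reproduces the simulation
  sim2 <- simulate_closure_trawls(sc, surf, n = 12, seed = 3,
                                  length_nm = 5, small_lengths_nm = c(2, 3))
  expect_equal(sim$trawls, sim2$trawls)
  # a closure too small for the requested effort shortens with a warning:
  # eight 30 nm swaths cannot pack without overlap into one 6 x 6 km closure
  sc1 <- generate_seascape(seascape_config(
    extent_km = c(0, 0, 60, 40), res_km = 2, n_patches = 6,
    n_closures = 1, closure_halfwidth_km = c(3, 3), seed = 7))
  surf1 <- structure(list(grid = sc1$grid,
                          biomass_t = sc1$true_density * sc1$config$res_km^2 * 1e6 / 1000),
                     class = "model_surface")
  suppressWarnings(expect_warning(
    simulate_closure_trawls(sc1, surf1, n = 8, seed = 4, length_nm = 30),
    "shortened"))
})

test_that("an 18 nm trawl on a uniform ground removes L x W x density", {
  d <- 0.02   # kg m-2, the closure-scale density of the densest grounds
  surf <- uniform_surface(d, extent = c(0, 0, 50, 25), cell_km = 5)
  sw <- track_to_swath(rbind(c(5, 12.5), c(5 + 18 * 1.852, 12.5)), 100)
  rem <- removal_by_cell(sw$quads, surf)
  expect_equal(attr(rem, "total_removal_t"), 33.336 * 0.1 * d * 1e6 / 1000,
               tolerance = 1e-9)
  expect_equal(round(attr(rem, "total_removal_t"), 1), 66.7)
})

test_that("trawls-to-depletion applies a ceiling under non-overlap", {
  expect_equal(trawls_to_depletion(0, 29.5), 0L)
  expect_equal(trawls_to_depletion(29.5, 29.5), 1L)
  expect_equal(trawls_to_depletion(29.51, 29.5), 2L)
  expect_equal(trawls_to_depletion(884, 884 / 30), 30L)
  expect_error(trawls_to_depletion(100, 0), "positive")
})
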