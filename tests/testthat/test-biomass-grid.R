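make_tow <- function(x, y, gear, catch_kg, id = 1) {
  data.frame(tow_id = id, x = x, y = y, division = "3M", gear = gear,
             swept_area_m2 = c(Campelen = 67000, Lofoten = 39000)[[gear]],
             catch_kg = catch_kg)
}

test_that("trawls-per-cell factors match the gear swept areas", {
  expect_equal(trawls_per_cell("Campelen")$rounded, 373)
  expect_equal(trawls_per_cell("Campelen")$unrounded, 25e6 / 67000)
  expect_equal(trawls_per_cell("Lofoten")$rounded, 641)
  expect_equal(trawls_per_cell("Lofoten")$unrounded, 25e6 / 39000)
  expect_equal(trawls_per_cell(25e6)$unrounded, 1)
  expect_error(trawls_per_cell("Otter"), "unknown gear")
})

test_that("cell means scale tow catch to whole-cell biomass", {
  g <- grid_for_extent(c(0, 0, 20, 10), 5)
  # one Lofoten tow of 100 kg: 100 * (25e6/39000) / 1000 = 64.103 t
  bg <- cell_mean_biomass(make_tow(2, 2, "Lofoten", 100), g)
  expect_equal(bg$biomass_t[1, 1], 100 * (25e6 / 39000) / 1000)
  expect_equal(round(bg$biomass_t[1, 1], 3), 64.103)
  # two Campelen tows 50 and 150 kg in one cell: mean 100 kg -> 37.313 t
  tows <- rbind(make_tow(2, 2, "Campelen", 50, 1), make_tow(3, 3, "Campelen", 150, 2))
  bg <- cell_mean_biomass(tows, g)
  expect_equal(round(bg$biomass_t[1, 1], 3), 37.313)
  # zero catch is an observed zero, not an empty cell
  bg <- cell_mean_biomass(make_tow(7, 2, "Campelen", 0), g)
  expect_equal(bg$biomass_t[1, 2], 0)
  expect_equal(bg$source_out[1, 2], "observed")
  expect_equal(bg$source_out[1, 1], "empty")
  # tows outside the grid are rejected with a message
  expect_message(cell_mean_biomass(make_tow(999, 2, "Campelen", 10), g), "rejected")
})

test_that("focal fill averages observed neighbours once and only once", {
  g <- grid_for_extent(c(0, 0, 20, 15), 5)
  tows <- rbind(make_tow(2, 2, "Campelen", 10 / 0.3731343284, 1),
                make_tow(7, 2, "Campelen", 20 / 0.3731343284, 2),
                make_tow(12, 7, "Campelen", 30 / 0.3731343284, 3))
  bg <- cell_mean_biomass(tows, g)
  # cell (2,2) is empty with populated neighbours 10, 20, 30 -> mean 20
  expect_true(is.na(bg$biomass_t[2, 2]))
  filled <- focal_fill(bg)
  expect_equal(filled$biomass_t[2, 2], 20, tolerance = 1e-9)
  expect_equal(filled$source_out[2, 2], "focal_filled")
  # observed cells unchanged; populated count never decreases
  expect_equal(filled$biomass_t[1, 1], bg$biomass_t[1, 1])
  expect_gte(sum(!is.na(filled$biomass_t)), sum(!is.na(bg$biomass_t)))
  # empty cell with no observed neighbour stays empty: single-pass fill
  # does not cascade through freshly filled values
  expect_true(is.na(filled$biomass_t[3, 1]))
  # a fill pass on a fully populated grid is the identity
  g1 <- grid_for_extent(c(0, 0, 10, 5), 5)
  tows2 <- rbind(make_tow(2, 2, "Campelen", 100, 1), make_tow(7, 2, "Campelen", 50, 2))
  full <- cell_mean_biomass(tows2, g1)
  expect_equal(focal_fill(full)$biomass_t, full$biomass_t)
})

test_that("closure strata are estimated and merged geometrically", {
  g <- grid_for_extent(c(0, 0, 10, 5), 5)
  # closure covers the west half of cell (1,1)
  closures <- list(list(code = 1L, poly = rect_poly(0, 0, 2.5, 5)))
  tows <- rbind(make_tow(1, 2, "Campelen", 200, 1),    # inside closure
                make_tow(4, 2, "Campelen", 40, 2))     # outside, same cell
  bg <- cell_mean_biomass(tows, g, closures)
  b_in <- 200 * (25e6 / 67000) / 1000
  b_out <- 40 * (25e6 / 67000) / 1000
  expect_equal(bg$biomass_in[1, 1], b_in)
  expect_equal(bg$biomass_out[1, 1], b_out)
  expect_equal(bg$frac_in[1, 1], 0.5)
  expect_equal(bg$biomass_t[1, 1], 0.5 * b_in + 0.5 * b_out)
  # the two half-cells report their stratum-specific estimates
  expect_equal(total_biomass(bg, rect_poly(0, 0, 2.5, 5)), b_in / 2)
  expect_equal(total_biomass(bg, rect_poly(2.5, 0, 5, 5)), b_out / 2)
  expect_equal(total_biomass(bg), 0.5 * b_in + 0.5 * b_out)
})

test_that("grid totals weight cells by their fractional area in a region", {
  g <- grid_for_extent(c(0, 0, 20, 10), 5)
  tows <- do.call(rbind, lapply(1:8, function(i) {
    make_tow(((i - 1) %% 4) * 5 + 2, ((i - 1) %/% 4) * 5 + 2, "Campelen",
             10 * 1000 / (25e6 / 67000), i)  # 10 t per cell
  }))
  bg <- cell_mean_biomass(tows, g)
  expect_equal(total_biomass(bg), 80, tolerance = 1e-9)
  # region covering exactly 2 of the 8 cells
  expect_equal(total_biomass(bg, rect_poly(0, 0, 10, 5)), 20, tolerance = 1e-9)
  expect_warning(out <- total_biomass(bg, rect_poly(1, 1, 1, 1)), "empty region")
  expect_equal(out, 0)
})

test_that("the grid estimator recovers a known synthetic biomass total", {
  sc <- small_scape(seed = 7)
  g5 <- grid_for_extent(sc$extent_km, 5)
  # about 12 tows per 5 km cell over a 60 x 40 km extent
  tows <- sample_rv_tows(sc, 1200, seed = 21)
  bg <- focal_fill(cell_mean_biomass(tows, g5, sc$closures))
  expect_equal(total_biomass(bg), true_biomass_t(sc), tolerance = 0.05)
})
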