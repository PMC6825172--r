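test_that("training tables standardize catch to density", {
  sc <- small_scape()
  tows <- sample_rv_tows(sc, 60, seed = 2)
  tb <- make_training_table(tows, sc)
  expect_equal(nrow(tb), 60)
  expect_named(tb, c("response", names(sc$covariates)))
  expect_false(anyNA(tb))
  expect_equal(tb$response, tows$catch_kg / tows$swept_area_m2)
  # a 113.9 kg Campelen catch standardizes to 0.0017 kg m-2
  expect_equal(113.9 / 67000, 0.0017)
  # raw-catch mode preserved as an option
  tb2 <- make_training_table(tows, sc, response = "catch")
  expect_equal(tb2$response, tows$catch_kg)
  # tows off the covariate extent are dropped with a message
  tows$x[1] <- 1e4
  expect_message(tb3 <- make_training_table(tows, sc), "dropped")
  expect_equal(nrow(tb3), 59)
})

test_that("cross-validation separates signal from noise and is seeded", {
  set.seed(123)
  n <- 400
  x1 <- runif(n); x2 <- runif(n)
  cfg <- rf_config(n_trees = 200, cv_repeats = 2, seed = 77)
  # noiseless smooth response: held-out R2 is high
  smooth <- data.frame(response = x1^2 + sin(2 * pi * x2), x1 = x1, x2 = x2)
  fit_s <- fit_and_validate(smooth, cfg)
  expect_gte(fit_s$cv_r2_mean, 0.8)
  # pure noise: held-out R2 is near zero or negative
  noise <- data.frame(response = rnorm(n), x1 = x1, x2 = x2)
  fit_n <- fit_and_validate(noise, cfg)
  expect_lte(fit_n$cv_r2_mean, 0.1)
  # seeded: identical config gives identical R2 values
  fit_s2 <- fit_and_validate(smooth, cfg)
  expect_identical(fit_s$cv_r2, fit_s2$cv_r2)
  expect_equal(fit_s$config$min_node_size, 5)
  expect_error(fit_and_validate(smooth[1:5, ], rf_config(cv_folds = 10)),
               "at least")
})

test_that("prediction masks the 50-2000 m depth window", {
  sc <- small_scape(seed = 11)
  tows <- sample_rv_tows(sc, 300, seed = 12)
  fit <- fit_and_validate(make_training_table(tows, sc),
                          rf_config(n_trees = 100, cv_repeats = 1, seed = 1))
  surf <- predict_surface(fit, sc)
  deep <- sc$bathymetry > 2000 | sc$bathymetry < 50
  expect_true(all(is.na(surf$biomass_t[deep])))
  expect_true(all(surf$biomass_t[!deep] >= 0))
  # a constant-zero response predicts an identically zero surface
  zero_tb <- make_training_table(tows, sc)
  zero_tb$response <- 0
  zfit <- suppressWarnings(  # the engine warns on a degenerate constant response
    fit_and_validate(zero_tb, rf_config(n_trees = 50, cv_repeats = 1, seed = 1)))
  zsurf <- predict_surface(zfit, sc)
  expect_true(all(zsurf$biomass_t[!deep] == 0))
  # shrinking the depth window never increases integrated biomass
  narrow <- predict_surface(fit, sc, depth_range_m = c(200, 1500))
  expect_lte(integrate_biomass(narrow), integrate_biomass(surf))
})

test_that("integration is additive over disjoint division polygons", {
  sc <- small_scape(seed = 11)
  tows <- sample_rv_tows(sc, 300, seed = 12)
  fit <- fit_and_validate(make_training_table(tows, sc),
                          rf_config(n_trees = 100, cv_repeats = 1, seed = 1))
  surf <- predict_surface(fit, sc)
  total <- integrate_biomass(surf)
  parts <- vapply(sc$divisions, function(p)
    suppressWarnings(integrate_biomass(surf, p)), 0)  # deep strips warn as fully masked
  expect_equal(sum(parts), total, tolerance = 1e-6)
  # fully masked region warns and returns zero
  deep_cells <- which(sc$bathymetry > 2000, arr.ind = TRUE)
  expect_warning(
    out <- integrate_biomass(surf, cell_poly(sc$grid, deep_cells[1, 1], deep_cells[1, 2])),
    "masked")
  expect_equal(out, 0)
})

test_that("the model recovers a known biomass total from dense training", {
  sc <- small_scape(seed = 5)
  tows <- sample_rv_tows(sc, 1500, seed = 6)
  fit <- fit_and_validate(make_training_table(tows, sc),
                          rf_config(n_trees = 300, cv_repeats = 1, seed = 9))
  surf <- predict_surface(fit, sc)
  truth <- true_biomass_t(sc)
  expect_equal(integrate_biomass(surf), truth, tolerance = 0.15)
  # mean-density identity: total biomass over unmasked area gives back the
  # average density (paper-style arithmetic at 2 significant figures)
  area_km2 <- sum(surf$mask) * cell_area_km2(surf$grid)
  mean_dens <- integrate_biomass(surf) * 1000 / (area_km2 * 1e6)
  true_dens <- truth * 1000 / (area_km2 * 1e6)
  expect_equal(signif(mean_dens, 1), signif(true_dens, 1))
})
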