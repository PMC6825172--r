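# Modelling approach: random-forest regression of sponge biomass density
# on environmental covariates, repeated k-fold cross-validation, and
# prediction over the seascape restricted to the 50-2000 m depth window.

#' Random-forest configuration
#'
#' Defaults follow the biomass model: 1000 regression trees, two candidate
#' variables per split, the regression default terminal-node size (5,
#' echoed into the fit report), and 10-fold cross-validation repeated 10
#' times.
#'
#' @param n_trees Number of trees.
#' @param vars_per_split Candidate variables per split (mtry).
#' @param min_node_size Minimum terminal-node size; `NULL` uses the
#'   regression default of the engine (5) and records it.
#' @param cv_folds,cv_repeats Cross-validation design.
#' @param seed Integer seed.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_trees = 1000, vars_per_split = 2, min_node_size = NULL,
                      cv_folds = 10, cv_repeats = 10, seed = 1L) {
  stopifnot(n_trees >= 1, vars_per_split >= 1, cv_folds >= 2, cv_repeats >= 1)
  structure(list(n_trees = n_trees, vars_per_split = vars_per_split,
                 min_node_size = min_node_size %||% 5,
                 cv_folds = cv_folds, cv_repeats = cv_repeats, seed = seed),
            class = "rf_config")
}

#' Training table from tows and seascape covariates
#'
#' The response standardizes each tow catch to a density (kg m^-2,
#' `catch_kg / swept_area_m2`) so the two gears are comparable; the raw
#' catch can be used instead via `response = "catch"`. Features are the
#' covariate rasters sampled at tow midpoints. Tows outside the covariate
#' extent are dropped with a message.
#'
#' @param tows Tow data frame (see [sample_rv_tows()]).
#' @param seascape A `seascape` supplying the covariate stack.
#' @param response `"density"` (default) or `"catch"`.
#' @return Data frame with column `response` then one column per covariate.
#' @export
make_training_table <- function(tows, seascape, response = c("density", "catch")) {
  response <- match.arg(response)
  feats <- lapply(seascape$covariates, function(v)
    raster_at(seascape$grid, v, tows$x, tows$y))
  feats <- as.data.frame(feats)
  drop <- !stats::complete.cases(feats)
  if (any(drop)) {
    message(sum(drop), " tow(s) outside the covariate extent dropped")
    tows <- tows[!drop, , drop = FALSE]
    feats <- feats[!drop, , drop = FALSE]
  }
  y <- if (response == "density") tows$catch_kg / tows$swept_area_m2 else tows$catch_kg
  cbind(data.frame(response = y), feats)
}

fit_forest <- function(table, cfg, seed) {
  set.seed(seed)
  randomForest::randomForest(
    x = table[, -1, drop = FALSE], y = table$response,
    ntree = cfg$n_trees,
    mtry = min(cfg$vars_per_split, ncol(table) - 1),
    nodesize = cfg$min_node_size)
}

#' Fit the biomass forest with repeated cross-validation
#'
#' Out-of-sample R-squared (1 - SSE/SST about the held-out mean) is
#' computed on every held-out fold of a `cv_repeats` x `cv_folds` design;
#' the summary is the mean and SD over all folds. The returned model is
#' refit on the full table. Fully seeded: the same seed reproduces the
#' same folds, forests and R-squared values.
#'
#' @param table Training table from [make_training_table()].
#' @param config An [rf_config()].
#' @return List: `model`, `cv_r2_mean`, `cv_r2_sd`, `cv_r2` (per fold),
#'   `config` (with the realized `min_node_size` echoed).
#' @export
fit_and_validate <- function(table, config = rf_config()) {
  cfg <- config
  n <- nrow(table)
  if (n < cfg$cv_folds)
    stop("need at least cv_folds = ", cfg$cv_folds, " rows, got ", n)
  r2 <- numeric(0)
  for (rep_i in seq_len(cfg$cv_repeats)) {
    set.seed(cfg$seed + 1000L * rep_i)
    fold <- sample(rep(seq_len(cfg$cv_folds), length.out = n))
    for (k in seq_len(cfg$cv_folds)) {
      test <- fold == k
      fit <- fit_forest(table[!test, , drop = FALSE], cfg,
                        seed = cfg$seed + 1000L * rep_i + k)
      pred <- stats::predict(fit, table[test, -1, drop = FALSE])
      obs <- table$response[test]
      sst <- sum((obs - mean(obs))^2)
      r2 <- c(r2, if (sst > 0) 1 - sum((obs - pred)^2) / sst else NA_real_)
    }
  }
  model <- fit_forest(table, cfg, seed = cfg$seed)
  list(model = model,
       cv_r2_mean = mean(r2, na.rm = TRUE),
       cv_r2_sd = stats::sd(r2, na.rm = TRUE),
       cv_r2 = r2, config = cfg)
}

#' Predict the biomass surface over a seascape
#'
#' Predicts density on every raster cell, converts to tonnes per cell, and
#' masks cells whose depth falls outside `depth_range_m` (default
#' 50-2000 m, the observed bathymetric envelope of these sponge grounds).
#'
#' @param fit Result of [fit_and_validate()] (or a bare randomForest).
#' @param seascape A `seascape` with aligned covariates and bathymetry.
#' @param depth_range_m Valid depth window, m.
#' @return A `model_surface`: `grid`, `density` (kg m^-2, NA where
#'   masked), `biomass_t` (t per cell, NA where masked), `mask` (logical
#'   matrix of valid cells), `depth_range_m`.
#' @export
predict_surface <- function(fit, seascape, depth_range_m = c(50, 2000)) {
  model <- if (inherits(fit, "randomForest")) fit else fit$model
  grid <- seascape$grid
  dims <- vapply(seascape$covariates, function(v) all(dim(v) == dim(seascape$bathymetry)), TRUE)
  if (!all(dims)) stop("covariate rasters are not aligned with the bathymetry")
  newdata <- as.data.frame(lapply(seascape$covariates, as.vector))
  dens <- matrix(stats::predict(model, newdata), grid$n_row, grid$n_col)
  mask <- seascape$bathymetry >= depth_range_m[1] & seascape$bathymetry <= depth_range_m[2]
  dens[!mask] <- NA_real_
  structure(list(grid = grid, density = dens,
                 biomass_t = dens * cell_area_km2(grid) * 1e6 / 1000,
                 mask = mask, depth_range_m = depth_range_m),
            class = "model_surface")
}

#' @export
print.model_surface <- function(x, ...) {
  cat(sprintf("model_surface: %d x %d cells, %d valid (%g-%g m), total %.0f t\n",
              x$grid$n_row, x$grid$n_col, sum(x$mask),
              x$depth_range_m[1], x$depth_range_m[2],
              sum(x$biomass_t, na.rm = TRUE)))
  invisible(x)
}

#' Integrate a model surface over a region
#'
#' Area-weighted sum over unmasked cells: each cell contributes its
#' biomass times the fraction of the cell inside the region.
#'
#' @param surface A `model_surface` (or any list with `grid` and
#'   `biomass_t`).
#' @param region Convex polygon (km), or `NULL` for the whole surface.
#' @return Tonnes wet weight.
#' @export
integrate_biomass <- function(surface, region = NULL) {
  grid <- surface$grid
  b <- surface$biomass_t
  if (is.null(region)) return(sum(b, na.rm = TRUE))
  if (poly_area(region) <= 0) {
    warning("empty region; integrated biomass is 0")
    return(0)
  }
  bb <- poly_bbox(region)
  a_cell <- cell_area_km2(grid)
  total <- 0
  any_valid <- FALSE
  for (r in seq_len(grid$n_row)) for (co in seq_len(grid$n_col)) {
    cellp <- cell_poly(grid, r, co)
    if (!bbox_overlaps(poly_bbox(cellp), bb)) next
    p <- clip_convex(cellp, region)
    if (is.null(p)) next
    if (is.na(b[r, co])) next
    any_valid <- TRUE
    total <- total + b[r, co] * poly_area(p) / a_cell
  }
  if (!any_valid) warning("region is fully masked; integrated biomass is 0")
  total
}
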