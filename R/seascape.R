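# Synthetic seascape generator.
#
# Emulates the statistical structure the downstream analysis assumes: a
# bathyal cap rising from deep water, a patchy sponge biomass density field
# confined to a 50-2000 m depth window, environmental covariate rasters,
# fishery closures over the densest grounds, and division polygons
# partitioning the extent. Everything is seeded and planar (km).

GEAR_SWEPT_M2 <- c(Campelen = 67000, Lofoten = 39000)
NM_KM <- 1.852
KN_KM_H <- 1.852

#' Configuration for a synthetic seascape
#'
#' Defaults emulate the study system: a ~60,000 km^2 planar extent around a
#' bathyal cap (140-3000 m), sponge density as a sum of Gaussian patches
#' with log-normal amplitudes on a depth taper (area-mean density of order
#' 0.002 kg m^-2, patch peaks up to ~0.1 kg m^-2, zero beyond 2000 m),
#' six closures over the densest patches and four division strips.
#'
#' @param extent_km Bounding box `c(xmin, ymin, xmax, ymax)`, km.
#' @param res_km Raster resolution, km.
#' @param depth_shallow_m,depth_deep_m Cap summit and basin depths, m
#'   (positive down). Equal values give a flat seafloor.
#' @param depth_window_m Habitable depth window; density is zero outside.
#' @param depth_peak_m,depth_taper_sd_m Gaussian depth taper of density.
#' @param n_patches Number of Gaussian density patches.
#' @param patch_sd_km Range of patch standard deviations, km.
#' @param patch_amp_meanlog,patch_amp_sdlog Log-normal patch peak
#'   amplitudes, kg m^-2.
#' @param patch_amplitude_scale Overall multiplier on patch amplitudes
#'   (0 gives an identically zero density field).
#' @param uniform_density_kg_m2 If non-`NULL`, overrides the patch field
#'   with a uniform density inside the depth window.
#' @param n_closures Number of closure rectangles.
#' @param closure_halfwidth_km Range of closure half-widths, km.
#' @param division_breaks Fractions of the x-extent at which the four
#'   division strips split.
#' @param seed Integer seed; required for reproducibility.
#' @return A `seascape_config` list.
#' @export
seascape_config <- function(extent_km = c(0, 0, 300, 200),
                            res_km = 2,
                            depth_shallow_m = 140,
                            depth_deep_m = 3000,
                            depth_window_m = c(50, 2000),
                            depth_peak_m = 1100,
                            depth_taper_sd_m = 500,
                            n_patches = 25,
                            patch_sd_km = c(5, 12),
                            patch_amp_meanlog = log(0.025),
                            patch_amp_sdlog = 0.8,
                            patch_amplitude_scale = 1,
                            uniform_density_kg_m2 = NULL,
                            n_closures = 6,
                            closure_halfwidth_km = c(5, 16),
                            division_breaks = c(0.20, 0.65, 0.95),
                            seed = 1L) {
  if (extent_km[3] <= extent_km[1] || extent_km[4] <= extent_km[2])
    stop("invalid extent: xmax/ymax must exceed xmin/ymin")
  if (res_km <= 0) stop("res_km must be positive")
  structure(as.list(environment()), class = "seascape_config")
}

# Smooth random field as a sum of Gaussian bumps; returns matrix over grid.
gaussian_bump_field <- function(grid, n, sd_range, amps, centers_x, centers_y) {
  cc <- cell_centers(grid)
  f <- matrix(0, grid$n_row, grid$n_col)
  X <- matrix(cc$x, grid$n_row, grid$n_col, byrow = TRUE)
  Y <- matrix(cc$y, grid$n_row, grid$n_col)
  for (k in seq_len(n)) {
    s2 <- sd_range[k]^2
    f <- f + amps[k] * exp(-((X - centers_x[k])^2 + (Y - centers_y[k])^2) / (2 * s2))
  }
  f
}

#' Generate a synthetic seascape
#'
#' @param config A [seascape_config()].
#' @return A `seascape` object: grid, `bathymetry` (depth m, positive
#'   down), named `covariates` rasters (`depth`, `slope`, `habitat`,
#'   `current`), `true_density` (kg m^-2), `closures` (list of
#'   `list(code, poly)`), named `divisions` polygons, and the config.
#' @export
generate_seascape <- function(config = seascape_config()) {
  cfg <- config
  set.seed(cfg$seed)
  grid <- grid_for_extent(cfg$extent_km, cfg$res_km)
  cc <- cell_centers(grid)
  X <- matrix(cc$x, grid$n_row, grid$n_col, byrow = TRUE)
  Y <- matrix(cc$y, grid$n_row, grid$n_col)

  # bathymetric cap: Gaussian rise from the basin depth
  W <- cfg$extent_km[3] - cfg$extent_km[1]
  H <- cfg$extent_km[4] - cfg$extent_km[2]
  cx <- cfg$extent_km[1] + 0.45 * W
  cy <- cfg$extent_km[2] + 0.50 * H
  sx <- 0.25 * W; sy <- 0.30 * H
  bathy <- cfg$depth_deep_m - (cfg$depth_deep_m - cfg$depth_shallow_m) *
    exp(-((X - cx)^2 / (2 * sx^2) + (Y - cy)^2 / (2 * sy^2)))

  # slope (m per km) from central differences
  gx <- bathy; gy <- bathy
  gx[] <- 0; gy[] <- 0
  if (grid$n_col > 2) gx[, 2:(grid$n_col - 1)] <-
    (bathy[, 3:grid$n_col] - bathy[, 1:(grid$n_col - 2)]) / (2 * cfg$res_km)
  if (grid$n_row > 2) gy[2:(grid$n_row - 1), ] <-
    (bathy[3:grid$n_row, ] - bathy[1:(grid$n_row - 2), ]) / (2 * cfg$res_km)
  slope <- sqrt(gx^2 + gy^2)

  # patchy habitat field: Gaussian bumps with log-normal amplitudes
  n <- cfg$n_patches
  patch_x <- stats::runif(n, cfg$extent_km[1], cfg$extent_km[3])
  patch_y <- stats::runif(n, cfg$extent_km[2], cfg$extent_km[4])
  patch_sd <- stats::runif(n, cfg$patch_sd_km[1], cfg$patch_sd_km[2])
  patch_amp <- stats::rlnorm(n, cfg$patch_amp_meanlog, cfg$patch_amp_sdlog) *
    cfg$patch_amplitude_scale
  habitat <- gaussian_bump_field(grid, n, patch_sd, patch_amp, patch_x, patch_y)

  # nuisance covariate: independent smooth field
  m <- 12
  current <- gaussian_bump_field(
    grid, m, stats::runif(m, 15, 40), stats::rlnorm(m, 0, 0.5),
    stats::runif(m, cfg$extent_km[1], cfg$extent_km[3]),
    stats::runif(m, cfg$extent_km[2], cfg$extent_km[4]))

  taper <- exp(-0.5 * ((bathy - cfg$depth_peak_m) / cfg$depth_taper_sd_m)^2)
  habitable <- bathy >= cfg$depth_window_m[1] & bathy <= cfg$depth_window_m[2]
  if (is.null(cfg$uniform_density_kg_m2)) {
    dens <- habitat * taper
  } else {
    dens <- matrix(cfg$uniform_density_kg_m2, grid$n_row, grid$n_col)
  }
  dens[!habitable] <- 0

  # closures over the strongest patches (by realized peak density, i.e.
  # amplitude times the depth taper at the patch centre), clamped inside
  closures <- list()
  if (cfg$n_closures > 0) {
    depth_at <- raster_at(grid, bathy, patch_x, patch_y)
    peak <- patch_amp * exp(-0.5 * ((depth_at - cfg$depth_peak_m) / cfg$depth_taper_sd_m)^2) *
      (depth_at >= cfg$depth_window_m[1] & depth_at <= cfg$depth_window_m[2])
    ord <- order(peak, decreasing = TRUE)
    k <- min(cfg$n_closures, n)
    hw <- stats::runif(k, cfg$closure_halfwidth_km[1], cfg$closure_halfwidth_km[2])
    for (i in seq_len(k)) {
      px <- patch_x[ord[i]]; py <- patch_y[ord[i]]
      x1 <- max(cfg$extent_km[1], px - hw[i]); x2 <- min(cfg$extent_km[3], px + hw[i])
      y1 <- max(cfg$extent_km[2], py - hw[i]); y2 <- min(cfg$extent_km[4], py + hw[i])
      closures[[i]] <- list(code = i, poly = rect_poly(x1, y1, x2, y2))
    }
  }

  # four division strips partitioning the extent west to east
  br <- c(0, cfg$division_breaks, 1)
  div_names <- c("3L", "3M", "3N", "3O")
  divisions <- stats::setNames(lapply(1:4, function(i) {
    rect_poly(cfg$extent_km[1] + br[i] * W, cfg$extent_km[2],
              cfg$extent_km[1] + br[i + 1] * W, cfg$extent_km[4])
  }), div_names)

  structure(list(
    extent_km = cfg$extent_km, grid = grid,
    bathymetry = bathy, grad_x = gx, grad_y = gy,
    covariates = list(depth = bathy, slope = slope,
                      habitat = habitat, current = current),
    true_density = dens, closures = closures, divisions = divisions,
    config = cfg, seed = cfg$seed), class = "seascape")
}

#' @export
print.seascape <- function(x, ...) {
  cat(sprintf("seascape: %g x %g km at %g km, %d closures, %d divisions\n",
              x$extent_km[3] - x$extent_km[1], x$extent_km[4] - x$extent_km[2],
              x$config$res_km, length(x$closures), length(x$divisions)))
  cat(sprintf("  true biomass: %.0f t; habitable cells: %d\n",
              density_total_t(x$grid, x$true_density),
              sum(x$true_density > 0)))
  invisible(x)
}

#' Total true sponge biomass of a seascape
#'
#' Raster integral of the true density field.
#'
#' @param seascape A `seascape`.
#' @return Tonnes wet weight.
#' @export
true_biomass_t <- function(seascape) {
  density_total_t(seascape$grid, seascape$true_density)
}

#' Division membership of points
#'
#' @param seascape A `seascape`.
#' @param x,y Coordinates, km.
#' @return Character vector of division names (NA outside all divisions).
#' @export
division_of <- function(seascape, x, y) {
  out <- rep(NA_character_, length(x))
  for (nm in names(seascape$divisions)) {
    hit <- is.na(out) & point_in_convex(x, y, seascape$divisions[[nm]])
    out[hit] <- nm
  }
  out
}

#' Sample research-vessel survey tows
#'
#' Tow midpoints are drawn uniformly over the extent; the sponge catch of a
#' tow is the true density at the tow location times the gear swept area,
#' with 100 percent catchability, so `catch_kg / swept_area` recovers the
#' density exactly.
#'
#' @param seascape A `seascape`.
#' @param n_tows Number of tows (>= 1).
#' @param gear_by_division Named character vector mapping every division to
#'   `"Campelen"` (67,000 m^2 swept) or `"Lofoten"` (39,000 m^2).
#' @param seed Integer seed.
#' @return Data frame: `tow_id`, `x`, `y`, `division`, `gear`,
#'   `swept_area_m2`, `catch_kg`.
#' @export
sample_rv_tows <- function(seascape, n_tows,
                           gear_by_division = c("3L" = "Campelen", "3M" = "Lofoten",
                                                "3N" = "Campelen", "3O" = "Campelen"),
                           seed = 1L) {
  stopifnot(n_tows >= 1)
  missing_div <- setdiff(names(seascape$divisions), names(gear_by_division))
  if (length(missing_div))
    stop("no gear mapped for division(s): ", paste(missing_div, collapse = ", "))
  if (!all(gear_by_division %in% names(GEAR_SWEPT_M2)))
    stop("gear must be one of: ", paste(names(GEAR_SWEPT_M2), collapse = ", "))
  set.seed(seed)
  x <- stats::runif(n_tows, seascape$extent_km[1], seascape$extent_km[3])
  y <- stats::runif(n_tows, seascape$extent_km[2], seascape$extent_km[4])
  division <- division_of(seascape, x, y)
  gear <- unname(gear_by_division[division])
  swept <- unname(GEAR_SWEPT_M2[gear])
  dens <- raster_at(seascape$grid, seascape$true_density, x, y)
  data.frame(tow_id = seq_len(n_tows), x = x, y = y, division = division,
             gear = gear, swept_area_m2 = swept,
             catch_kg = dens * swept * 1.0)
}

# Unit tangent of the local isobath (perpendicular to the depth gradient);
# random direction on flats. `prev` keeps the heading sign-consistent.
contour_direction <- function(seascape, x, y, prev = NULL) {
  gx <- raster_at(seascape$grid, seascape$grad_x, x, y)
  gy <- raster_at(seascape$grid, seascape$grad_y, x, y)
  if (is.na(gx) || is.na(gy) || (gx^2 + gy^2) < 1e-12) {
    ang <- stats::runif(1, 0, 2 * pi)
    v <- c(cos(ang), sin(ang))
  } else {
    v <- c(-gy, gx) / sqrt(gx^2 + gy^2)
  }
  if (!is.null(prev) && sum(v * prev) < 0) v <- -v
  v
}

#' Simulate vessel-monitoring-system pings
#'
#' Each vessel alternates steaming legs (9 +/- 1 kn, truncated above
#' 6.5 kn) and contour-following fishing legs (3 +/- 0.3 kn, truncated
#' below 5.9 kn) emitting one ping per `ping_interval_h`. A fishing leg of
#' the default 18 nm at 3 kn lasts 6 h and so emits 7 pings. Headings turn
#' toward the extent centre near the boundary.
#'
#' @param seascape A `seascape`.
#' @param n_vessels Number of vessels (0 gives an empty ping set).
#' @param n_tows_per_vessel Fishing legs per vessel; 0 gives pure steaming.
#' @param ping_interval_h Hours between pings (> 0).
#' @param seed Integer seed.
#' @param trawl_length_nm Fishing leg length, nautical miles.
#' @param fishing_speed_kn,fishing_speed_sd Fishing speed distribution.
#' @param steam_speed_kn,steam_speed_sd Steaming speed distribution.
#' @return Data frame: `vessel_id`, `timestamp` (POSIXct, UTC), `x`, `y`,
#'   `speed_kn`, ordered by vessel and time.
#' @export
simulate_vms <- function(seascape, n_vessels = 10, n_tows_per_vessel = 8,
                         ping_interval_h = 1, seed = 1L,
                         trawl_length_nm = 18,
                         fishing_speed_kn = 3, fishing_speed_sd = 0.3,
                         steam_speed_kn = 9, steam_speed_sd = 1) {
  stopifnot(ping_interval_h > 0)
  empty <- data.frame(vessel_id = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                      x = numeric(), y = numeric(), speed_kn = numeric())
  if (n_vessels == 0) return(empty)
  set.seed(seed)
  ext <- seascape$extent_km
  centre <- c(mean(ext[c(1, 3)]), mean(ext[c(2, 4)]))
  margin <- 0.03 * min(ext[3] - ext[1], ext[4] - ext[2])
  t0 <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")
  draw_speed <- function(fishing) {
    if (fishing) min(stats::rnorm(1, fishing_speed_kn, fishing_speed_sd), 5.9)
    else max(stats::rnorm(1, steam_speed_kn, steam_speed_sd), 6.5)
  }
  rows <- vector("list", n_vessels)
  for (v in seq_len(n_vessels)) {
    pos <- c(stats::runif(1, ext[1] + margin, ext[3] - margin),
             stats::runif(1, ext[2] + margin, ext[4] - margin))
    t_h <- stats::runif(1, 0, 24)
    px <- numeric(0); py <- numeric(0); pt <- numeric(0); pv <- numeric(0)
    heading <- NULL
    emit_leg <- function(fishing, n_steps) {
      for (s in seq_len(n_steps)) {
        spd <- draw_speed(fishing)
        px <<- c(px, pos[1]); py <<- c(py, pos[2]); pt <<- c(pt, t_h); pv <<- c(pv, spd)
        if (fishing) {
          heading <<- contour_direction(seascape, pos[1], pos[2], heading)
          ang <- stats::rnorm(1, 0, 5 * pi / 180)
          R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
          heading <<- as.numeric(R %*% heading)
        } else if (is.null(heading)) {
          a <- stats::runif(1, 0, 2 * pi); heading <<- c(cos(a), sin(a))
        }
        step_km <- spd * KN_KM_H * ping_interval_h
        nxt <- pos + heading * step_km
        if (nxt[1] < ext[1] + margin || nxt[1] > ext[3] - margin ||
            nxt[2] < ext[2] + margin || nxt[2] > ext[4] - margin) {
          heading <<- (centre - pos) / sqrt(sum((centre - pos)^2))
          nxt <- pos + heading * step_km
        }
        pos <<- nxt
        t_h <<- t_h + ping_interval_h
      }
      # closing ping of the leg
      spd <- draw_speed(fishing)
      px <<- c(px, pos[1]); py <<- c(py, pos[2]); pt <<- c(pt, t_h); pv <<- c(pv, spd)
      t_h <<- t_h + ping_interval_h
    }
    fishing_steps <- max(1, round(trawl_length_nm / (fishing_speed_kn * ping_interval_h)))
    if (n_tows_per_vessel == 0) {
      emit_leg(FALSE, round(12 / ping_interval_h))
    } else {
      for (tow in seq_len(n_tows_per_vessel)) {
        heading <- NULL
        emit_leg(FALSE, max(1, round(stats::runif(1, 2, 6) / ping_interval_h)))
        heading <- NULL
        emit_leg(TRUE, fishing_steps)
      }
    }
    rows[[v]] <- data.frame(vessel_id = sprintf("V%03d", v),
                            timestamp = t0 + pt * 3600,
                            x = px, y = py, speed_kn = pv)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
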