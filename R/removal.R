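# Sponge-removal accounting: overlay the trawl footprint on a biomass
# surface, simulate directed trawling inside closures, and count the
# trawl sets needed to deplete a standing stock.

biomass_matrix_of <- function(biomass) {
  if (inherits(biomass, "biomass_grid")) {
    b <- biomass$biomass_t
    b[is.na(b)] <- 0
    list(grid = biomass$grid, b = b)
  } else if (inherits(biomass, "model_surface") || (is.list(biomass) && !is.null(biomass$biomass_t))) {
    b <- biomass$biomass_t
    b[is.na(b)] <- 0
    list(grid = biomass$grid, b = b)
  } else stop("biomass must be a biomass_grid or model_surface")
}

#' Per-cell sponge removal under a trawl footprint
#'
#' For each biomass cell, the removed tonnage is the fraction of the cell
#' area trawled at least once (union of swaths clipped to the cell) times
#' the cell biomass times `removal_rate` (default 1: every pass removes
#' 100 percent of the sponges it covers, the worst case).
#'
#' @param footprint A `footprint` (or list of swaths/quads).
#' @param biomass A `biomass_grid` or `model_surface`.
#' @param removal_rate Fraction of covered biomass removed per pass.
#' @param region Optional convex polygon; the overlay is restricted to it.
#' @return A `removal_table` data frame: `row`, `col`, `biomass_t`,
#'   `trawled_frac`, `removal_t`, `removal_pct`, with attributes
#'   `total_removal_t` and `total_biomass_t`.
#' @export
removal_by_cell <- function(footprint, biomass, removal_rate = 1.0, region = NULL) {
  stopifnot(removal_rate >= 0, removal_rate <= 1)
  bm <- biomass_matrix_of(biomass)
  grid <- bm$grid
  quads <- if (inherits(footprint, "footprint")) footprint$quads
           else if (is.list(footprint) && length(footprint) && inherits(footprint[[1]], "swath"))
             unlist(lapply(footprint, `[[`, "quads"), recursive = FALSE)
           else footprint
  boxes <- lapply(quads, poly_bbox)
  a_cell <- cell_area_km2(grid)
  rows <- list()
  # restrict the scan to the cell ranges under the footprint bounding box
  if (length(boxes)) {
    fb <- c(min(vapply(boxes, `[[`, 0, "xmin")), min(vapply(boxes, `[[`, 0, "ymin")),
            max(vapply(boxes, `[[`, 0, "xmax")), max(vapply(boxes, `[[`, 0, "ymax")))
    ext <- grid_extent(grid)
    c1 <- max(1L, floor((fb[1] - ext[1]) / grid$cell_km) + 1L)
    c2 <- min(grid$n_col, floor((fb[3] - ext[1]) / grid$cell_km) + 1L)
    r1 <- max(1L, floor((fb[2] - ext[2]) / grid$cell_km) + 1L)
    r2 <- min(grid$n_row, floor((fb[4] - ext[2]) / grid$cell_km) + 1L)
  } else {
    r1 <- 1L; r2 <- 0L; c1 <- 1L; c2 <- 0L
  }
  for (r in seq_len(grid$n_row)) for (co in seq_len(grid$n_col)) {
    if (r < r1 || r > r2 || co < c1 || co > c2) next
    cellp <- cell_poly(grid, r, co)
    if (!is.null(region)) {
      cellp <- clip_convex(cellp, region)
      if (is.null(cellp)) next
    }
    cb <- poly_bbox(cellp)
    touch <- which(vapply(boxes, bbox_overlaps, TRUE, b = cb))
    if (!length(touch)) next
    a_trawled <- poly_union_area_in(quads[touch], cellp)
    if (a_trawled <= 0) next
    frac <- min(a_trawled / a_cell, 1)
    b <- bm$b[r, co]
    rows[[length(rows) + 1]] <- data.frame(
      row = r, col = co, biomass_t = b, trawled_frac = frac,
      removal_t = frac * b * removal_rate)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(row = integer(), col = integer(), biomass_t = numeric(),
               trawled_frac = numeric(), removal_t = numeric())
  out$removal_pct <- ifelse(out$biomass_t > 0, 100 * out$removal_t / out$biomass_t, 0)
  attr(out, "total_removal_t") <- sum(out$removal_t)
  attr(out, "total_biomass_t") <- sum(bm$b)
  class(out) <- c("removal_table", class(out))
  out
}

#' Removal as a percentage of a reference biomass
#'
#' The reference is an explicit argument (footprint total, study-area
#' total, ...) because published percentages mix denominators.
#'
#' @param removal_t Removed tonnage.
#' @param reference_biomass_t Reference biomass, tonnes (> 0).
#' @param digits Decimals (default 1).
#' @return Percent.
#' @export
removal_percent <- function(removal_t, reference_biomass_t, digits = 1) {
  if (reference_biomass_t <= 0) stop("reference biomass must be positive")
  round(100 * removal_t / reference_biomass_t, digits)
}

# One contour-following path inside a closure: steps of `step_nm` oriented
# along the local isobath with angular jitter, kept inside the closure by
# turning toward the closure centre.
contour_path <- function(seascape, closure_poly, length_nm, step_nm = 1, seed_state = NULL) {
  bb <- poly_bbox(closure_poly)
  for (try in 1:50) {
    x <- stats::runif(1, bb[1], bb[3]); y <- stats::runif(1, bb[2], bb[4])
    if (point_in_convex(x, y, closure_poly)) break
  }
  centre <- c(mean(closure_poly[, 1]), mean(closure_poly[, 2]))
  n_steps <- max(1, round(length_nm / step_nm))
  step_km <- (length_nm / n_steps) * NM_KM
  pos <- c(x, y)
  path <- matrix(NA_real_, n_steps + 1, 2)
  path[1, ] <- pos
  heading <- NULL
  for (s in seq_len(n_steps)) {
    heading <- contour_direction(seascape, pos[1], pos[2], heading)
    ang <- stats::rnorm(1, 0, 4 * pi / 180)
    R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
    heading <- as.numeric(R %*% heading)
    nxt <- pos + heading * step_km
    if (!point_in_convex(nxt[1], nxt[2], closure_poly)) {
      heading <- (centre - pos) / sqrt(sum((centre - pos)^2))
      nxt <- pos + heading * step_km
      if (!point_in_convex(nxt[1], nxt[2], closure_poly)) return(NULL)
    }
    pos <- nxt
    path[s + 1, ] <- pos
  }
  path
}

swaths_overlap <- function(quads_new, quads_old) {
  if (!length(quads_old)) return(FALSE)
  boxes_old <- lapply(quads_old, poly_bbox)
  for (q in quads_new) {
    qb <- poly_bbox(q)
    for (k in seq_along(quads_old)) {
      if (!bbox_overlaps(qb, boxes_old[[k]])) next
      p <- clip_convex(q, quads_old[[k]])
      if (!is.null(p) && poly_area(p) > 1e-6) return(TRUE)
    }
  }
  FALSE
}

#' Simulate directed trawling inside the closures
#'
#' Places `n` non-overlapping trawl sets inside the closure polygons
#' (allocation proportional to closure area), each following bathymetric
#' contours. Trawls are 18 nm long (6 h at 3 kn) except in the two
#' smallest closures, where they cover 7 and 8 nm. Removal per trawl is
#' the swath (100 m wingspread) overlaid on the biomass surface at 100
#' percent removal. Overlapping candidates are rejected and redrawn; if a
#' closure cannot host the full length the path is shortened with a
#' warning.
#'
#' @param seascape A `seascape` (bathymetry and closures).
#' @param biomass A `biomass_grid` or `model_surface`.
#' @param n Number of simulated trawl sets (default 30).
#' @param seed Integer seed.
#' @param wingspread_m Swath width, metres.
#' @param length_nm Default trawl length, nautical miles.
#' @param small_lengths_nm Lengths for the two smallest closures
#'   (smallest first), nautical miles.
#' @return List: `trawls` data frame (`trawl_id`, `closure`, `length_nm`,
#'   `removal_t`), `paths`, `swaths`, `mean_removal_t`, `sd_removal_t`,
#'   `total_removal_t`.
#' @export
simulate_closure_trawls <- function(seascape, biomass, n = 30, seed = 1L,
                                    wingspread_m = 100, length_nm = 18,
                                    small_lengths_nm = c(7, 8)) {
  closures <- seascape$closures
  if (!length(closures)) stop("seascape has no closures")
  set.seed(seed)
  areas <- vapply(closures, function(cl) poly_area(cl$poly), 0)
  lengths <- rep(length_nm, length(closures))
  if (length(closures) > 2) {
    ord <- order(areas)
    lengths[ord[1]] <- small_lengths_nm[1]
    lengths[ord[2]] <- small_lengths_nm[2]
  }
  bm <- biomass_matrix_of(biomass)
  paths <- list(); swaths <- list(); recs <- list(); all_quads <- list()
  for (i in seq_len(n)) {
    placed <- FALSE
    for (attempt in 1:25) {
      ci <- sample.int(length(closures), 1, prob = areas)
      path <- contour_path(seascape, closures[[ci]]$poly, lengths[ci])
      if (is.null(path)) next
      sw <- track_to_swath(path, wingspread_m)
      if (swaths_overlap(sw$quads, all_quads)) next
      placed <- TRUE
      break
    }
    if (!placed) {
      # fall back to a shortened straight set across the largest closure
      warning("trawl ", i, " could not be placed without overlap; shortened")
      ci <- which.max(areas)
      cp <- closures[[ci]]$poly
      ctr <- c(mean(cp[, 1]), mean(cp[, 2]))
      half <- min(lengths[ci] * NM_KM, max(cp[, 1]) - min(cp[, 1])) / 2
      off <- stats::runif(1, -0.4, 0.4) * (max(cp[, 2]) - min(cp[, 2]))
      path <- rbind(c(ctr[1] - half, ctr[2] + off), c(ctr[1] + half, ctr[2] + off))
      sw <- track_to_swath(path, wingspread_m)
    }
    rem <- removal_by_cell(sw$quads, biomass, removal_rate = 1)
    recs[[i]] <- data.frame(trawl_id = i, closure = closures[[ci]]$code,
                            length_nm = polyline_length(path) / NM_KM,
                            removal_t = attr(rem, "total_removal_t"))
    paths[[i]] <- path
    swaths[[i]] <- sw
    all_quads <- c(all_quads, sw$quads)
  }
  trawls <- do.call(rbind, recs)
  list(trawls = trawls, paths = paths, swaths = swaths,
       mean_removal_t = mean(trawls$removal_t),
       sd_removal_t = stats::sd(trawls$removal_t),
       total_removal_t = sum(trawls$removal_t))
}

#' Trawl sets needed to deplete a standing stock
#'
#' Ceiling of total biomass over mean removal per trawl, under the
#' non-overlapping-trawls assumption: eliminating the entire stock
#' requires covering all of it, so partial final trawls count in full.
#'
#' @param total_biomass_t Standing stock, tonnes.
#' @param mean_removal_per_trawl_t Mean removal per trawl set, tonnes (> 0).
#' @return Integer count (0 for zero stock).
#' @export
trawls_to_depletion <- function(total_biomass_t, mean_removal_per_trawl_t) {
  if (total_biomass_t == 0) return(0L)
  if (mean_removal_per_trawl_t <= 0) stop("mean removal per trawl must be positive")
  as.integer(ceiling(total_biomass_t / mean_removal_per_trawl_t))
}
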