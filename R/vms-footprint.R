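# Trawl-track reconstruction from vessel pings and the swept-area
# footprint ("trawled at least once").
#
# Pings at speeds strictly below 6 knots are taken as fishing; maximal
# runs of two or more consecutive fishing pings of one vessel form a
# track. Tracks are buffered to 100 m wingspread swaths with flat end
# caps (one rectangle per segment, so a straight track's swath area is
# exactly length x wingspread), and the footprint is the geometric union
# of swaths: subsequent passes over the same ground add nothing.

#' Retain likely-fishing pings
#'
#' Strict inequality: a ping at exactly the threshold is steaming.
#'
#' @param pings Ping data frame (`vessel_id`, `timestamp`, `x`, `y`,
#'   `speed_kn`).
#' @param speed_max_kn Fishing speed threshold, knots (default 6).
#' @return The subset with `speed_kn < speed_max_kn`, order preserved.
#' @export
filter_fishing_pings <- function(pings, speed_max_kn = 6) {
  pings[pings$speed_kn < speed_max_kn, , drop = FALSE]
}

#' Build trawl tracks from pings
#'
#' Per vessel, maximal runs of >= 2 consecutive fishing pings become one
#' polyline each. A run breaks when a non-fishing ping intervenes or the
#' time between consecutive retained pings exceeds `max_gap_h` (default
#' twice the median ping interval of the data). Unsorted input is sorted
#' by vessel and time with a warning.
#'
#' @param pings Ping data frame; may already be speed-filtered.
#' @param speed_max_kn Fishing threshold, knots.
#' @param max_gap_h Maximum hours between consecutive pings of one track.
#' @return List of `trawl_track` objects: data frame `vertices`
#'   (`x`, `y`, `timestamp`), `vessel_id`, `length_km`.
#' @export
build_tracks <- function(pings, speed_max_kn = 6, max_gap_h = NULL) {
  if (nrow(pings) == 0) return(list())
  o <- order(pings$vessel_id, pings$timestamp)
  if (!identical(o, seq_len(nrow(pings)))) {
    warning("pings were not sorted by vessel and time; sorting")
    pings <- pings[o, , drop = FALSE]
  }
  if (is.null(max_gap_h)) {
    dt <- unlist(tapply(as.numeric(pings$timestamp), pings$vessel_id,
                        function(t) diff(t) / 3600, simplify = FALSE))
    max_gap_h <- if (length(dt)) 2 * stats::median(dt) else Inf
  }
  fishing <- pings$speed_kn < speed_max_kn
  tracks <- list()
  for (v in unique(pings$vessel_id)) {
    p <- pings[pings$vessel_id == v, , drop = FALSE]
    f <- fishing[pings$vessel_id == v]
    gap_ok <- c(TRUE, diff(as.numeric(p$timestamp)) / 3600 <= max_gap_h + 1e-9)
    # run id increments when fishing status flips or a gap breaks the run
    brk <- !f | !gap_ok
    run <- cumsum(brk)
    for (id in unique(run[f])) {
      sel <- which(run == id & f)
      if (length(sel) < 2) next
      tracks[[length(tracks) + 1]] <- structure(list(
        vessel_id = v,
        vertices = data.frame(x = p$x[sel], y = p$y[sel],
                              timestamp = p$timestamp[sel]),
        length_km = polyline_length(cbind(p$x[sel], p$y[sel]))),
        class = "trawl_track")
    }
  }
  tracks
}

#' Buffer a track into its swept-area swath
#'
#' One rectangle of width `wingspread_m` per segment, flat end caps;
#' for a straight track the swath area equals length x wingspread
#' exactly. The union of the segment rectangles is the swath polygon set
#' (bends self-overlap harmlessly; area is always measured as a union).
#'
#' @param track A `trawl_track` (or a 2-column vertex matrix, km).
#' @param wingspread_m Swath width, metres (default 100; must be > 0).
#' @return A `swath`: list of convex quads, `area_km2` (union area),
#'   `length_km`, `vessel_id`.
#' @export
track_to_swath <- function(track, wingspread_m = 100) {
  if (wingspread_m <= 0) stop("wingspread must be positive")
  xy <- if (inherits(track, "trawl_track"))
    cbind(track$vertices$x, track$vertices$y) else track
  len <- polyline_length(xy)
  if (len <= 0) stop("zero-length track cannot be buffered")
  w_km <- wingspread_m / 1000
  quads <- list()
  for (i in seq_len(nrow(xy) - 1)) {
    q <- segment_quad(xy[i, 1], xy[i, 2], xy[i + 1, 1], xy[i + 1, 2], w_km)
    if (!is.null(q)) quads[[length(quads) + 1]] <- q
  }
  structure(list(quads = quads, area_km2 = poly_union_area(quads),
                 length_km = len,
                 vessel_id = if (inherits(track, "trawl_track")) track$vessel_id else NA),
            class = "swath")
}

#' Union footprint of a set of swaths
#'
#' The total area of seafloor trawled at least once: the geometric union
#' of all swath polygons, optionally clipped to a region. Cumulative
#' effort over the same ground is deliberately not counted.
#'
#' @param swaths List of `swath` objects (may be empty).
#' @param region Convex polygon to clip to, or `NULL`.
#' @return A `footprint`: `swaths`, all `quads`, `region`, `area_km2`.
#' @export
union_footprint <- function(swaths, region = NULL) {
  quads <- unlist(lapply(swaths, `[[`, "quads"), recursive = FALSE)
  if (is.null(quads)) quads <- list()
  area <- poly_union_area_in(quads, region)
  structure(list(swaths = swaths, quads = quads, region = region,
                 area_km2 = area, n_tracks = length(swaths)),
            class = "footprint")
}

#' @export
print.footprint <- function(x, ...) {
  cat(sprintf("footprint: %d tracks, %.2f km2 trawled at least once\n",
              x$n_tracks, x$area_km2))
  invisible(x)
}

#' Footprint coverage of a region
#'
#' @param footprint_area_km2 Footprint area.
#' @param region_area_km2 Region area (> 0).
#' @param digits Decimals for rounding (default 1).
#' @return Percent of the region trawled at least once.
#' @export
coverage_fraction <- function(footprint_area_km2, region_area_km2, digits = 1) {
  if (region_area_km2 <= 0) stop("region area must be positive")
  round(100 * footprint_area_km2 / region_area_km2, digits)
}
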