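# Plain-text interchange: CSV for tows/pings/catch tables, GeoJSON for
# polygons and tracks (planar km coordinates written as-is), ESRI ASCII
# for rasters (see raster.R), YAML for rates and configs.

#' Write and read survey tows as CSV
#'
#' Fixed columns: `tow_id`, `x`, `y`, `division`, `gear`,
#' `swept_area_m2`, `catch_kg`.
#'
#' @param tows Tow data frame.
#' @param path File path.
#' @export
write_tows_csv <- function(tows, path) {
  utils::write.csv(tows[, c("tow_id", "x", "y", "division", "gear",
                            "swept_area_m2", "catch_kg")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tows_csv
#' @export
read_tows_csv <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' Write and read vessel pings as CSV
#'
#' Fixed columns: `vessel_id`, `timestamp` (ISO 8601, UTC), `x`, `y`,
#' `speed_kn`.
#'
#' @param pings Ping data frame.
#' @param path File path.
#' @export
write_pings_csv <- function(pings, path) {
  p <- pings[, c("vessel_id", "timestamp", "x", "y", "speed_kn")]
  p$timestamp <- format(p$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(p, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pings_csv
#' @export
read_pings_csv <- function(path) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  p$timestamp <- as.POSIXct(p$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  p
}

close_ring <- function(poly) rbind(poly, poly[1, , drop = FALSE])

#' Write polygons as GeoJSON
#'
#' One Polygon feature per entry. `polys` may be a named list of polygon
#' matrices (names become the `name` property) or a closures list of
#' `list(code, poly)` (codes become the `code` property).
#'
#' @param polys Polygons (see above).
#' @param path Output file.
#' @export
write_polygons_geojson <- function(polys, path) {
  feats <- lapply(seq_along(polys), function(i) {
    el <- polys[[i]]
    if (is.list(el) && !is.null(el$poly)) {
      props <- list(code = el$code)
      poly <- el$poly
    } else {
      props <- list(name = names(polys)[i] %||% as.character(i))
      poly <- el
    }
    ring <- close_ring(poly)
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)), function(k)
                           c(ring[k, 1], ring[k, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from GeoJSON
#'
#' @param path GeoJSON file with Polygon features.
#' @return List of `list(properties, poly)`; the closing vertex is dropped.
#' @export
read_polygons_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
    m <- m[-nrow(m), , drop = FALSE]
    colnames(m) <- c("x", "y")
    list(properties = f$properties, poly = m)
  })
}

#' Write trawl tracks as GeoJSON LineStrings
#'
#' @param tracks List of `trawl_track` objects from [build_tracks()].
#' @param path Output file.
#' @export
write_tracks_geojson <- function(tracks, path) {
  feats <- lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    list(type = "Feature",
         properties = list(track_id = i, vessel_id = tr$vessel_id,
                           length_km = tr$length_km),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(tr$vertices)), function(k)
                           c(tr$vertices$x[k], tr$vertices$y[k]))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a biomass grid as CSV
#'
#' Long format, one row per populated cell: `cell_row`, `cell_col`,
#' `biomass_t`, `source`, `stratum`.
#'
#' @param bg A `biomass_grid`.
#' @param path Output file.
#' @export
write_biomass_grid_csv <- function(bg, path) {
  rows <- list()
  for (stratum in c("in", "out")) {
    b <- bg[[paste0("biomass_", stratum)]]
    src <- bg[[paste0("source_", stratum)]]
    idx <- which(!is.na(b), arr.ind = TRUE)
    if (nrow(idx)) rows[[stratum]] <- data.frame(
      cell_row = idx[, 1], cell_col = idx[, 2], biomass_t = b[idx],
      source = src[idx],
      stratum = if (stratum == "in") "inside_closure" else "outside_closure")
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cell_row = integer(), cell_col = integer(), biomass_t = numeric(),
               source = character(), stratum = character())
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
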