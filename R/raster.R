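# Lightweight matrix-backed planar rasters.
#
# A grid definition tiles the extent with square cells of `cell_km`;
# indexing is row-major from the origin with row 1 the southernmost band
# and column 1 the westernmost, and cells are half-open intervals
# [x0 + (j-1)c, x0 + j*c) so a point on a shared edge belongs to exactly
# one cell. Raster values are matrices [n_row, n_col].

#' Define a square-cell analysis grid
#'
#' @param x0,y0 Origin (south-west corner), km.
#' @param cell_km Cell edge length, km.
#' @param n_col,n_row Number of columns (x) and rows (y).
#' @return A `grid_def` object.
#' @export
grid_def <- function(x0, y0, cell_km, n_col, n_row) {
  stopifnot(cell_km > 0, n_col >= 1, n_row >= 1)
  structure(list(x0 = x0, y0 = y0, cell_km = cell_km,
                 n_col = as.integer(n_col), n_row = as.integer(n_row)),
            class = "grid_def")
}

#' Grid for a rectangular extent
#'
#' @param extent_km `c(xmin, ymin, xmax, ymax)` in km.
#' @param cell_km Cell size, km. The extent must be a whole number of cells.
#' @return A `grid_def`.
#' @export
grid_for_extent <- function(extent_km, cell_km) {
  nx <- (extent_km[3] - extent_km[1]) / cell_km
  ny <- (extent_km[4] - extent_km[2]) / cell_km
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9)
    stop("extent is not a whole number of cells of size ", cell_km, " km")
  grid_def(extent_km[1], extent_km[2], cell_km, round(nx), round(ny))
}

#' @export
print.grid_def <- function(x, ...) {
  cat(sprintf("grid_def: %d x %d cells of %g km (origin %g, %g)\n",
              x$n_row, x$n_col, x$cell_km, x$x0, x$y0))
  invisible(x)
}

cell_area_km2 <- function(grid) grid$cell_km^2

grid_extent <- function(grid) {
  c(grid$x0, grid$y0,
    grid$x0 + grid$n_col * grid$cell_km,
    grid$y0 + grid$n_row * grid$cell_km)
}

#' Cell centre coordinates
#'
#' @param grid A `grid_def`.
#' @return List with vectors `x` (length n_col) and `y` (length n_row).
#' @export
cell_centers <- function(grid) {
  list(x = grid$x0 + (seq_len(grid$n_col) - 0.5) * grid$cell_km,
       y = grid$y0 + (seq_len(grid$n_row) - 0.5) * grid$cell_km)
}

#' Locate points on a grid
#'
#' Half-open cell convention: a point on a shared cell edge belongs to the
#' cell to its north-east.
#'
#' @param grid A `grid_def`.
#' @param x,y Coordinates, km.
#' @return Data frame with columns `row`, `col` (NA outside the grid).
#' @export
cell_of <- function(grid, x, y) {
  col <- floor((x - grid$x0) / grid$cell_km) + 1
  row <- floor((y - grid$y0) / grid$cell_km) + 1
  bad <- col < 1 | col > grid$n_col | row < 1 | row > grid$n_row
  col[bad] <- NA_integer_; row[bad] <- NA_integer_
  data.frame(row = as.integer(row), col = as.integer(col))
}

#' Polygon of one grid cell
#'
#' @param grid A `grid_def`.
#' @param row,col Cell indices.
#' @return Rectangle polygon of the cell.
#' @export
cell_poly <- function(grid, row, col) {
  x1 <- grid$x0 + (col - 1) * grid$cell_km
  y1 <- grid$y0 + (row - 1) * grid$cell_km
  rect_poly(x1, y1, x1 + grid$cell_km, y1 + grid$cell_km)
}

#' Sample a raster at point locations
#'
#' @param grid A `grid_def`.
#' @param values Matrix `[n_row, n_col]`.
#' @param x,y Coordinates, km.
#' @return Vector of cell values (NA outside the grid).
#' @export
raster_at <- function(grid, values, x, y) {
  rc <- cell_of(grid, x, y)
  out <- rep(NA_real_, length(x))
  ok <- !is.na(rc$row)
  out[ok] <- values[cbind(rc$row[ok], rc$col[ok])]
  out
}

#' Integrate a density raster to tonnes
#'
#' Treats `values` as a density in kg m^-2 constant within each cell.
#'
#' @param grid A `grid_def`.
#' @param values Density matrix, kg m^-2.
#' @return Total mass in tonnes.
#' @export
density_total_t <- function(grid, values) {
  sum(values, na.rm = TRUE) * cell_area_km2(grid) * 1e6 / 1000
}

#' Write a raster as an ESRI ASCII grid
#'
#' Plain-text interchange format readable by standard GIS tools. Coordinates
#' are the package's planar km (written as-is).
#'
#' @param grid A `grid_def`.
#' @param values Matrix `[n_row, n_col]`.
#' @param path Output file.
#' @param nodata NODATA sentinel (default -9999).
#' @export
write_ascii_grid <- function(grid, values, path, nodata = -9999) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", grid$n_col),
    paste("nrows", grid$n_row),
    paste("xllcorner", grid$x0),
    paste("yllcorner", grid$y0),
    paste("cellsize", grid$cell_km),
    paste("NODATA_value", nodata)), con)
  v <- values
  v[is.na(v)] <- nodata
  # ASCII grids run north to south: top line is the last matrix row
  for (r in rev(seq_len(grid$n_row))) {
    writeLines(paste(format(v[r, ], trim = TRUE, scientific = FALSE), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File written by [write_ascii_grid()] (or any ESRI ASCII grid).
#' @return List with `grid` (a `grid_def`) and `values` matrix.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  g <- grid_def(hdr$xllcorner, hdr$yllcorner, hdr$cellsize, hdr$ncols, hdr$nrows)
  vals <- lapply(lines[i:length(lines)], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  m <- do.call(rbind, vals)
  m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA_real_
  list(grid = g, values = m)
}
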