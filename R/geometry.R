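# Planar geometry on convex polygons, km coordinates.
#
# The synthetic seascape lives on a planar equal-area grid, so all spatial
# overlay reduces to exact operations on convex polygons: shoelace areas,
# Sutherland-Hodgman clipping (exact for a convex clip window), and the area
# of a union of convex polygons by a vertical slab sweep.  Polygons are
# 2-column matrices of vertices (x, y), not closed.

#' Polygon area (shoelace formula)
#'
#' @param poly Two-column matrix of vertices (x, y) in km, not closed.
#' @return Area in km^2 (non-negative).
#' @export
poly_area <- function(poly) abs(poly_signed_area(poly))

poly_signed_area <- function(poly) {
  n <- nrow(poly)
  if (is.null(n) || n < 3) return(0)
  x <- poly[, 1]; y <- poly[, 2]
  j <- c(2:n, 1)
  sum(x * y[j] - x[j] * y) / 2
}

poly_orient_ccw <- function(poly) {
  if (poly_signed_area(poly) < 0) poly[rev(seq_len(nrow(poly))), , drop = FALSE] else poly
}

poly_bbox <- function(poly) {
  c(xmin = min(poly[, 1]), ymin = min(poly[, 2]),
    xmax = max(poly[, 1]), ymax = max(poly[, 2]))
}

bbox_overlaps <- function(a, b) {
  a[1] <= b[3] && b[1] <= a[3] && a[2] <= b[4] && b[2] <= a[4]
}

#' Axis-aligned rectangle polygon
#'
#' @param xmin,ymin,xmax,ymax Corners in km.
#' @return A 4-vertex polygon matrix (counter-clockwise).
#' @export
rect_poly <- function(xmin, ymin, xmax, ymax) {
  cbind(x = c(xmin, xmax, xmax, xmin), y = c(ymin, ymin, ymax, ymax))
}

#' Test points against a convex polygon
#'
#' Half-plane test; points exactly on the boundary count as inside.
#'
#' @param x,y Coordinate vectors.
#' @param poly Convex polygon matrix.
#' @return Logical vector.
#' @export
point_in_convex <- function(x, y, poly) {
  poly <- poly_orient_ccw(poly)
  n <- nrow(poly)
  inside <- rep(TRUE, length(x))
  for (i in seq_len(n)) {
    a <- poly[i, ]; b <- poly[if (i == n) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (y - a[2]) - (b[2] - a[2]) * (x - a[1])
    inside <- inside & cross >= -1e-12
  }
  inside
}

#' Clip a polygon to a convex window
#'
#' Sutherland-Hodgman clipping. Exact when `clip` is convex; the subject may
#' be any simple polygon.
#'
#' @param subject Polygon matrix to be clipped.
#' @param clip Convex polygon matrix.
#' @return Clipped polygon matrix, or `NULL` if the intersection is empty.
#' @export
clip_convex <- function(subject, clip) {
  if (is.null(subject) || nrow(subject) < 3) return(NULL)
  clip <- poly_orient_ccw(clip)
  nc <- nrow(clip)
  out <- subject
  for (i in seq_len(nc)) {
    a <- clip[i, ]; b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1] - a[1]; ey <- b[2] - a[2]
    inp <- out
    if (is.null(inp) || nrow(inp) < 3) return(NULL)
    np <- nrow(inp)
    side <- ex * (inp[, 2] - a[2]) - ey * (inp[, 1] - a[1])  # >= 0 is inside
    keep_x <- numeric(0); keep_y <- numeric(0)
    for (k in seq_len(np)) {
      k2 <- if (k == np) 1L else k + 1L
      p <- inp[k, ]; q <- inp[k2, ]
      sp <- side[k]; sq <- side[k2]
      if (sp >= 0) { keep_x <- c(keep_x, p[1]); keep_y <- c(keep_y, p[2]) }
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        keep_x <- c(keep_x, p[1] + t * (q[1] - p[1]))
        keep_y <- c(keep_y, p[2] + t * (q[2] - p[2]))
      }
    }
    if (length(keep_x) < 3) return(NULL)
    out <- cbind(x = keep_x, y = keep_y)
  }
  if (poly_area(out) <= 0) NULL else out
}

# Edge list of a polygon as a matrix (x1, y1, x2, y2)
poly_edges <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  cbind(poly[, 1], poly[, 2], poly[j, 1], poly[j, 2])
}

# x-coordinates of proper intersections between two edge sets (vectorized
# over the cartesian pairing). Collinear overlaps contribute nothing: the
# union-length function has its kinks at segment endpoints there, which are
# already breakpoints.
edge_intersection_x <- function(E1, E2) {
  n1 <- nrow(E1); n2 <- nrow(E2)
  if (n1 == 0 || n2 == 0) return(numeric(0))
  i <- rep(seq_len(n1), each = n2)
  j <- rep(seq_len(n2), times = n1)
  p1x <- E1[i, 1]; p1y <- E1[i, 2]; d1x <- E1[i, 3] - p1x; d1y <- E1[i, 4] - p1y
  q1x <- E2[j, 1]; q1y <- E2[j, 2]; d2x <- E2[j, 3] - q1x; d2y <- E2[j, 4] - q1y
  den <- d1x * d2y - d1y * d2x
  ok <- abs(den) > 1e-14
  t <- ((q1x - p1x) * d2y - (q1y - p1y) * d2x) / den
  s <- ((q1x - p1x) * d1y - (q1y - p1y) * d1x) / den
  ok <- ok & t >= 0 & t <= 1 & s >= 0 & s <= 1
  (p1x + t * d1x)[ok]
}

# Cross-section [ylo, yhi] of a convex polygon at vertical line x = x0,
# or NULL when the line misses it.
poly_cross_section <- function(poly, x0) {
  E <- poly_edges(poly)
  hit <- (E[, 1] - x0) * (E[, 3] - x0) <= 0 & abs(E[, 3] - E[, 1]) > 1e-14
  if (!any(hit)) return(NULL)
  t <- (x0 - E[hit, 1]) / (E[hit, 3] - E[hit, 1])
  ys <- E[hit, 2] + t * (E[hit, 4] - E[hit, 2])
  c(min(ys), max(ys))
}

union_interval_length <- function(lo, hi) {
  if (length(lo) == 0) return(0)
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  total <- 0
  cur_lo <- lo[1]; cur_hi <- hi[1]
  for (k in seq_along(lo)[-1]) {
    if (lo[k] > cur_hi) {
      total <- total + (cur_hi - cur_lo)
      cur_lo <- lo[k]; cur_hi <- hi[k]
    } else if (hi[k] > cur_hi) {
      cur_hi <- hi[k]
    }
  }
  total + (cur_hi - cur_lo)
}

#' Area of the union of convex polygons
#'
#' Exact vertical slab sweep: x-breakpoints are all vertices plus all
#' pairwise edge intersections, so within a slab the union cross-section
#' length is linear in x and the slab integral equals width times the
#' midpoint value.
#'
#' @param polys List of convex polygon matrices (`NULL` entries ignored).
#' @return Union area in km^2.
#' @export
poly_union_area <- function(polys) {
  polys <- Filter(function(p) !is.null(p) && nrow(p) >= 3 && poly_area(p) > 1e-14, polys)
  np <- length(polys)
  if (np == 0) return(0)
  if (np == 1) return(poly_area(polys[[1]]))
  boxes <- lapply(polys, poly_bbox)
  edges <- lapply(polys, poly_edges)
  xs <- unlist(lapply(polys, function(p) p[, 1]))
  if (np > 1) {
    for (a in seq_len(np - 1)) {
      for (b in (a + 1):np) {
        if (bbox_overlaps(boxes[[a]], boxes[[b]])) {
          xs <- c(xs, edge_intersection_x(edges[[a]], edges[[b]]))
        }
      }
    }
  }
  xs <- sort(unique(xs))
  if (length(xs) < 2) return(0)
  xmins <- vapply(boxes, `[[`, 0, "xmin")
  xmaxs <- vapply(boxes, `[[`, 0, "xmax")
  total <- 0
  for (s in seq_len(length(xs) - 1)) {
    w <- xs[s + 1] - xs[s]
    if (w <= 1e-14) next
    xm <- (xs[s] + xs[s + 1]) / 2
    active <- which(xmins < xm & xmaxs > xm)
    if (!length(active)) next
    lo <- numeric(0); hi <- numeric(0)
    for (k in active) {
      cs <- poly_cross_section(polys[[k]], xm)
      if (!is.null(cs)) { lo <- c(lo, cs[1]); hi <- c(hi, cs[2]) }
    }
    total <- total + w * union_interval_length(lo, hi)
  }
  total
}

#' Area of the union of polygons clipped to a convex window
#'
#' @param polys List of convex polygons.
#' @param window Convex polygon, or `NULL` for no clipping.
#' @return Area in km^2.
#' @export
poly_union_area_in <- function(polys, window = NULL) {
  if (is.null(window)) return(poly_union_area(polys))
  wb <- poly_bbox(window)
  clipped <- lapply(polys, function(p) {
    if (is.null(p) || !bbox_overlaps(poly_bbox(p), wb)) return(NULL)
    clip_convex(p, window)
  })
  poly_union_area(clipped)
}

# Buffer one straight segment into its swath rectangle (flat caps).
segment_quad <- function(x1, y1, x2, y2, width_km) {
  dx <- x2 - x1; dy <- y2 - y1
  len <- sqrt(dx^2 + dy^2)
  if (len <= 0) return(NULL)
  nx <- -dy / len * width_km / 2
  ny <- dx / len * width_km / 2
  cbind(x = c(x1 + nx, x2 + nx, x2 - nx, x1 - nx),
        y = c(y1 + ny, y2 + ny, y2 - ny, y1 - ny))
}

#' Polyline length
#'
#' @param xy Two-column matrix of vertices (km).
#' @return Length in km.
#' @export
polyline_length <- function(xy) {
  if (nrow(xy) < 2) return(0)
  sum(sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2))
}
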