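# Planar geometry helpers. All coordinates are projected metres on a
# fictional national-grid-like plane; nothing here touches lat/lon.

#' Euclidean distance between two point sets
#' @param x1,y1,x2,y2 numeric vectors (recycled)
#' @return numeric vector of distances in metres
#' @keywords internal
euclid <- function(x1, y1, x2, y2) sqrt((x1 - x2)^2 + (y1 - y2)^2)

# Closed-rectangle containment (boundary counts as inside).
point_in_rect <- function(x, y, rect) {
  x >= rect$xmin & x <= rect$xmax & y >= rect$ymin & y <= rect$ymax
}

# For each point return the id of the containing rectangle (first match,
# rectangles assumed non-overlapping) or NA_character_.
rect_id_at <- function(x, y, rects) {
  out <- rep(NA_character_, length(x))
  for (i in seq_len(nrow(rects))) {
    hit <- is.na(out) &
      x >= rects$xmin[i] & x <= rects$xmax[i] &
      y >= rects$ymin[i] & y <= rects$ymax[i]
    out[hit] <- rects$id[i]
  }
  out
}

#' Convex hull of a point cloud as a closed polygon
#'
#' @param x,y coordinates of the points.
#' @return data.frame with columns `x`, `y`: hull vertices in
#'   counter-clockwise order, first vertex not repeated.
#' @keywords internal
convex_hull <- function(x, y) {
  idx <- grDevices::chull(x, y)
  data.frame(x = x[idx], y = y[idx])[rev(seq_along(idx)), , drop = FALSE]
}

#' Signed polygon area by the shoelace formula (positive if CCW)
#' @param poly data.frame with `x`, `y` vertex columns.
#' @return signed area in square metres.
#' @export
polygon_area <- function(poly) {
  x <- poly$x; y <- poly$y
  j <- c(seq_along(x)[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Test points against a convex polygon (boundary counts as inside)
#' @param px,py point coordinates in metres.
#' @param poly data.frame with `x`, `y` vertex columns (either winding).
#' @return logical vector.
#' @export
point_in_convex <- function(px, py, poly) {
  x <- poly$x; y <- poly$y
  n <- length(x)
  j <- c(seq_len(n)[-1], 1L)
  inside <- rep(TRUE, length(px))
  s <- sign(polygon_area(poly))
  if (s == 0) stop("degenerate (collinear) polygon")
  for (k in seq_len(n)) {
    cr <- (x[j[k]] - x[k]) * (py - y[k]) - (y[j[k]] - y[k]) * (px - x[k])
    inside <- inside & (s * cr >= -1e-9)
  }
  inside
}

# Distance from points to one segment (vectorised over points).
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  if (L2 == 0) return(euclid(px, py, x1, y1))
  t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / L2))
  euclid(px, py, x1 + t * dx, y1 + t * dy)
}

#' Distance from points to the nearest road polyline
#' @param px,py point coordinates in metres.
#' @param roads list of two-column matrices (x, y vertex coordinates).
#' @return numeric vector of distances in metres.
#' @export
dist_to_roads <- function(px, py, roads) {
  d <- rep(Inf, length(px))
  for (r in roads) {
    for (k in seq_len(nrow(r) - 1L)) {
      d <- pmin(d, dist_point_segment(px, py,
                                      r[k, 1], r[k, 2], r[k + 1, 1], r[k + 1, 2]))
    }
  }
  d
}

# Reflect coordinates into [lo, hi] (used to keep simulated birds on the map).
reflect_into <- function(v, lo, hi) {
  w <- hi - lo
  v <- (v - lo) %% (2 * w)
  v <- ifelse(v > w, 2 * w - v, v)
  v + lo
}
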