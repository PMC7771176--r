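# Planar geometry primitives. All coordinates are two-column matrices
# (x, y) in meters in a single metric CRS; polylines are ordered vertex
# matrices, polygons are rings (closure implicit).

#' Length of a polyline
#'
#' @param line two-column coordinate matrix (meters).
#' @param units `"m"` or `"km"`.
#' @return Total length along consecutive vertices.
#' @export
polyline_length <- function(line, units = c("m", "km")) {
  units <- match.arg(units)
  line <- as_coords(line)
  if (nrow(line) < 2L) stop("polyline needs at least 2 vertices")
  d <- sqrt(diff(line[, 1L])^2 + diff(line[, 2L])^2)
  len <- sum(d)
  if (units == "km") len / 1000 else len
}

as_coords <- function(x) {
  m <- as.matrix(x)
  if (ncol(m) < 2L) stop("coordinates must have two columns")
  storage.mode(m) <- "double"
  m[, 1:2, drop = FALSE]
}

# Distances from points (n x 2) to each segment of a polyline, returning
# the minimum per point. Vectorised over points, looped over segments:
# itineraries have tens of vertices while point sets can be large.
points_polyline_distance <- function(points, line) {
  points <- as_coords(points)
  line <- as_coords(line)
  if (nrow(line) < 2L) stop("empty polyline")
  px <- points[, 1L]; py <- points[, 2L]
  best <- rep(Inf, length(px))
  for (i in seq_len(nrow(line) - 1L)) {
    d <- points_segment_distance(px, py,
                                 line[i, 1L], line[i, 2L],
                                 line[i + 1L, 1L], line[i + 1L, 2L])
    best <- pmin(best, d)
  }
  best
}

points_segment_distance <- function(px, py, x1, y1, x2, y2) {
  vx <- x2 - x1; vy <- y2 - y1
  len2 <- vx * vx + vy * vy
  if (len2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(1, pmax(0, ((px - x1) * vx + (py - y1) * vy) / len2))
  sqrt((px - (x1 + t * vx))^2 + (py - (y1 + t * vy))^2)
}

#' Perpendicular distance from observation points to the itinerary
#'
#' Shortest Euclidean distance from each point to the nearest segment of
#' the roadside-count polyline.
#'
#' @param points two-column coordinate matrix (meters).
#' @param itinerary polyline vertex matrix, or a [landscape] object.
#' @return Numeric vector of distances in meters.
#' @export
perpendicular_distance <- function(points, itinerary) {
  if (inherits(itinerary, "landscape")) itinerary <- itinerary$itinerary
  points_polyline_distance(points, itinerary)
}

points_in_polygon <- function(points, ring) {
  points <- as_coords(points)
  ring <- as_coords(ring)
  pracma::inpolygon(points[, 1L], points[, 2L], ring[, 1L], ring[, 2L],
                    boundary = TRUE)
}

# Closed-ring boundary treated as a polyline with explicit closure.
ring_boundary_distance <- function(points, ring) {
  ring <- as_coords(ring)
  closed <- rbind(ring, ring[1L, , drop = FALSE])
  points_polyline_distance(points, closed)
}

#' Distance to the nearest habitat polygon
#'
#' Zero for points inside any polygon of the set, otherwise the distance
#' to the nearest polygon boundary.
#'
#' @param points two-column coordinate matrix (meters).
#' @param polygons a single ring matrix or a list of ring matrices.
#' @return Numeric vector of distances in meters.
#' @export
nearest_habitat_distance <- function(points, polygons) {
  if (is.matrix(polygons) || is.data.frame(polygons)) polygons <- list(polygons)
  if (length(polygons) == 0L) stop("empty polygon set")
  points <- as_coords(points)
  d <- rep(Inf, nrow(points))
  inside <- rep(FALSE, nrow(points))
  for (ring in polygons) {
    inside <- inside | points_in_polygon(points, ring)
    d <- pmin(d, ring_boundary_distance(points, ring))
  }
  d[inside] <- 0
  d
}

# Cumulative arclength parameterisation of a polyline; returns points and
# unit normals at given arclength positions (used to place simulated
# individuals at a perpendicular offset from the track).
polyline_point_at <- function(line, s) {
  line <- as_coords(line)
  seg <- cbind(diff(line[, 1L]), diff(line[, 2L]))
  seglen <- sqrt(rowSums(seg^2))
  cum <- c(0, cumsum(seglen))
  total <- cum[length(cum)]
  s <- pmin(pmax(s, 0), total)
  idx <- findInterval(s, cum, rightmost.closed = TRUE)
  idx <- pmin(idx, length(seglen))
  frac <- (s - cum[idx]) / seglen[idx]
  pt <- line[idx, , drop = FALSE] + seg[idx, , drop = FALSE] * frac
  nrm <- cbind(-seg[idx, 2L], seg[idx, 1L]) / seglen[idx]
  list(point = pt, normal = nrm)
}

bbox_of <- function(coords, pad = 0) {
  coords <- as_coords(coords)
  c(xmin = min(coords[, 1L]) - pad, xmax = max(coords[, 1L]) + pad,
    ymin = min(coords[, 2L]) - pad, ymax = max(coords[, 2L]) + pad)
}

# Shoelace area (positive regardless of orientation).
ring_area <- function(ring) {
  ring <- as_coords(ring)
  x <- ring[, 1L]; y <- ring[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# A ring is simple (non self-intersecting) if no two non-adjacent edges
# cross. O(E^2), used only on load for validation of small polygon sets.
ring_is_simple <- function(ring) {
  ring <- as_coords(ring)
  n <- nrow(ring)
  if (n < 3L) return(FALSE)
  edges <- cbind(ring, rbind(ring[-1L, , drop = FALSE], ring[1L, , drop = FALSE]))
  segs_cross <- function(a, b) {
    d <- function(p, q, r) (q[1] - p[1]) * (r[2] - p[2]) - (q[2] - p[2]) * (r[1] - p[1])
    p1 <- a[1:2]; p2 <- a[3:4]; p3 <- b[1:2]; p4 <- b[3:4]
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    js <- seq.int(i + 2L, jmax)
    for (j in js) {
      if (segs_cross(edges[i, ], edges[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Local equirectangular projection of lon/lat (degrees) to meters around a
# reference point; adequate at the few-kilometre extent of a study area.
project_lonlat <- function(coords, origin = NULL) {
  coords <- as_coords(coords)
  if (is.null(origin)) origin <- colMeans(coords)
  R <- 6378137
  rad <- pi / 180
  x <- (coords[, 1L] - origin[1L]) * rad * R * cos(origin[2L] * rad)
  y <- (coords[, 2L] - origin[2L]) * rad * R
  cbind(x, y)
}

looks_lonlat <- function(coords) {
  coords <- as_coords(coords)
  all(abs(coords[, 1L]) <= 180) && all(abs(coords[, 2L]) <= 90)
}
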