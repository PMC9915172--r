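# Planar geometry primitives. All coordinates are numeric matrices with two
# columns (x, y) in a projected CRS with meter units; no geographic coordinates.

#' Length of a polyline
#'
#' @param coords Two-column numeric matrix of vertices (meters).
#' @return Total length in meters.
#' @keywords internal
polyline_length <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  dx <- diff(coords[, 1L])
  dy <- diff(coords[, 2L])
  sum(sqrt(dx * dx + dy * dy))
}

# Cumulative vertex distances along a polyline (first entry 0).
polyline_cumdist <- function(coords) {
  if (nrow(coords) < 2L) return(0)
  dx <- diff(coords[, 1L])
  dy <- diff(coords[, 2L])
  c(0, cumsum(sqrt(dx * dx + dy * dy)))
}

#' Point on a polyline at a given arc-length distance
#' @keywords internal
interpolate_along <- function(coords, d) {
  cd <- polyline_cumdist(coords)
  total <- cd[length(cd)]
  d <- min(max(d, 0), total)
  i <- findInterval(d, cd, rightmost.closed = TRUE)
  i <- min(i, nrow(coords) - 1L)
  seg_len <- cd[i + 1L] - cd[i]
  t <- if (seg_len > 0) (d - cd[i]) / seg_len else 0
  coords[i, ] + t * (coords[i + 1L, ] - coords[i, ])
}

# Sub-polyline between arc-length distances d0 < d1; keeps interior vertices.
substring_polyline <- function(coords, d0, d1) {
  cd <- polyline_cumdist(coords)
  total <- cd[length(cd)]
  d0 <- min(max(d0, 0), total)
  d1 <- min(max(d1, 0), total)
  if (d1 < d0) { tmp <- d0; d0 <- d1; d1 <- tmp }
  p0 <- interpolate_along(coords, d0)
  p1 <- interpolate_along(coords, d1)
  keep <- which(cd > d0 + 1e-12 & cd < d1 - 1e-12)
  rbind(p0, coords[keep, , drop = FALSE], p1, deparse.level = 0)
}

# Split a polyline at sorted interior arc-length distances; returns a list of
# sub-polylines covering the whole line.
split_polyline_at <- function(coords, dists) {
  total <- polyline_length(coords)
  dists <- sort(unique(dists))
  dists <- dists[dists > 1e-9 & dists < total - 1e-9]
  bounds <- c(0, dists, total)
  lapply(seq_len(length(bounds) - 1L), function(i) {
    substring_polyline(coords, bounds[i], bounds[i + 1L])
  })
}

# Vectorized distance from points (px, py) to the segment a-b; also returns the
# projection parameter t in [0, 1].
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax
  vy <- by - ay
  len2 <- vx * vx + vy * vy
  # len2 may be scalar (one segment, many points) or vector; keep t full length
  t <- ((px - ax) * vx + (py - ay) * vy) / ifelse(len2 > 0, len2, 1)
  t <- t * (len2 > 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * vx
  qy <- ay + t * vy
  list(dist = sqrt((px - qx)^2 + (py - qy)^2), t = t, qx = qx, qy = qy)
}

# Nearest point on a polyline to point p; returns distance, arc-length offset
# and the snapped coordinates.
project_to_polyline <- function(p, coords) {
  n <- nrow(coords)
  cd <- polyline_cumdist(coords)
  pr <- point_segment_distance(p[1L], p[2L],
                               coords[-n, 1L], coords[-n, 2L],
                               coords[-1L, 1L], coords[-1L, 2L])
  i <- which.min(pr$dist)
  seg_len <- cd[i + 1L] - cd[i]
  list(dist = pr$dist[i],
       offset = cd[i] + pr$t[i] * seg_len,
       point = c(pr$qx[i], pr$qy[i]))
}

# Signed area of a closed ring (shoelace); positive for counter-clockwise.
polygon_signed_area <- function(coords) {
  n <- nrow(coords)
  if (n < 3L) return(0)
  x <- coords[, 1L]; y <- coords[, 2L]
  j <- c(2:n, 1L)
  sum(x * y[j] - x[j] * y) / 2
}

#' Area of a simple polygon ring
#' @keywords internal
polygon_area <- function(coords) abs(polygon_signed_area(coords))

polygon_centroid <- function(coords) {
  n <- nrow(coords)
  x <- coords[, 1L]; y <- coords[, 2L]
  j <- c(2:n, 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(coords))
  c(sum((x + x[j]) * cr), sum((y + y[j]) * cr)) / (6 * a)
}

# Ray-casting point-in-polygon, vectorized over points. Boundary points may go
# either way (irrelevant at raster-cell-center resolution).
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1L]; yi <- poly[i, 2L]
    xj <- poly[j, 1L]; yj <- poly[j, 2L]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Angle (degrees, [0, 180]) between two direction vectors.
vector_angle <- function(ux, uy, vx, vy) {
  dot <- ux * vx + uy * vy
  nu <- sqrt(ux * ux + uy * uy)
  nv <- sqrt(vx * vx + vy * vy)
  ct <- pmin(pmax(dot / (nu * nv), -1), 1)
  acos(ct) * 180 / pi
}

# Intersection of segments p1-p2 and p3-p4. Returns NULL or c(t, u, x, y) with
# parameters along each segment. Collinear overlaps are ignored.
segment_intersection <- function(p1, p2, p3, p4, eps = 1e-9) {
  r <- p2 - p1
  s <- p4 - p3
  denom <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(denom) < eps) return(NULL)
  q <- p3 - p1
  t <- (q[1L] * s[2L] - q[2L] * s[1L]) / denom
  u <- (q[1L] * r[2L] - q[2L] * r[1L]) / denom
  if (t < -eps || t > 1 + eps || u < -eps || u > 1 + eps) return(NULL)
  t <- min(max(t, 0), 1)
  u <- min(max(u, 0), 1)
  c(t, u, p1[1L] + t * r[1L], p1[2L] + t * r[2L])
}

# Sutherland-Hodgman clip of a subject ring against a convex clip ring.
# Returns a matrix ring (possibly with 0 rows).
clip_polygon_convex <- function(subject, clip) {
  if (polygon_signed_area(clip) < 0) clip <- clip[rev(seq_len(nrow(clip))), , drop = FALSE]
  out <- subject
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0L) break
    a <- clip[i, ]
    b <- clip[if (i == nc) 1L else i + 1L, ]
    ex <- b[1L] - a[1L]; ey <- b[2L] - a[2L]
    side <- function(p) ex * (p[2L] - a[2L]) - ey * (p[1L] - a[1L])
    inp <- out
    out <- matrix(numeric(0), ncol = 2L)
    np <- nrow(inp)
    for (k in seq_len(np)) {
      cur <- inp[k, ]
      prv <- inp[if (k == 1L) np else k - 1L, ]
      cs <- side(cur); ps <- side(prv)
      if (cs >= -1e-9) {
        if (ps < -1e-9) {
          t <- ps / (ps - cs)
          out <- rbind(out, prv + t * (cur - prv))
        }
        out <- rbind(out, cur)
      } else if (ps >= -1e-9) {
        t <- ps / (ps - cs)
        out <- rbind(out, prv + t * (cur - prv))
      }
    }
  }
  out
}

# TRUE if ring is convex (allowing collinear vertices); uses cross products of
# consecutive edges.
is_convex_ring <- function(coords) {
  n <- nrow(coords)
  if (n < 4L) return(TRUE)
  j <- c(2:n, 1L)
  k <- c(3:n, 1L, 2L)
  cr <- (coords[j, 1L] - coords[, 1L]) * (coords[k, 2L] - coords[j, 2L]) -
    (coords[j, 2L] - coords[, 2L]) * (coords[k, 1L] - coords[j, 1L])
  all(cr >= -1e-9) || all(cr <= 1e-9)
}

# Guard: reject coordinates that look geographic (degrees). Heuristic: the
# whole extent fits in the lon/lat box AND spans less than one unit in each
# axis (a city in degrees spans ~0.1, in meters thousands; meter-unit toy
# fixtures near the origin span tens of units and pass).
check_projected <- function(coords_list) {
  all_xy <- do.call(rbind, coords_list)
  if (nrow(all_xy) == 0L) return(invisible(TRUE))
  rx <- range(all_xy[, 1L]); ry <- range(all_xy[, 2L])
  in_deg_box <- rx[1L] >= -180 && rx[2L] <= 180 && ry[1L] >= -90 && ry[2L] <= 90
  tiny_span <- diff(rx) < 1 && diff(ry) < 1
  if (in_deg_box && tiny_span) {
    stop("coordinates appear to be geographic (degree units); ",
         "a projected CRS in meters is required", call. = FALSE)
  }
  invisible(TRUE)
}
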