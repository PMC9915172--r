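# Regular-grid raster surfaces and zonal statistics.
#
# A raster_surface stores a value matrix with row 1 at the TOP (northernmost)
# row, anchored at a lower-left corner (xll, yll) with square cells, mirroring
# the Esri ASCII grid layout used for (de)serialization. Cells equal to the
# nodata marker are excluded from every statistic.

#' Create a raster surface
#'
#' @param values Numeric matrix; row 1 is the northernmost row.
#' @param xll,yll Coordinates of the lower-left corner of the grid (meters).
#' @param cellsize Cell edge length in meters (> 0).
#' @param nodata Value marking missing cells (default -9999).
#' @return An object of class `raster_surface`.
#' @export
raster_surface <- function(values, xll, yll, cellsize, nodata = -9999) {
  stopifnot(is.matrix(values), cellsize > 0)
  structure(
    list(values = values, xll = xll, yll = yll,
         cellsize = cellsize, nodata = nodata),
    class = "raster_surface"
  )
}

#' @export
print.raster_surface <- function(x, ...) {
  v <- raster_values(x)
  cat(sprintf("raster_surface: %d x %d cells @ %g m, origin (%g, %g)\n",
              nrow(x$values), ncol(x$values), x$cellsize, x$xll, x$yll))
  cat(sprintf("  values: [%g, %g], %d nodata cells\n",
              suppressWarnings(min(v, na.rm = TRUE)),
              suppressWarnings(max(v, na.rm = TRUE)), sum(is.na(v))))
  invisible(x)
}

# Values with nodata replaced by NA.
raster_values <- function(r) {
  v <- r$values
  v[v == r$nodata] <- NA_real_
  v
}

# Cell-center coordinates for given row/col index vectors.
raster_cell_center <- function(r, row, col) {
  nr <- nrow(r$values)
  list(x = r$xll + (col - 0.5) * r$cellsize,
       y = r$yll + (nr - row + 0.5) * r$cellsize)
}

# All cell-center x (per column) and y (per row) coordinates.
raster_axes <- function(r) {
  nr <- nrow(r$values); nc <- ncol(r$values)
  list(x = r$xll + (seq_len(nc) - 0.5) * r$cellsize,
       y = r$yll + (nr - seq_len(nr) + 0.5) * r$cellsize)
}

raster_extent <- function(r) {
  c(xmin = r$xll, ymin = r$yll,
    xmax = r$xll + ncol(r$values) * r$cellsize,
    ymax = r$yll + nrow(r$values) * r$cellsize)
}

same_grid <- function(a, b, tol = 1e-6) {
  abs(a$xll - b$xll) < tol && abs(a$yll - b$yll) < tol &&
    abs(a$cellsize - b$cellsize) < tol &&
    nrow(a$values) == nrow(b$values) && ncol(a$values) == ncol(b$values)
}

#' Write a raster surface as an Esri ASCII grid
#' @param r A `raster_surface`.
#' @param path Output path (conventionally `.asc`).
#' @export
write_ascii_grid <- function(r, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(r$values)),
    sprintf("nrows %d", nrow(r$values)),
    sprintf("xllcorner %.6f", r$xll),
    sprintf("yllcorner %.6f", r$yll),
    sprintf("cellsize %.6f", r$cellsize),
    sprintf("NODATA_value %g", r$nodata)
  ), con)
  for (i in seq_len(nrow(r$values))) {
    writeLines(paste(format(r$values[i, ], trim = TRUE, digits = 10),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Read an Esri ASCII grid
#' @param path Path to a `.asc` file.
#' @return A `raster_surface`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- lapply(lines[i:length(lines)], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1L]])
  })
  m <- do.call(rbind, vals)
  stopifnot(nrow(m) == hdr$nrows, ncol(m) == hdr$ncols)
  raster_surface(m, hdr$xllcorner, hdr$yllcorner, hdr$cellsize,
                 nodata = if (is.null(hdr$nodata_value)) -9999 else hdr$nodata_value)
}

#' Normalized difference vegetation index
#'
#' Per-cell (NIR - RED) / (NIR + RED) from co-registered near-infrared and red
#' reflectance surfaces. Cells where NIR + RED is zero (or either band is
#' nodata) become nodata; all defined values lie in [-1, 1].
#'
#' @param nir,red Co-registered `raster_surface` objects (same origin, cell
#'   size and shape).
#' @return A `raster_surface` of NDVI values.
#' @export
compute_ndvi <- function(nir, red) {
  if (!same_grid(nir, red)) {
    stop("NIR and RED rasters are not co-registered", call. = FALSE)
  }
  a <- raster_values(nir)
  b <- raster_values(red)
  denom <- a + b
  v <- (a - b) / denom
  v[!is.finite(v) | denom == 0] <- NA_real_
  out <- v
  out[is.na(out)] <- -9999
  raster_surface(out, nir$xll, nir$yll, nir$cellsize, nodata = -9999)
}

## Zones ---------------------------------------------------------------------
# A zone is anything with a bounding box and a cell-center containment test:
# circular buffers, route/catchment corridors, and polygon rings.

#' Circular buffer zone
#' @param center Numeric length-2 (x, y) in meters.
#' @param radius Radius in meters (> 0).
#' @export
zone_circle <- function(center, radius) {
  stopifnot(radius > 0)
  structure(list(center = c(center[[1L]], center[[2L]]), radius = radius),
            class = c("zone_circle", "zone"))
}

#' Corridor zone around polyline portions
#'
#' The union of fixed-half-width corridors around a set of polylines (e.g., the
#' reachable portions of a catchment, or a route); containment is distance to
#' the nearest polyline <= width.
#'
#' @param portions List of two-column coordinate matrices.
#' @param width Corridor half-width in meters (> 0).
#' @export
zone_corridor <- function(portions, width) {
  if (width <= 0) stop("corridor width must be positive", call. = FALSE)
  if (length(portions) == 0L) stop("empty corridor zone", call. = FALSE)
  structure(list(portions = portions, width = width),
            class = c("zone_corridor", "zone"))
}

#' Polygon zone
#' @param ring Two-column coordinate matrix (closed or open ring).
#' @export
zone_polygon <- function(ring) {
  structure(list(ring = ring), class = c("zone_polygon", "zone"))
}

#' @export
zone_bbox <- function(zone) UseMethod("zone_bbox")

#' @export
zone_bbox.zone_circle <- function(zone) {
  c(xmin = zone$center[1L] - zone$radius, ymin = zone$center[2L] - zone$radius,
    xmax = zone$center[1L] + zone$radius, ymax = zone$center[2L] + zone$radius)
}

#' @export
zone_bbox.zone_corridor <- function(zone) {
  xy <- do.call(rbind, zone$portions)
  c(xmin = min(xy[, 1L]) - zone$width, ymin = min(xy[, 2L]) - zone$width,
    xmax = max(xy[, 1L]) + zone$width, ymax = max(xy[, 2L]) + zone$width)
}

#' @export
zone_bbox.zone_polygon <- function(zone) {
  c(xmin = min(zone$ring[, 1L]), ymin = min(zone$ring[, 2L]),
    xmax = max(zone$ring[, 1L]), ymax = max(zone$ring[, 2L]))
}

#' Test points for zone membership
#' @param zone A zone object.
#' @param px,py Point coordinate vectors.
#' @return Logical vector.
#' @export
zone_contains <- function(zone, px, py) UseMethod("zone_contains")

#' @export
zone_contains.zone_circle <- function(zone, px, py) {
  (px - zone$center[1L])^2 + (py - zone$center[2L])^2 <= zone$radius^2
}

#' @export
zone_contains.zone_corridor <- function(zone, px, py) {
  inside <- rep(FALSE, length(px))
  w <- zone$width
  for (coords in zone$portions) {
    todo <- which(!inside)
    if (length(todo) == 0L) break
    # cheap bbox pre-filter per portion
    bb <- c(min(coords[, 1L]) - w, max(coords[, 1L]) + w,
            min(coords[, 2L]) - w, max(coords[, 2L]) + w)
    cand <- todo[px[todo] >= bb[1L] & px[todo] <= bb[2L] &
                   py[todo] >= bb[3L] & py[todo] <= bb[4L]]
    if (length(cand) == 0L) next
    n <- nrow(coords)
    dmin <- rep(Inf, length(cand))
    for (s in seq_len(n - 1L)) {
      pr <- point_segment_distance(px[cand], py[cand],
                                   coords[s, 1L], coords[s, 2L],
                                   coords[s + 1L, 1L], coords[s + 1L, 2L])
      dmin <- pmin(dmin, pr$dist)
    }
    inside[cand[dmin <= w]] <- TRUE
  }
  inside
}

#' @export
zone_contains.zone_polygon <- function(zone, px, py) {
  point_in_polygon(px, py, zone$ring)
}

#' Zone area by grid integration
#'
#' Area of a zone estimated by counting cell centers of a fine grid; exact
#' closed forms exist only for simple shapes, and corridor unions are handled
#' uniformly this way.
#'
#' @param zone A zone object.
#' @param cell Integration cell size in meters (default 0.5).
#' @export
zone_area <- function(zone, cell = 0.5) {
  if (inherits(zone, "zone_circle")) return(pi * zone$radius^2)
  if (inherits(zone, "zone_polygon")) return(polygon_area(zone$ring))
  bb <- zone_bbox(zone)
  xs <- seq(bb["xmin"] + cell / 2, bb["xmax"], by = cell)
  ys <- seq(bb["ymin"] + cell / 2, bb["ymax"], by = cell)
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  sum(zone_contains(zone, grid$x, grid$y)) * cell * cell
}

#' Zonal statistic of a raster over a zone
#'
#' Aggregates the raster cells whose centers fall inside the zone; nodata
#' cells are excluded. Returns `NA` with a `reason` attribute when no valid
#' cell is covered.
#'
#' @param zone A zone object.
#' @param raster A `raster_surface`.
#' @param stat `"mean"` or `"max"`.
#' @return Numeric value (NA with attribute `reason` if undefined).
#' @export
zonal_stat <- function(zone, raster, stat = c("mean", "max")) {
  stat <- match.arg(stat)
  bb <- zone_bbox(zone)
  ext <- raster_extent(raster)
  if (bb["xmax"] < ext["xmin"] || bb["xmin"] > ext["xmax"] ||
      bb["ymax"] < ext["ymin"] || bb["ymin"] > ext["ymax"]) {
    return(structure(NA_real_, reason = "outside-raster"))
  }
  ax <- raster_axes(raster)
  cols <- which(ax$x >= bb["xmin"] & ax$x <= bb["xmax"])
  rows <- which(ax$y >= bb["ymin"] & ax$y <= bb["ymax"])
  if (length(cols) == 0L || length(rows) == 0L) {
    return(structure(NA_real_, reason = "outside-raster"))
  }
  px <- rep(ax$x[cols], each = length(rows))
  py <- rep(ax$y[rows], times = length(cols))
  inside <- zone_contains(zone, px, py)
  if (!any(inside)) return(structure(NA_real_, reason = "no-cells-covered"))
  sub <- raster_values(raster)[rows, cols, drop = FALSE]
  vals <- as.vector(sub)[inside]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(structure(NA_real_, reason = "all-nodata"))
  if (stat == "mean") mean(vals) else max(vals)
}
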