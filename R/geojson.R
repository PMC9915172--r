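# Minimal GeoJSON reader/writer for the vector layers the toolkit exchanges
# (Point / LineString / Polygon features with flat properties), built on
# jsonlite. Geometries are plain two-column coordinate matrices.

#' Read a GeoJSON FeatureCollection
#'
#' @param path Path to a GeoJSON file.
#' @return A list with `geometry` (list of coordinate matrices, or lists of
#'   rings for polygons), `type` (character vector of geometry types) and
#'   `properties` (data.frame).
#' @export
read_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("not a GeoJSON FeatureCollection: ", path, call. = FALSE)
  }
  feats <- gj$features
  geom <- vector("list", length(feats))
  type <- character(length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    g <- feats[[i]]$geometry
    type[i] <- g$type
    geom[[i]] <- switch(
      g$type,
      Point = matrix(unlist(g$coordinates), ncol = 2L, byrow = TRUE),
      LineString = do.call(rbind, lapply(g$coordinates, unlist)),
      Polygon = lapply(g$coordinates, function(r) do.call(rbind, lapply(r, unlist))),
      stop("unsupported geometry type: ", g$type, call. = FALSE)
    )
    props[[i]] <- feats[[i]]$properties
  }
  keys <- unique(unlist(lapply(props, names)))
  pdf <- as.data.frame(
    lapply(keys, function(k) {
      vals <- lapply(props, function(p) if (is.null(p[[k]])) NA else p[[k]])
      unlist(vals)
    }),
    col.names = keys, optional = TRUE, stringsAsFactors = FALSE
  )
  names(pdf) <- keys
  list(geometry = geom, type = type, properties = pdf)
}

geojson_geometry <- function(type, coords, digits = 3L) {
  rnd <- function(m) lapply(seq_len(nrow(m)), function(i) round(unname(m[i, ]), digits))
  coordinates <- switch(
    type,
    Point = round(unname(as.numeric(coords)), digits),
    LineString = rnd(coords),
    Polygon = lapply(if (is.list(coords)) coords else list(coords), rnd),
    stop("unsupported geometry type: ", type, call. = FALSE)
  )
  list(type = type, coordinates = coordinates)
}

#' Write a GeoJSON FeatureCollection
#'
#' @param geometry List of coordinate matrices (Point rows, LineString
#'   matrices, or lists of Polygon rings).
#' @param type Geometry type, one of `"Point"`, `"LineString"`, `"Polygon"`;
#'   recycled across features.
#' @param properties Data frame of feature properties (one row per feature) or
#'   NULL.
#' @param path Output path.
#' @export
write_geojson <- function(geometry, type, properties = NULL, path) {
  n <- length(geometry)
  type <- rep_len(type, n)
  feats <- lapply(seq_len(n), function(i) {
    props <- if (is.null(properties)) {
      structure(list(), names = character(0))
    } else {
      as.list(properties[i, , drop = FALSE])
    }
    list(type = "Feature",
         geometry = geojson_geometry(type[i], geometry[[i]]),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
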