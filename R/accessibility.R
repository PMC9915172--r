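# Feature accessibility: nearest distances, counts, decay-weighted counts and
# sizes, outlet ratios and route-corridor exposure for classed urban features
# (greenspaces with entrances and areas, transit stops with modes, food
# outlets with a fast-food flag).
#
# A feature may have several entrance points; its distance is the minimum over
# entrances and it is counted once no matter how many entrances fall in range.

#' Urban feature set
#'
#' @param features Data frame with columns `id`, `class`, and optionally
#'   `fast_food` (logical) and `area_m2` (> 0 where present).
#' @param entrances Data frame with columns `feature_id`, `x`, `y`; every
#'   feature must have at least one entrance (for point features the point
#'   itself).
#' @return An `urban_features` object.
#' @export
urban_features <- function(features, entrances) {
  stopifnot(all(c("id", "class") %in% names(features)),
            all(c("feature_id", "x", "y") %in% names(entrances)))
  missing_ent <- setdiff(features$id, entrances$feature_id)
  if (length(missing_ent) > 0L) {
    stop("features without entrances: ", paste(missing_ent, collapse = ", "),
         call. = FALSE)
  }
  if ("area_m2" %in% names(features)) {
    bad <- !is.na(features$area_m2) & features$area_m2 <= 0
    if (any(bad)) {
      stop("non-positive area for features: ",
           paste(features$id[bad], collapse = ", "), call. = FALSE)
    }
  }
  structure(list(features = features, entrances = entrances, snapped = NULL),
            class = "urban_features")
}

#' Subset an urban feature set by class
#' @param uf An `urban_features` object.
#' @param classes Character vector of class labels to keep.
#' @export
filter_features <- function(uf, classes) {
  keep <- uf$features$class %in% classes
  ids <- uf$features$id[keep]
  out <- urban_features(uf$features[keep, , drop = FALSE],
                        uf$entrances[uf$entrances$feature_id %in% ids, ,
                                     drop = FALSE])
  if (!is.null(uf$snapped)) {
    out$snapped <- uf$snapped[uf$snapped$feature_id %in% ids, , drop = FALSE]
  }
  out
}

#' Snap feature entrances to the network (cached)
#' @param uf An `urban_features` object.
#' @param network A `street_network`.
#' @param tolerance Snap tolerance in meters.
#' @return The feature set with a `snapped` entrance table attached.
#' @export
snap_entrances <- function(uf, network, tolerance = 500) {
  if (!is.null(uf$snapped)) return(uf)
  xy <- as.matrix(uf$entrances[, c("x", "y")])
  sp <- snap_points(xy, network, tolerance)
  uf$snapped <- cbind(uf$entrances, sp)
  uf
}

entrance_locations <- function(uf) {
  lapply(seq_len(nrow(uf$snapped)), function(i) {
    r <- uf$snapped[i, ]
    network_location(r$seg, r$offset, r$connector, c(r$sx, r$sy),
                     c(r$x, r$y))
  })
}

#' Network distance from an address to each feature
#'
#' Minimum metric network distance over each feature's entrances (connectors
#' included). Entrances that cannot be snapped are ignored; a feature with no
#' snappable entrance gets `Inf`.
#'
#' @param location Snapped address (`network_location`).
#' @param uf An `urban_features` object.
#' @param network A `street_network`.
#' @return Named numeric vector (names are feature ids).
#' @export
feature_distances <- function(location, uf, network) {
  uf <- snap_entrances(uf, network)
  ok <- !is.na(uf$snapped$seg)
  out <- stats::setNames(rep(Inf, nrow(uf$features)), uf$features$id)
  if (!any(ok)) return(out)
  ents <- entrance_locations(filter_snapped(uf, ok))
  D <- nl_distance_matrix(list(location), ents, network)[1L, ]
  d_by_feat <- tapply(D, uf$snapped$feature_id[ok], min)
  out[names(d_by_feat)] <- d_by_feat
  out
}

# TRUE positions of a possibly-NA logical vector
isTRUE_vec <- function(x) !is.na(x) & x

filter_snapped <- function(uf, keep) {
  uf$snapped <- uf$snapped[keep, , drop = FALSE]
  uf
}

#' Distance to the nearest feature
#'
#' @inheritParams feature_distances
#' @param cutoff Maximum search distance in meters; beyond it the result is
#'   `NA` with a `reason` attribute.
#' @return Distance in meters, or `NA` (reason `"no-features-of-class"` or
#'   `"beyond-cutoff"`).
#' @export
distance_to_nearest <- function(location, uf, network, cutoff = Inf) {
  if (nrow(uf$features) == 0L) {
    return(structure(NA_real_, reason = "no-features-of-class"))
  }
  d <- min(feature_distances(location, uf, network))
  if (!is.finite(d) || d > cutoff) {
    return(structure(NA_real_, reason = "beyond-cutoff"))
  }
  d
}

#' Count features within a radius
#'
#' A feature counts once when at least one entrance is within the radius under
#' the chosen distance type.
#'
#' @inheritParams distance_to_nearest
#' @param radius Radius in meters (> 0).
#' @param distance_type `"metric-network"` or `"euclidean"` (straight-line
#'   from the address point to entrance points).
#' @export
count_within <- function(location, uf, network, radius,
                         distance_type = c("metric-network", "euclidean")) {
  distance_type <- match.arg(distance_type)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  if (nrow(uf$features) == 0L) return(0L)
  if (distance_type == "metric-network") {
    d <- feature_distances(location, uf, network)
  } else {
    p <- location$source_point %||% location$snap_point
    ed <- sqrt((uf$entrances$x - p[1L])^2 + (uf$entrances$y - p[2L])^2)
    d <- tapply(ed, uf$entrances$feature_id, min)
  }
  sum(d <= radius)
}

#' Decay-weighted feature count
#'
#' Sum over features of `exp(-k * d)` where d is the nearest-entrance metric
#' network distance; features beyond the cutoff contribute zero.
#'
#' @inheritParams distance_to_nearest
#' @param params `decay_params` or bare k (1/m).
#' @param cutoff Contribution cutoff in meters (default `Inf`).
#' @export
decay_weighted_count <- function(location, uf, network, params, cutoff = Inf) {
  if (nrow(uf$features) == 0L) return(0)
  d <- feature_distances(location, uf, network)
  d <- d[is.finite(d) & d <= cutoff]
  if (length(d) == 0L) return(0)
  sum(decay(d, params))
}

#' Decay-weighted greenspace area
#'
#' Sum over greenspaces of `area_m2 * exp(-k * d)`.
#'
#' @inheritParams decay_weighted_count
#' @export
decay_weighted_area <- function(location, uf, network, params, cutoff = Inf) {
  if (!("area_m2" %in% names(uf$features)) || any(is.na(uf$features$area_m2))) {
    bad <- if ("area_m2" %in% names(uf$features)) {
      uf$features$id[is.na(uf$features$area_m2)]
    } else uf$features$id
    stop("features without area: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(uf$features) == 0L) return(0)
  d <- feature_distances(location, uf, network)
  keep <- is.finite(d) & d <= cutoff
  if (!any(keep)) return(0)
  areas <- uf$features$area_m2[match(names(d)[keep], uf$features$id)]
  sum(areas * decay(d[keep], params))
}

#' Greenspace standard counts
#'
#' Counts of greenspaces of at least 2 ha within 300 m, 20 ha within 2000 m,
#' and 100 ha within 5000 m network distance (accessible-greenspace
#' standards).
#'
#' @inheritParams distance_to_nearest
#' @return Named integer vector `c(ha2_300m, ha20_2000m, ha100_5000m)`.
#' @export
greenspace_standard_counts <- function(location, uf, network) {
  spec <- data.frame(min_ha = c(2, 20, 100), within_m = c(300, 2000, 5000))
  if (nrow(uf$features) == 0L) {
    return(stats::setNames(c(0L, 0L, 0L), c("ha2_300m", "ha20_2000m", "ha100_5000m")))
  }
  d <- feature_distances(location, uf, network)
  areas <- uf$features$area_m2[match(names(d), uf$features$id)]
  counts <- vapply(seq_len(3L), function(i) {
    sum(!is.na(areas) & areas >= spec$min_ha[i] * 1e4 & d <= spec$within_m[i])
  }, integer(1))
  stats::setNames(counts, c("ha2_300m", "ha20_2000m", "ha100_5000m"))
}

#' Fast-food outlet ratio
#'
#' Ratio of fast-food outlets to all food outlets within a radius; `NA` with
#' reason when no food outlet is in range.
#'
#' @inheritParams count_within
#' @export
outlet_ratio <- function(location, uf, network, radius,
                         distance_type = c("metric-network", "euclidean")) {
  distance_type <- match.arg(distance_type)
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  total <- count_within(location, uf, network, radius, distance_type)
  if (total == 0L) return(structure(NA_real_, reason = "zero-denominator"))
  ff_ids <- uf$features$id[isTRUE_vec(uf$features$fast_food)]
  if (length(ff_ids) == 0L) return(0)
  ff <- uf
  ff$features <- ff$features[ff$features$id %in% ff_ids, , drop = FALSE]
  ff$entrances <- ff$entrances[ff$entrances$feature_id %in% ff_ids, , drop = FALSE]
  if (!is.null(ff$snapped)) {
    ff$snapped <- ff$snapped[ff$snapped$feature_id %in% ff_ids, , drop = FALSE]
  }
  count_within(location, ff, network, radius, distance_type) / total
}

#' Feature exposure along a route
#'
#' Counts features with an entrance inside the corridor of the metric
#' shortest route between two locations.
#'
#' @param origin,dest Snapped locations (`network_location`).
#' @param uf An `urban_features` object.
#' @param network A `street_network`.
#' @param buffer_width Corridor half-width in meters (default 25).
#' @return Integer count, or `NA` with reason `"unreachable"`.
#' @export
route_exposure <- function(origin, dest, uf, network, buffer_width = 25) {
  rt <- shortest_path(origin, dest, network, "metric")
  if (!rt$reachable) return(structure(NA_integer_, reason = "unreachable"))
  geom <- rt$geometry
  if (is.null(geom) || nrow(geom) < 2L) {
    geom <- rbind(origin$snap_point, origin$snap_point + c(1e-9, 0))
  }
  zone <- zone_corridor(list(geom), buffer_width)
  inside <- zone_contains(zone, uf$entrances$x, uf$entrances$y)
  length(unique(uf$entrances$feature_id[inside]))
}
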