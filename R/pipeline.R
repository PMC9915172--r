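# Indicator pipeline: orchestrates every module into the long per-address
# indicator table across the eleven environmental domains.
#
# Every cell records the address (UPRN), domain (I-XI), measure, spatial
# relationship (a-i: a address, b street, c block, d nearest feature, e all
# features, f features in catchment, g circular buffer, h route corridor,
# i catchment buffer), distance type (1 straight-line, 2 metric network,
# 3 angular network, 4 decay-weighted network), the radius (m) or decay k
# (1/m) where applicable, the value, and a machine-readable reason whenever
# the value is missing. Missing values are never silent.

#' Pipeline configuration
#'
#' Radius defaults follow the indicator table conventions: raster domains use
#' circular buffers of 100-1500 m, feature domains network radii of
#' 300-5000 m, centrality metric radii 300-2000 m (the 1500 m entry is
#' configurable). All randomness lives in the synthetic-city generator; the
#' pipeline itself is deterministic.
#'
#' @param radii_raster Circular buffer radii (m) for raster domains.
#' @param radii_feature Network radii (m) for feature-accessibility domains.
#' @param radii_centrality Metric radii (m) for segment centralities.
#' @param catchment_radii Catchment thresholds (m) for catchment-buffer
#'   aggregation (relationship i).
#' @param k_grid Decay parameters (1/m) for decay-weighted measures.
#' @param buffer_width Corridor half-width (m) for catchment/route buffers.
#' @param nearest_cutoff Search cutoff (m) for nearest-feature distances.
#' @param traffic_catchment Traffic aggregation catchment (m).
#' @param max_segment_length Network dissection length (m).
#' @param snap_tolerance Address snap tolerance (m).
#' @param walkability_cell,walkability_neighborhood Walkability / land-use
#'   surface resolution and neighborhood radius (m).
#' @export
run_config <- function(radii_raster = c(100, 300, 500, 1000, 1500),
                       radii_feature = c(300, 500, 1000, 2000, 5000),
                       radii_centrality = c(300, 500, 1000, 1500, 2000),
                       catchment_radii = c(300, 1000),
                       k_grid = default_k_grid(),
                       buffer_width = 25,
                       nearest_cutoff = 5000,
                       traffic_catchment = 300,
                       max_segment_length = 20,
                       snap_tolerance = 500,
                       walkability_cell = 25,
                       walkability_neighborhood = 300) {
  as.list(environment())
}

#' Compute the full indicator table for a city
#'
#' @param city A `synthetic_city` (or any list with the same layers).
#' @param config A [run_config()].
#' @param verbose Print per-domain progress.
#' @return Long data frame of indicator records (one row per address x
#'   expanded indicator) with attributes `excluded` (unsnappable UPRNs) and
#'   `config`.
#' @export
compute_indicators <- function(city, config = run_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  say("building network ...")
  network <- build_network(city$streets$geoms, config$max_segment_length,
                           street_ids = city$streets$table$street_id)

  addr <- city$addresses
  snaps <- snap_points(as.matrix(addr[, c("x", "y")]), network,
                       config$snap_tolerance)
  excluded <- addr$uprn[is.na(snaps$seg)]
  if (length(excluded) > 0L) {
    say("excluding %d unsnappable addresses", length(excluded))
  }
  keep <- !is.na(snaps$seg)
  addr <- addr[keep, , drop = FALSE]
  snaps <- snaps[keep, , drop = FALSE]
  na <- nrow(addr)
  locs <- lapply(seq_len(na), function(i) {
    network_location(snaps$seg[i], snaps$offset[i], snaps$connector[i],
                     c(snaps$sx[i], snaps$sy[i]), c(addr$x[i], addr$y[i]))
  })

  say("computing catchments ...")
  thresholds <- sort(unique(c(config$catchment_radii, config$traffic_catchment,
                              300)))
  catch <- precompute_catchments(locs, thresholds, network)

  say("snapping features and computing feature distances ...")
  uf <- snap_entrances(city$features, network, config$snap_tolerance)
  fd <- feature_distance_table(locs, uf, network)

  say("rasters ...")
  ndvi <- compute_ndvi(city$rasters$nir, city$rasters$red)
  pollutants <- list(pm10 = city$rasters$pm10, pm25 = city$rasters$pm25,
                     nox = city$rasters$nox)

  say("surfaces (land use, walkability) ...")
  surf <- build_surfaces(city, uf, network, config)

  say("centralities ...")
  cents <- lapply(config$radii_centrality, function(r) {
    segment_centrality(network, r)
  })
  names(cents) <- as.character(config$radii_centrality)

  say("blocks ...")
  blocks <- polygonize_blocks(network)
  block_dens <- block_density_table(blocks, city$buildings)
  addr_block <- assign_blocks(addr, blocks)

  rows <- list()
  push <- function(df) rows[[length(rows) + 1L]] <<- df

  say("domain I: air quality ...")
  push(domain_raster_buffers(addr, pollutants, "I", config))
  push(domain_raster_catchments(addr, catch, pollutants, "I", config))

  say("domain II: traffic ...")
  push(domain_traffic(addr, locs, catch, city$traffic, network, config))

  say("domain III: greenness ...")
  push(domain_raster_buffers(addr, list(ndvi = ndvi), "III", config))
  push(domain_raster_catchments(addr, catch, list(ndvi = ndvi), "III", config))
  push(domain_street_ndvi(addr, locs, network, ndvi, config))

  say("domains IV-VI: feature accessibility ...")
  push(domain_features(addr, uf, fd, "IV", config))
  push(domain_features(addr, uf, fd, "V", config))
  push(domain_features(addr, uf, fd, "VI", config))
  push(domain_food_routes(addr, locs, uf, network, config))

  say("domains VII-VIII: land use and walkability ...")
  push(domain_raster_buffers(addr, surf$landuse_rasters, "VII", config))
  push(domain_raster_catchments(addr, catch, surf$landuse_rasters["sdi"],
                                "VII", config))
  push(domain_raster_buffers(addr, list(walkability = surf$walkability),
                             "VIII", config))
  push(domain_raster_catchments(addr, catch,
                                list(walkability = surf$walkability), "VIII",
                                config))

  say("domain IX: centrality ...")
  push(domain_centrality(addr, locs, catch, cents, network, config))

  say("domain X: built form ...")
  push(domain_built_form(addr, city$buildings, addr_block, block_dens))
  push(domain_dwellings(addr, city$dwellings))

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  say("done: %d rows in %.1f s", nrow(out),
      as.numeric(difftime(Sys.time(), t0, units = "secs")))
  structure(out, excluded = excluded, config = config)
}

# Vectorized long-row constructor; all arguments recycled to max length.
indicator_rows <- function(uprn, domain, measure, relationship, dtype,
                           param = NA_real_, value = NA_real_,
                           label = NA_character_, reason = NA_character_) {
  n <- max(length(uprn), length(measure), length(param), length(value))
  data.frame(uprn = rep_len(uprn, n), domain = rep_len(domain, n),
             measure = rep_len(measure, n),
             relationship = rep_len(relationship, n),
             dtype = rep_len(dtype, n), param = rep_len(param, n),
             value = rep_len(value, n), label = rep_len(label, n),
             reason = rep_len(reason, n), stringsAsFactors = FALSE)
}

## -- shared precomputations --------------------------------------------------

# Catchments for all addresses at all thresholds with one node-distance call.
precompute_catchments <- function(locs, thresholds, network) {
  segs <- network$segments
  o_seg <- vapply(locs, function(l) l$seg, integer(1))
  o_nodes <- unique(c(segs$node_u[o_seg], segs$node_v[o_seg]))
  D <- igraph::distances(network$graph, v = node_names(o_nodes),
                         weights = igraph::E(network$graph)$weight)
  out <- vector("list", length(locs))
  for (i in seq_along(locs)) {
    l <- locs[[i]]
    u <- segs$node_u[l$seg]; v <- segs$node_v[l$seg]
    L0 <- segs$length[l$seg]
    nd <- pmin(l$offset + D[match(u, o_nodes), ],
               (L0 - l$offset) + D[match(v, o_nodes), ])
    out[[i]] <- lapply(thresholds, function(th) {
      network_catchment(l, th, network, node_dists = nd)
    })
    names(out[[i]]) <- as.character(thresholds)
  }
  out
}

# Address x feature minimum network distances (meters), one igraph call.
feature_distance_table <- function(locs, uf, network) {
  ok <- !is.na(uf$snapped$seg)
  ids <- uf$features$id
  M <- matrix(Inf, length(locs), length(ids), dimnames = list(NULL, ids))
  E <- M
  if (any(ok)) {
    ents <- entrance_locations(filter_snapped(uf, ok))
    D <- nl_distance_matrix(locs, ents, network)
    feat_of <- uf$snapped$feature_id[ok]
    for (f in unique(feat_of)) {
      cols <- which(feat_of == f)
      M[, f] <- if (length(cols) == 1L) D[, cols] else
        do.call(pmin, lapply(cols, function(c2) D[, c2]))
    }
  }
  ax <- vapply(locs, function(l) l$source_point[1L], numeric(1))
  ay <- vapply(locs, function(l) l$source_point[2L], numeric(1))
  for (f in ids) {
    e <- uf$entrances[uf$entrances$feature_id == f, , drop = FALSE]
    d <- sqrt(outer(ax, e$x, "-")^2 + outer(ay, e$y, "-")^2)
    E[, f] <- apply(d, 1L, min)
  }
  list(network = M, euclid = E)
}

build_surfaces <- function(city, uf, network, config) {
  ext <- city$extent
  cell <- config$walkability_cell
  nb <- config$walkability_neighborhood
  sdi <- landuse_intensity_surface(uf, ext, cell, nb, equitability = FALSE)
  sdi_eq <- landuse_intensity_surface(uf, ext, cell, nb, equitability = TRUE)

  ax <- raster_axes(sdi)
  nr <- nrow(sdi$values); nc <- ncol(sdi$values)
  px <- rep(ax$x, each = nr)
  py <- rep(ax$y, times = nc)

  # transit accessibility: straight-line decay-weighted stop count per cell
  transit <- uf$entrances[
    uf$features$class[match(uf$entrances$feature_id, uf$features$id)] %in%
      c("bus", "rail", "metro", "coach"), , drop = FALSE]
  tv <- numeric(length(px))
  if (nrow(transit) > 0L) {
    for (i in seq_len(nrow(transit))) {
      tv <- tv + exp(-0.002 * sqrt((px - transit$x[i])^2 +
                                     (py - transit$y[i])^2))
    }
  }
  transit_r <- raster_surface(matrix(tv, nr, nc), sdi$xll, sdi$yll, cell)

  # street centrality: closeness of the nearest segment (1000 m radius)
  cent <- segment_centrality(network, 1000)
  mids <- t(vapply(network$geoms, function(g) {
    interpolate_along(g, polyline_length(g) / 2)
  }, numeric(2)))
  nearest_seg <- nearest_point_index(px, py, mids)
  cv <- cent$cc[nearest_seg]
  cv[is.na(cv)] <- 0
  cent_r <- raster_surface(matrix(cv, nr, nc), sdi$xll, sdi$yll, cell)

  # residential density: addresses within the neighborhood of each cell
  dv <- numeric(length(px))
  if (nrow(city$addresses) > 0L) {
    for (i in seq_len(nrow(city$addresses))) {
      dv <- dv + ((px - city$addresses$x[i])^2 +
                    (py - city$addresses$y[i])^2 <= nb^2)
    }
  }
  dens_r <- raster_surface(matrix(dv, nr, nc), sdi$xll, sdi$yll, cell)

  walk <- walkability_surface(list(landuse = sdi, transit = transit_r,
                                   centrality = cent_r, density = dens_r))
  list(landuse_rasters = list(sdi = sdi, sdi_equitability = sdi_eq),
       walkability = walk$surface)
}

# Index of the nearest reference point for each query point.
nearest_point_index <- function(px, py, ref) {
  best <- rep(1L, length(px))
  bestd <- (px - ref[1L, 1L])^2 + (py - ref[1L, 2L])^2
  for (i in seq_len(nrow(ref))[-1L]) {
    d <- (px - ref[i, 1L])^2 + (py - ref[i, 2L])^2
    hit <- d < bestd
    best[hit] <- i
    bestd[hit] <- d[hit]
  }
  best
}

## -- zonal helpers (fast masks shared across rasters) ------------------------

# Cell indices (into the value matrix) whose centers lie within each radius of
# a center point; returns a list parallel to radii.
circle_cell_index <- function(raster, center, radii) {
  ax <- raster_axes(raster)
  rmax <- max(radii)
  cols <- which(ax$x >= center[1L] - rmax & ax$x <= center[1L] + rmax)
  rows <- which(ax$y >= center[2L] - rmax & ax$y <= center[2L] + rmax)
  if (length(cols) == 0L || length(rows) == 0L) {
    return(lapply(radii, function(r) integer(0)))
  }
  nr <- nrow(raster$values)
  d2 <- outer((ax$y[rows] - center[2L])^2, (ax$x[cols] - center[1L])^2, "+")
  idx_full <- outer(rows, (cols - 1L) * nr, "+")
  lapply(radii, function(r) idx_full[d2 <= r * r])
}

# Cell indices whose centers lie within `width` of any portion polyline
# (rasterized per sub-segment in C++).
corridor_cell_index <- function(raster, portions, width) {
  x1 <- c(); y1 <- c(); x2 <- c(); y2 <- c()
  for (coords in portions) {
    n <- nrow(coords)
    if (n < 2L) next
    x1 <- c(x1, coords[-n, 1L]); y1 <- c(y1, coords[-n, 2L])
    x2 <- c(x2, coords[-1L, 1L]); y2 <- c(y2, coords[-1L, 2L])
  }
  if (length(x1) == 0L) return(integer(0))
  nr <- nrow(raster$values)
  ytop <- raster$yll + nr * raster$cellsize
  corridor_cells_cpp(raster$xll, ytop, raster$cellsize, nr,
                     ncol(raster$values), x1, y1, x2, y2, width)
}

stat_from_index <- function(raster, idx, stat) {
  if (length(idx) == 0L) return(structure(NA_real_, reason = "no-cells-covered"))
  v <- raster$values[idx]
  v <- v[v != raster$nodata & !is.na(v)]
  if (length(v) == 0L) return(structure(NA_real_, reason = "all-nodata"))
  if (stat == "mean") mean(v) else max(v)
}

## -- domains -----------------------------------------------------------------

# Circular-buffer zonal statistics (relationship g, straight-line radii).
domain_raster_buffers <- function(addr, rasters, domain, config) {
  radii <- config$radii_raster
  combos <- expand.grid(stat = c("mean", "max"), raster = names(rasters),
                        radius = radii, stringsAsFactors = FALSE)
  ncmb <- nrow(combos)
  na <- nrow(addr)
  V <- matrix(NA_real_, na, ncmb)
  R <- matrix(NA_character_, na, ncmb)
  grids <- !vapply(rasters, same_grid, logical(1), b = rasters[[1L]])
  for (i in seq_len(na)) {
    center <- c(addr$x[i], addr$y[i])
    idx_by_r <- circle_cell_index(rasters[[1L]], center, radii)
    idx_alt <- list()
    for (j in seq_len(ncmb)) {
      nm <- combos$raster[j]
      if (!grids[[nm]]) {
        idx <- idx_by_r[[match(combos$radius[j], radii)]]
      } else {
        key <- paste0(nm, "_", combos$radius[j])
        if (is.null(idx_alt[[key]])) {
          idx_alt[[key]] <- circle_cell_index(rasters[[nm]], center,
                                              combos$radius[j])[[1L]]
        }
        idx <- idx_alt[[key]]
      }
      v <- stat_from_index(rasters[[nm]], idx, combos$stat[j])
      V[i, j] <- v
      R[i, j] <- attr(v, "reason") %||% NA_character_
    }
  }
  indicator_rows(rep(addr$uprn, each = ncmb), domain,
                 paste0(combos$raster, "_", combos$stat)[rep(seq_len(ncmb), na)],
                 "g", 1L, combos$radius[rep(seq_len(ncmb), na)],
                 as.vector(t(V)), reason = as.vector(t(R)))
}

# Catchment-buffer zonal statistics (relationship i, network thresholds).
domain_raster_catchments <- function(addr, catch, rasters, domain, config) {
  ths <- config$catchment_radii
  combos <- expand.grid(stat = c("mean", "max"), raster = names(rasters),
                        threshold = ths, stringsAsFactors = FALSE)
  ncmb <- nrow(combos)
  na <- nrow(addr)
  V <- matrix(NA_real_, na, ncmb)
  R <- matrix(NA_character_, na, ncmb)
  grid_key <- vapply(rasters, function(r) {
    paste0(r$cellsize, "_", r$xll, "_", nrow(r$values))
  }, character(1))
  for (i in seq_len(na)) {
    for (th in ths) {
      ct <- catch[[i]][[as.character(th)]]
      idx_cache <- list()
      for (j in which(combos$threshold == th)) {
        nm <- combos$raster[j]
        key <- grid_key[[nm]]
        if (is.null(idx_cache[[key]])) {
          idx_cache[[key]] <- corridor_cell_index(rasters[[nm]], ct$geoms,
                                                  config$buffer_width)
        }
        v <- stat_from_index(rasters[[nm]], idx_cache[[key]], combos$stat[j])
        V[i, j] <- v
        R[i, j] <- attr(v, "reason") %||% NA_character_
      }
    }
  }
  indicator_rows(rep(addr$uprn, each = ncmb), domain,
                 paste0(combos$raster, "_", combos$stat)[rep(seq_len(ncmb), na)],
                 "i", 2L, combos$threshold[rep(seq_len(ncmb), na)],
                 as.vector(t(V)), reason = as.vector(t(R)))
}

# Mean NDVI over the corridor of the address's own street segment (b).
domain_street_ndvi <- function(addr, locs, network, ndvi, config) {
  na <- nrow(addr)
  vals <- numeric(na); reasons <- rep(NA_character_, na)
  for (i in seq_len(na)) {
    idx <- corridor_cell_index(ndvi, list(network$geoms[[locs[[i]]$seg]]),
                               config$buffer_width)
    v <- stat_from_index(ndvi, idx, "mean")
    vals[i] <- v
    reasons[i] <- attr(v, "reason") %||% NA_character_
  }
  indicator_rows(addr$uprn, "III", "ndvi_street_mean", "b", 1L, NA_real_,
                 vals, reason = reasons)
}

domain_traffic <- function(addr, locs, catch, records, network, config) {
  out <- vector("list", length(locs))
  for (i in seq_along(locs)) {
    ct <- catch[[i]][[as.character(config$traffic_catchment)]]
    ti <- traffic_indicators(locs[[i]], records, network,
                             config$traffic_catchment, catchment = ct)
    rel <- ifelse(ti$relationship == "street", "b", "f")
    out[[i]] <- indicator_rows(
      addr$uprn[i], "II",
      paste0(ti$measure, "_", ti$period,
             ifelse(ti$stat == "value", "", paste0("_", ti$stat))),
      rel, 2L, ifelse(rel == "f", config$traffic_catchment, NA_real_),
      ti$value, reason = ti$reason)
  }
  do.call(rbind, out)
}

# class groupings per feature domain
domain_classes <- function(domain) {
  switch(domain,
    "IV" = list(all_greenspace = c("public park or garden", "play space"),
                park = "public park or garden",
                play_space = "play space"),
    "V" = list(all_transit = c("bus", "rail", "metro", "coach"),
               bus = "bus", rail = "rail"),
    "VI" = list(all_food = c("fast-food outlet", "non-fast-food food outlet"),
                fast_food = "fast-food outlet")
  )
}

# Relationships (d), (e), (f): nearest distances, counts, decay-weighted
# counts/areas, ratios and greenspace standards, fully vectorized over
# addresses from the precomputed distance table.
domain_features <- function(addr, uf, fd, domain, config) {
  groups <- domain_classes(domain)
  fclass <- uf$features$class
  fids <- uf$features$id
  areas <- if ("area_m2" %in% names(uf$features)) uf$features$area_m2 else
    rep(NA_real_, length(fids))
  na <- nrow(addr)
  out <- list()
  row_min <- function(M) {
    if (ncol(M) == 0L) rep(Inf, nrow(M)) else
      do.call(pmin, lapply(seq_len(ncol(M)), function(j) M[, j]))
  }
  for (g in names(groups)) {
    cols <- fids[fclass %in% groups[[g]]]
    Dn <- fd$network[, cols, drop = FALSE]
    # (d) nearest
    nearest <- row_min(Dn)
    ok <- is.finite(nearest) & nearest <= config$nearest_cutoff
    reason <- ifelse(length(cols) == 0L, "no-features-of-class",
                     ifelse(ok, NA_character_, "beyond-cutoff"))
    out[[length(out) + 1L]] <- indicator_rows(
      addr$uprn, domain, paste0("nearest_", g), "d", 2L, NA_real_,
      ifelse(ok, nearest, NA_real_), reason = reason)
    # (f) counts within network radii
    for (r in config$radii_feature) {
      cnt <- rowSums(Dn <= r)
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, domain, paste0("count_", g), "f", 2L, r, cnt)
      if (domain == "VI" && g == "all_food") {
        nff <- rowSums(fd$network[, fids[fclass == "fast-food outlet"],
                                  drop = FALSE] <= r)
        out[[length(out) + 1L]] <- indicator_rows(
          addr$uprn, domain, "fast_food_ratio", "f", 2L, r,
          ifelse(cnt > 0, nff / cnt, NA_real_),
          reason = ifelse(cnt > 0, NA_character_, "zero-denominator"))
      }
    }
    # (e) decay-weighted counts (exp(-k * Inf) = 0 handles absent features)
    for (k in config$k_grid) {
      W <- exp(-k * Dn)
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, domain, paste0("decay_count_", g), "e", 4L, k, rowSums(W))
      if (domain == "IV") {
        ar <- areas[match(cols, fids)]
        ar[is.na(ar)] <- 0
        out[[length(out) + 1L]] <- indicator_rows(
          addr$uprn, domain, paste0("decay_area_", g), "e", 4L, k,
          as.vector(W %*% ar))
      }
    }
  }
  if (domain == "IV") {
    std <- data.frame(min_ha = c(2, 20, 100), within = c(300, 2000, 5000))
    gcols <- fids[fclass %in% groups$all_greenspace]
    gar <- areas[match(gcols, fids)]
    Dg <- fd$network[, gcols, drop = FALSE]
    for (s in seq_len(3L)) {
      big <- !is.na(gar) & gar >= std$min_ha[s] * 1e4
      cnt <- rowSums(Dg[, big, drop = FALSE] <= std$within[s])
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, domain, sprintf("greenspace_%dha", std$min_ha[s]),
        "f", 2L, std$within[s], cnt)
    }
  }
  do.call(rbind, out)
}

# (h): food outlets along the route from home toward the rail station.
domain_food_routes <- function(addr, locs, uf, network, config) {
  rail <- uf$snapped[
    uf$features$class[match(uf$snapped$feature_id, uf$features$id)] == "rail" &
      !is.na(uf$snapped$seg), , drop = FALSE]
  food <- uf
  keepf <- uf$features$class %in% c("fast-food outlet",
                                    "non-fast-food food outlet")
  food$features <- uf$features[keepf, , drop = FALSE]
  food$entrances <- uf$entrances[uf$entrances$feature_id %in% food$features$id, ,
                                 drop = FALSE]
  anchor <- if (nrow(rail) > 0L) {
    r <- rail[1L, ]
    network_location(r$seg, r$offset, r$connector, c(r$sx, r$sy), c(r$x, r$y))
  } else NULL
  na <- nrow(addr)
  vals <- rep(NA_real_, na); reasons <- rep(NA_character_, na)
  for (i in seq_len(na)) {
    if (is.null(anchor)) {
      reasons[i] <- "no-anchor-feature"
    } else {
      v <- route_exposure(locs[[i]], anchor, food, network,
                          config$buffer_width)
      vals[i] <- as.numeric(v)
      reasons[i] <- attr(v, "reason") %||% NA_character_
    }
  }
  indicator_rows(addr$uprn, "VI", "food_on_route_to_rail", "h", 2L,
                 config$buffer_width, vals, reason = reasons)
}

domain_centrality <- function(addr, locs, catch, cents, network, config) {
  na <- nrow(addr)
  out <- list()
  seg_of <- vapply(locs, function(l) l$seg, integer(1))
  catch_segs <- lapply(seq_len(na), function(i) {
    unique(c(seg_of[i], catch[[i]][["300"]]$segments))
  })
  for (ri in seq_along(cents)) {
    r <- as.numeric(names(cents)[ri])
    tab <- cents[[ri]]
    for (mm in c("cc", "cb")) {
      vals <- if (mm == "cc") tab$cc else tab$cb
      v_street <- vals[seg_of]
      street_reason <- if (mm == "cc") {
        ifelse(is.na(v_street), tab$cc_reason[seg_of], NA_character_)
      } else rep(NA_character_, na)
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, "IX", paste0(mm, "_street"), "b", 3L, r, v_street,
        reason = street_reason)
      v_mean <- numeric(na); v_max <- numeric(na)
      for (i in seq_len(na)) {
        v <- vals[catch_segs[[i]]]
        v <- v[!is.na(v)]
        if (length(v) == 0L) { v_mean[i] <- NA; v_max[i] <- NA }
        else { v_mean[i] <- mean(v); v_max[i] <- max(v) }
      }
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, "IX", paste0(mm, "_mean300"), "f", 3L, r, v_mean,
        reason = ifelse(is.na(v_mean), "undefined-closeness", NA_character_))
      out[[length(out) + 1L]] <- indicator_rows(
        addr$uprn, "IX", paste0(mm, "_max300"), "f", 3L, r, v_max,
        reason = ifelse(is.na(v_max), "undefined-closeness", NA_character_))
    }
  }
  do.call(rbind, out)
}

block_density_table <- function(blocks, buildings) {
  lapply(blocks, function(b) block_density(b, buildings))
}

assign_blocks <- function(addr, blocks) {
  out <- rep(NA_integer_, nrow(addr))
  for (b in blocks) {
    hit <- which(is.na(out))
    if (length(hit) == 0L) break
    inside <- point_in_polygon(addr$x[hit], addr$y[hit], b$ring)
    out[hit[inside]] <- b$id
  }
  out
}

domain_built_form <- function(addr, buildings, addr_block, block_dens) {
  na <- nrow(addr)
  bix <- match(addr$uprn, buildings$uprn)
  bm <- matrix(NA_real_, na, 4L,
               dimnames = list(NULL, c("footprint", "height", "volume",
                                       "floor_area")))
  for (i in which(!is.na(bix))) {
    bm[i, ] <- building_metrics(buildings$footprint[[bix[i]]],
                                buildings$height_m[bix[i]],
                                buildings$floors[bix[i]])
  }
  bd <- matrix(NA_real_, na, 4L, dimnames = list(NULL, c("fsi", "gsi", "osr",
                                                         "l")))
  for (i in which(!is.na(addr_block))) {
    bd[i, ] <- block_dens[[addr_block[i]]]
  }
  out <- list()
  for (nm in colnames(bm)) {
    out[[length(out) + 1L]] <- indicator_rows(
      addr$uprn, "X", paste0("building_", nm), "a", NA_integer_, NA_real_,
      bm[, nm],
      reason = ifelse(is.na(bm[, nm]), "no-building-for-address",
                      NA_character_))
  }
  for (nm in colnames(bd)) {
    out[[length(out) + 1L]] <- indicator_rows(
      addr$uprn, "X", paste0("block_", nm), "c", NA_integer_, NA_real_,
      bd[, nm],
      reason = ifelse(is.na(addr_block), "address-outside-blocks",
                      ifelse(is.na(bd[, nm]), "empty-block", NA_character_)))
  }
  do.call(rbind, out)
}

DOMAIN_X_FIELDS <- c("built_form", "dwelling_type", "construction_age_band",
                     "tenure", "storeys")

domain_dwellings <- function(addr, dwellings) {
  recs <- dwellings[dwellings$uprn %in% addr$uprn, , drop = FALSE]
  long <- dwelling_passthrough(recs, known_uprns = addr$uprn)
  dom <- ifelse(long$field %in% DOMAIN_X_FIELDS, "X", "XI")
  indicator_rows(long$uprn, dom, long$field, "a", NA_integer_, NA_real_,
                 long$numeric, label = long$value, reason = long$reason)
}

#' Pivot the long indicator table to wide
#'
#' One row per UPRN; one column per indicator (domain, measure, relationship,
#' distance type and radius/k encoded in the column name).
#' @param indicators Long table from [compute_indicators()].
#' @export
indicators_wide <- function(indicators) {
  key <- paste0(indicators$domain, ".", indicators$measure,
                ".", indicators$relationship,
                ifelse(is.na(indicators$param), "",
                       paste0(".", indicators$param)))
  uprns <- sort(unique(indicators$uprn))
  cols <- unique(key)
  M <- matrix(NA_real_, length(uprns), length(cols),
              dimnames = list(uprns, cols))
  M[cbind(match(indicators$uprn, uprns), match(key, cols))] <- indicators$value
  out <- data.frame(uprn = uprns)
  out <- cbind(out, as.data.frame(M, optional = TRUE))
  rownames(out) <- NULL
  out
}

#' Write indicator outputs
#'
#' Long CSV, wide CSV and a JSON run manifest (config echo, counts, package
#' version).
#' @param indicators Long table from [compute_indicators()].
#' @param dir Output directory.
#' @export
write_indicators <- function(indicators, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(indicators, file.path(dir, "indicators_long.csv"),
                   row.names = FALSE)
  utils::write.csv(indicators_wide(indicators),
                   file.path(dir, "indicators_wide.csv"), row.names = FALSE)
  manifest <- list(
    n_rows = nrow(indicators),
    n_addresses = length(unique(indicators$uprn)),
    excluded = attr(indicators, "excluded"),
    config = attr(indicators, "config"),
    package_version = as.character(utils::packageVersion("exposurekit"))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
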