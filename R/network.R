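# Pedestrian street-network model.
#
# Centerlines are noded at mutual intersections, dissected into segments of at
# most `max_segment_length` meters (default 20 m, split into ceiling(L/20)
# equal pieces to avoid stub segments), and assembled into a graph whose nodes
# are merged endpoints and whose edges are segments. Turn angles between
# adjacent segments are precomputed for angular (space-syntax) analysis.

#' Build a street network from centerlines
#'
#' @param centerlines A list of two-column coordinate matrices (meters), or
#'   the result of [read_geojson()] on a LineString layer.
#' @param max_segment_length Maximum segment length after dissection (m).
#' @param street_ids Optional vector of per-centerline identifiers carried onto
#'   segments (defaults to the centerline index).
#' @param node_tolerance Endpoint merge tolerance in meters (default 0.01).
#' @return A `street_network` object.
#' @export
build_network <- function(centerlines, max_segment_length = 20,
                          street_ids = NULL, node_tolerance = 0.01) {
  if (is.list(centerlines) && !is.null(centerlines$geometry)) {
    if (is.null(street_ids) && !is.null(centerlines$properties$street_id)) {
      street_ids <- centerlines$properties$street_id
    }
    centerlines <- centerlines$geometry
  }
  if (is.matrix(centerlines)) centerlines <- list(centerlines)
  if (length(centerlines) == 0L) stop("empty centerline input", call. = FALSE)
  if (max_segment_length <= 0) stop("max_segment_length must be > 0", call. = FALSE)
  check_projected(centerlines)
  if (is.null(street_ids)) street_ids <- seq_along(centerlines)
  total_input <- sum(vapply(centerlines, polyline_length, numeric(1)))
  if (total_input <= 0) stop("empty-network: centerlines have zero length", call. = FALSE)

  noded <- node_centerlines(centerlines)
  geoms <- list(); seg_street <- c()
  for (i in seq_along(noded$pieces)) {
    L <- polyline_length(noded$pieces[[i]])
    if (L <= 1e-9) next
    n_parts <- max(1L, ceiling(L / max_segment_length - 1e-9))
    cuts <- seq_len(n_parts - 1L) * (L / n_parts)
    parts <- split_polyline_at(noded$pieces[[i]], cuts)
    geoms <- c(geoms, parts)
    seg_street <- c(seg_street, rep(street_ids[noded$street[i]], length(parts)))
  }
  nseg <- length(geoms)
  lengths <- vapply(geoms, polyline_length, numeric(1))

  # merge endpoints into nodes with tolerance
  ends <- do.call(rbind, lapply(geoms, function(g) rbind(g[1L, ], g[nrow(g), ])))
  key <- paste(round(ends[, 1L] / node_tolerance), round(ends[, 2L] / node_tolerance))
  node_id <- match(key, unique(key))
  first_idx <- match(seq_len(max(node_id)), node_id)
  nodes <- data.frame(node = seq_len(max(node_id)),
                      x = ends[first_idx, 1L], y = ends[first_idx, 2L])
  node_u <- node_id[seq(1L, 2L * nseg, by = 2L)]
  node_v <- node_id[seq(2L, 2L * nseg, by = 2L)]

  segments <- data.frame(seg = seq_len(nseg), street = seg_street,
                         length = lengths, node_u = node_u, node_v = node_v)

  adjacency <- build_adjacency(segments, geoms)

  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(node_u), to = as.character(node_v),
               weight = lengths, seg = seq_len(nseg)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes$node))
  )

  structure(
    list(segments = segments, geoms = geoms, nodes = nodes,
         adjacency = adjacency, graph = g,
         max_segment_length = max_segment_length,
         total_input_length = total_input,
         node_tolerance = node_tolerance),
    class = "street_network"
  )
}

#' @export
print.street_network <- function(x, ...) {
  cat(sprintf("street_network: %d segments (max %g m), %d nodes, total %.1f m\n",
              nrow(x$segments), x$max_segment_length, nrow(x$nodes),
              sum(x$segments$length)))
  invisible(x)
}

# Split centerlines at their mutual crossings and touch points so the graph is
# properly noded. Returns pieces plus the index of the source street.
node_centerlines <- function(lines) {
  nl <- length(lines)
  cut_dists <- vector("list", nl)
  subsegs <- lapply(lines, function(m) {
    n <- nrow(m)
    list(a = m[-n, , drop = FALSE], b = m[-1L, , drop = FALSE],
         cum = polyline_cumdist(m))
  })
  if (nl > 1L) {
    for (i in seq_len(nl - 1L)) {
      for (j in seq.int(i + 1L, nl)) {
        si <- subsegs[[i]]; sj <- subsegs[[j]]
        for (p in seq_len(nrow(si$a))) {
          for (q in seq_len(nrow(sj$a))) {
            hit <- segment_intersection(si$a[p, ], si$b[p, ], sj$a[q, ], sj$b[q, ])
            if (!is.null(hit)) {
              li <- sqrt(sum((si$b[p, ] - si$a[p, ])^2))
              lj <- sqrt(sum((sj$b[q, ] - sj$a[q, ])^2))
              cut_dists[[i]] <- c(cut_dists[[i]], si$cum[p] + hit[1L] * li)
              cut_dists[[j]] <- c(cut_dists[[j]], sj$cum[q] + hit[2L] * lj)
            }
          }
        }
      }
    }
  }
  pieces <- list(); street <- integer(0)
  for (i in seq_len(nl)) {
    parts <- split_polyline_at(lines[[i]], cut_dists[[i]])
    pieces <- c(pieces, parts)
    street <- c(street, rep(i, length(parts)))
  }
  list(pieces = pieces, street = street)
}

# Direction (unit-ish vector) of a segment leaving a given end.
segment_direction_from <- function(coords, from_start) {
  n <- nrow(coords)
  if (from_start) coords[2L, ] - coords[1L, ] else coords[n - 1L, ] - coords[n, ]
}

# Turn angles for every unordered pair of segments sharing a node.
# Continuing straight is 0 degrees; a right angle 90; a full reversal 180.
build_adjacency <- function(segments, geoms) {
  inc <- rbind(
    data.frame(node = segments$node_u, seg = segments$seg, at_start = TRUE),
    data.frame(node = segments$node_v, seg = segments$seg, at_start = FALSE)
  )
  out <- list(); k <- 0L
  for (n in unique(inc$node)) {
    rows <- inc[inc$node == n, , drop = FALSE]
    m <- nrow(rows)
    if (m < 2L) next
    dirs <- t(vapply(seq_len(m), function(r) {
      segment_direction_from(geoms[[rows$seg[r]]], rows$at_start[r])
    }, numeric(2)))
    for (a in seq_len(m - 1L)) {
      for (b in seq.int(a + 1L, m)) {
        if (rows$seg[a] == rows$seg[b]) next  # a loop edge meeting itself
        ang <- 180 - vector_angle(dirs[a, 1L], dirs[a, 2L], dirs[b, 1L], dirs[b, 2L])
        # snap float noise from acos() so collinear continuations cost exactly 0
        if (ang < 1e-4) ang <- 0
        k <- k + 1L
        out[[k]] <- data.frame(node = n, seg_i = rows$seg[a], seg_j = rows$seg[b],
                               angle = ang)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(node = integer(0), seg_i = integer(0),
                      seg_j = integer(0), angle = numeric(0)))
  }
  do.call(rbind, out)
}

# Segment-adjacency (dual) arrays: angular cost = angle/90 per turn; metric
# step cost = (len_i + len_j)/2 (segment midpoint to midpoint).
dual_arrays <- function(network) {
  adj <- network$adjacency
  len <- network$segments$length
  list(i = adj$seg_i, j = adj$seg_j,
       ang = adj$angle / 90,
       met = (len[adj$seg_i] + len[adj$seg_j]) / 2)
}

## Snapping -------------------------------------------------------------------

#' Snap a point to the street network
#'
#' @param point Numeric length-2 (x, y) in meters.
#' @param network A `street_network`.
#' @param tolerance Maximum snap distance in meters (default 500).
#' @return A `network_location` (segment id, offset along segment, connector
#'   length, snapped coordinates).
#' @export
snap_to_network <- function(point, network, tolerance = 500) {
  res <- snap_points(matrix(point, ncol = 2L), network, tolerance)
  if (is.na(res$seg[1L])) {
    stop(sprintf("unsnappable-address: nearest street is %.1f m away (tolerance %g m)",
                 res$connector[1L], tolerance), call. = FALSE)
  }
  network_location(res$seg[1L], res$offset[1L], res$connector[1L],
                   c(res$sx[1L], res$sy[1L]), c(point[1L], point[2L]))
}

#' Snap many points to the street network
#'
#' Vectorized snapping; points beyond the tolerance get `NA` segment ids
#' rather than an error.
#'
#' @param xy Two-column matrix of points.
#' @inheritParams snap_to_network
#' @return Data frame: seg, offset, connector, sx, sy.
#' @export
snap_points <- function(xy, network, tolerance = 500) {
  np <- nrow(xy)
  best <- list(dist = rep(Inf, np), seg = rep(NA_integer_, np),
               offset = rep(NA_real_, np), sx = rep(NA_real_, np),
               sy = rep(NA_real_, np))
  for (s in seq_along(network$geoms)) {
    coords <- network$geoms[[s]]
    cd <- polyline_cumdist(coords)
    n <- nrow(coords)
    for (k in seq_len(n - 1L)) {
      pr <- point_segment_distance(xy[, 1L], xy[, 2L],
                                   coords[k, 1L], coords[k, 2L],
                                   coords[k + 1L, 1L], coords[k + 1L, 2L])
      better <- pr$dist < best$dist
      if (any(better)) {
        seg_len <- cd[k + 1L] - cd[k]
        best$dist[better] <- pr$dist[better]
        best$seg[better] <- s
        best$offset[better] <- cd[k] + pr$t[better] * seg_len
        best$sx[better] <- pr$qx[better]
        best$sy[better] <- pr$qy[better]
      }
    }
  }
  too_far <- best$dist > tolerance
  out <- data.frame(seg = best$seg, offset = best$offset,
                    connector = best$dist, sx = best$sx, sy = best$sy)
  out$seg[too_far] <- NA_integer_
  out
}

#' Construct a network location
#' @keywords internal
#' @export
network_location <- function(seg, offset, connector = 0, snap_point = NULL,
                             source_point = NULL) {
  structure(list(seg = seg, offset = offset, connector = connector,
                 snap_point = snap_point, source_point = source_point),
            class = "network_location")
}

## Distances ------------------------------------------------------------------

node_names <- function(nodes) as.character(nodes)

# Metric network distance matrix between two sets of network locations.
# Distances include partial segments at both ends; connectors are added when
# include_connectors is TRUE. Same-segment pairs also consider the direct
# along-segment path.
#' Metric network distances between sets of network locations
#' @param origins,dests Lists of `network_location` objects.
#' @param network A `street_network`.
#' @param include_connectors Add the off-network connector lengths (default TRUE).
#' @return A numeric matrix (origins x dests); `Inf` where unreachable.
#' @export
nl_distance_matrix <- function(origins, dests, network, include_connectors = TRUE) {
  segs <- network$segments
  o_seg <- vapply(origins, function(l) l$seg, integer(1))
  d_seg <- vapply(dests, function(l) l$seg, integer(1))
  o_off <- vapply(origins, function(l) l$offset, numeric(1))
  d_off <- vapply(dests, function(l) l$offset, numeric(1))
  o_con <- vapply(origins, function(l) l$connector, numeric(1))
  d_con <- vapply(dests, function(l) l$connector, numeric(1))
  o_u <- segs$node_u[o_seg]; o_v <- segs$node_v[o_seg]
  d_u <- segs$node_u[d_seg]; d_v <- segs$node_v[d_seg]
  o_len <- segs$length[o_seg]; d_len <- segs$length[d_seg]

  vs <- unique(c(o_u, o_v))
  ts <- unique(c(d_u, d_v))
  D <- igraph::distances(network$graph, v = node_names(vs), to = node_names(ts),
                         weights = igraph::E(network$graph)$weight)
  iu <- match(o_u, vs); iv <- match(o_v, vs)
  ju <- match(d_u, ts); jv <- match(d_v, ts)

  no <- length(origins); nd <- length(dests)
  a <- matrix(o_off, no, nd)          # origin -> its u node
  a2 <- matrix(o_len - o_off, no, nd) # origin -> its v node
  b <- matrix(d_off, no, nd, byrow = TRUE)
  b2 <- matrix(d_len - d_off, no, nd, byrow = TRUE)
  M <- pmin(a + D[iu, ju, drop = FALSE] + b,
            a + D[iu, jv, drop = FALSE] + b2,
            a2 + D[iv, ju, drop = FALSE] + b,
            a2 + D[iv, jv, drop = FALSE] + b2)
  same <- outer(o_seg, d_seg, "==")
  if (any(same)) {
    direct <- abs(outer(o_off, d_off, "-"))
    M[same] <- pmin(M[same], direct[same])
  }
  if (include_connectors) {
    M <- M + matrix(o_con, no, nd) + matrix(d_con, no, nd, byrow = TRUE)
  }
  M
}

#' Metric network distance between two network locations
#' @inheritParams nl_distance_matrix
#' @export
nl_distance <- function(origin, dest, network, include_connectors = TRUE) {
  nl_distance_matrix(list(origin), list(dest), network, include_connectors)[1L, 1L]
}

## Shortest paths -------------------------------------------------------------

#' Shortest route between two network locations
#'
#' Metric routes minimize length in meters (partial segments and connectors
#' included). Angular routes minimize cumulative turn cost on the segment
#' adjacency graph (turn angle / 90 per junction; continuing straight is
#' free), with ties broken by metric length then by segment id; the route
#' reports both the angular cost and the metric length of the chosen path.
#' Connectors count toward metric length but carry no angular cost.
#'
#' @param origin,dest `network_location` objects.
#' @param network A `street_network`.
#' @param distance_type `"metric"` or `"angular"`.
#' @return A `route` object (segments, metric_length, angular_cost, geometry),
#'   or a route with `reachable = FALSE` when no path exists.
#' @export
shortest_path <- function(origin, dest, network,
                          distance_type = c("metric", "angular")) {
  distance_type <- match.arg(distance_type)
  if (distance_type == "metric") route_metric(origin, dest, network)
  else route_angular(origin, dest, network)
}

route_result <- function(origin, dest, segments, metric_length, angular_cost,
                         geometry = NULL, reachable = TRUE) {
  structure(list(origin = origin, dest = dest, segments = segments,
                 metric_length = metric_length, angular_cost = angular_cost,
                 geometry = geometry, reachable = reachable),
            class = "route")
}

# Angular turn cost between consecutive segments in a node path.
path_angular_cost <- function(seg_path, network) {
  if (length(seg_path) < 2L) return(0)
  adj <- network$adjacency
  total <- 0
  for (i in seq_len(length(seg_path) - 1L)) {
    a <- seg_path[i]; b <- seg_path[i + 1L]
    hit <- adj[(adj$seg_i == a & adj$seg_j == b) |
                 (adj$seg_i == b & adj$seg_j == a), , drop = FALSE]
    if (nrow(hit) == 0L) stop("non-adjacent consecutive segments in path")
    total <- total + min(hit$angle) / 90
  }
  total
}

route_metric <- function(origin, dest, network) {
  segs <- network$segments
  conn <- origin$connector + dest$connector
  if (origin$seg == dest$seg) {
    len <- abs(origin$offset - dest$offset)
    geom <- substring_polyline(network$geoms[[origin$seg]],
                               min(origin$offset, dest$offset),
                               max(origin$offset, dest$offset))
    # a loop through nodes could still be shorter in pathological geometries
    via <- nl_via_nodes(origin, dest, network)
    if (via$dist < len - 1e-9) {
      return(route_from_nodepath(origin, dest, via, network, conn))
    }
    return(route_result(origin, dest, origin$seg, len + conn, 0, geom))
  }
  via <- nl_via_nodes(origin, dest, network)
  if (!is.finite(via$dist)) {
    return(route_result(origin, dest, integer(0), NA_real_, NA_real_,
                        reachable = FALSE))
  }
  route_from_nodepath(origin, dest, via, network, conn)
}

# Best origin-end / dest-end combination and its node-graph path.
nl_via_nodes <- function(origin, dest, network) {
  segs <- network$segments
  o_ends <- c(segs$node_u[origin$seg], segs$node_v[origin$seg])
  o_costs <- c(origin$offset, segs$length[origin$seg] - origin$offset)
  d_ends <- c(segs$node_u[dest$seg], segs$node_v[dest$seg])
  d_costs <- c(dest$offset, segs$length[dest$seg] - dest$offset)
  D <- igraph::distances(network$graph, v = node_names(o_ends),
                         to = node_names(d_ends),
                         weights = igraph::E(network$graph)$weight)
  tot <- outer(o_costs, d_costs, "+") + D
  k <- arrayInd(which.min(tot), dim(tot))
  list(dist = tot[k], o_end = o_ends[k[1L]], d_end = d_ends[k[2L]],
       o_cost = o_costs[k[1L]], d_cost = d_costs[k[2L]])
}

route_from_nodepath <- function(origin, dest, via, network, conn) {
  sp <- igraph::shortest_paths(network$graph,
                               from = as.character(via$o_end),
                               to = as.character(via$d_end),
                               weights = igraph::E(network$graph)$weight,
                               output = "both")
  epath <- sp$epath[[1L]]
  mid_segs <- igraph::edge_attr(network$graph, "seg", epath)
  seg_path <- c(origin$seg, mid_segs, dest$seg)
  seg_path <- seg_path[c(TRUE, diff(seg_path) != 0L)]  # collapse repeats at joins
  metric <- via$o_cost + sum(network$segments$length[mid_segs]) + via$d_cost + conn
  ang <- path_angular_cost(seg_path, network)
  geom <- route_geometry(origin, dest, via, mid_segs, sp$vpath[[1L]], network)
  route_result(origin, dest, seg_path, metric, ang, geom)
}

route_geometry <- function(origin, dest, via, mid_segs, vpath, network) {
  segs <- network$segments
  pieces <- list()
  # origin partial: from offset toward the chosen end
  og <- network$geoms[[origin$seg]]
  o_len <- segs$length[origin$seg]
  if (via$o_end == segs$node_u[origin$seg]) {
    p <- substring_polyline(og, 0, origin$offset)
    pieces[[1L]] <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  } else {
    pieces[[1L]] <- substring_polyline(og, origin$offset, o_len)
  }
  node_ids <- as.integer(igraph::vertex_attr(network$graph, "name", vpath))
  if (length(mid_segs) > 0L) {
    for (i in seq_along(mid_segs)) {
      g <- network$geoms[[mid_segs[i]]]
      if (segs$node_u[mid_segs[i]] != node_ids[i]) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
      pieces[[length(pieces) + 1L]] <- g
    }
  }
  dg <- network$geoms[[dest$seg]]
  d_len <- segs$length[dest$seg]
  if (via$d_end == segs$node_u[dest$seg]) {
    pieces[[length(pieces) + 1L]] <- substring_polyline(dg, 0, dest$offset)
  } else {
    p <- substring_polyline(dg, dest$offset, d_len)
    pieces[[length(pieces) + 1L]] <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  }
  do.call(rbind, pieces)
}

# Angular route via label-setting on the dual graph. States are segments; the
# cost to enter the origin segment is zero, and each adjacency traversal adds
# its turn cost. Ties are broken by accumulated metric length, then by the
# smaller predecessor segment id.
route_angular <- function(origin, dest, network) {
  conn <- origin$connector + dest$connector
  if (origin$seg == dest$seg) {
    len <- abs(origin$offset - dest$offset)
    geom <- substring_polyline(network$geoms[[origin$seg]],
                               min(origin$offset, dest$offset),
                               max(origin$offset, dest$offset))
    return(route_result(origin, dest, origin$seg, len + conn, 0, geom))
  }
  da <- dual_arrays(network)
  nseg <- nrow(network$segments)
  adj_list <- vector("list", nseg)
  for (r in seq_along(da$i)) {
    adj_list[[da$i[r]]] <- rbind(adj_list[[da$i[r]]], c(da$j[r], da$ang[r]))
    adj_list[[da$j[r]]] <- rbind(adj_list[[da$j[r]]], c(da$i[r], da$ang[r]))
  }
  dist_a <- rep(Inf, nseg); dist_m <- rep(Inf, nseg)
  pred <- rep(NA_integer_, nseg)
  done <- rep(FALSE, nseg)
  dist_a[origin$seg] <- 0; dist_m[origin$seg] <- 0
  lens <- network$segments$length
  repeat {
    active <- which(!done & is.finite(dist_a))
    if (length(active) == 0L) break
    u <- active[order(dist_a[active], dist_m[active], active)][1L]
    done[u] <- TRUE
    if (u == dest$seg) break
    nb <- adj_list[[u]]
    if (is.null(nb)) next
    for (r in seq_len(nrow(nb))) {
      v <- nb[r, 1L]
      if (done[v]) next
      na <- dist_a[u] + nb[r, 2L]
      nm <- dist_m[u] + (lens[u] + lens[v]) / 2
      if (na < dist_a[v] - 1e-6 ||
          (na < dist_a[v] + 1e-6 &&
           (nm < dist_m[v] - 1e-9 ||
            (nm < dist_m[v] + 1e-9 && !is.na(pred[v]) && u < pred[v])))) {
        dist_a[v] <- na; dist_m[v] <- nm; pred[v] <- u
      }
    }
  }
  if (!is.finite(dist_a[dest$seg])) {
    return(route_result(origin, dest, integer(0), NA_real_, NA_real_,
                        reachable = FALSE))
  }
  seg_path <- dest$seg
  while (seg_path[1L] != origin$seg) seg_path <- c(pred[seg_path[1L]], seg_path)
  metric <- angular_route_metric_length(seg_path, origin, dest, network) + conn
  route_result(origin, dest, seg_path, metric, dist_a[dest$seg], NULL)
}

# Metric length of a segment path: partial origin and dest segments toward the
# shared nodes, full interior segments.
angular_route_metric_length <- function(seg_path, origin, dest, network) {
  segs <- network$segments
  shared_node <- function(a, b) {
    na <- c(segs$node_u[a], segs$node_v[a])
    nb <- c(segs$node_u[b], segs$node_v[b])
    intersect(na, nb)[1L]
  }
  n <- length(seg_path)
  if (n == 1L) return(abs(origin$offset - dest$offset))
  first_exit <- shared_node(seg_path[1L], seg_path[2L])
  o_part <- if (first_exit == segs$node_u[origin$seg]) origin$offset
            else segs$length[origin$seg] - origin$offset
  last_enter <- shared_node(seg_path[n - 1L], seg_path[n])
  d_part <- if (last_enter == segs$node_u[dest$seg]) dest$offset
            else segs$length[dest$seg] - dest$offset
  interior <- if (n > 2L) sum(segs$length[seg_path[2:(n - 1L)]]) else 0
  o_part + interior + d_part
}

## Catchments -----------------------------------------------------------------

#' Metric network catchment around a network location
#'
#' All segment portions whose metric network distance from the origin is at
#' most `threshold` meters; segments crossed by the distance frontier are split
#' there. The connector length counts toward the threshold when
#' `include_connector` is TRUE.
#'
#' @param origin A `network_location`.
#' @param threshold Metric distance threshold in meters (> 0).
#' @param network A `street_network`.
#' @param include_connector Whether the connector consumes threshold budget.
#' @param node_dists Optional precomputed named vector of node distances from
#'   this origin's segment end nodes (internal speed-up).
#' @return A `catchment` (portions, total reachable length, segment ids).
#' @export
network_catchment <- function(origin, threshold, network,
                              include_connector = TRUE, node_dists = NULL) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  segs <- network$segments
  d0 <- if (include_connector) origin$connector else 0
  budget <- threshold - d0
  empty <- function() {
    pt <- matrix(rep(origin$snap_point %||% c(NA_real_, NA_real_), 2L),
                 ncol = 2L, byrow = TRUE)
    structure(list(origin = origin, threshold = threshold,
                   portions = data.frame(seg = integer(0), from = numeric(0),
                                         to = numeric(0)),
                   geoms = list(pt), total_length = 0,
                   segments = integer(0)),
              class = "catchment")
  }
  if (budget <= 0) return(empty())
  u <- segs$node_u[origin$seg]; v <- segs$node_v[origin$seg]
  L0 <- segs$length[origin$seg]
  if (is.null(node_dists)) {
    D <- igraph::distances(network$graph, v = node_names(c(u, v)),
                           weights = igraph::E(network$graph)$weight)
    # vertex order equals node id order (1..n)
    nd <- pmin(origin$offset + D[1L, ], (L0 - origin$offset) + D[2L, ])
  } else {
    nd <- node_dists
  }
  nd <- unname(nd)
  L <- segs$length
  # covered lengths from each end of every segment
  covA <- pmin(pmax(budget - nd[segs$node_u], 0), L)
  covB <- pmin(pmax(budget - nd[segs$node_v], 0), L)
  covA[!is.finite(covA)] <- 0
  covB[!is.finite(covB)] <- 0
  seg_from <- vector("list", nrow(segs))
  seg_to <- vector("list", nrow(segs))
  full <- covA + covB >= L - 1e-9 & (covA > 0 | covB > 0)
  partA <- !full & covA > 1e-9
  partB <- !full & covB > 1e-9
  for (s in which(full)) { seg_from[[s]] <- 0; seg_to[[s]] <- L[s] }
  for (s in which(partA)) { seg_from[[s]] <- 0; seg_to[[s]] <- covA[s] }
  for (s in which(partB)) {
    seg_from[[s]] <- c(seg_from[[s]], L[s] - covB[s])
    seg_to[[s]] <- c(seg_to[[s]], L[s])
  }
  # origin segment: direct interval from the offset, merged with node-side
  os <- origin$seg
  lo <- max(0, origin$offset - budget)
  hi <- min(L[os], origin$offset + budget)
  ivs <- list(c(lo, hi))
  if (length(seg_from[[os]]) > 0L) {
    for (j in seq_along(seg_from[[os]])) {
      ivs[[length(ivs) + 1L]] <- c(seg_from[[os]][j], seg_to[[os]][j])
    }
  }
  merged <- merge_intervals(ivs)
  seg_from[[os]] <- vapply(merged, `[`, numeric(1), 1L)
  seg_to[[os]] <- vapply(merged, `[`, numeric(1), 2L)

  covered <- which(lengths(seg_from) > 0L)
  if (length(covered) == 0L) return(empty())
  pdf <- data.frame(
    seg = rep(covered, lengths(seg_from[covered])),
    from = unlist(seg_from[covered]),
    to = unlist(seg_to[covered])
  )
  keep <- pdf$to - pdf$from > 1e-9
  pdf <- pdf[keep, , drop = FALSE]
  if (nrow(pdf) == 0L) return(empty())
  geoms <- lapply(seq_len(nrow(pdf)), function(i) {
    s <- pdf$seg[i]
    if (pdf$from[i] <= 1e-9 && pdf$to[i] >= L[s] - 1e-9) network$geoms[[s]]
    else substring_polyline(network$geoms[[s]], pdf$from[i], pdf$to[i])
  })
  structure(list(origin = origin, threshold = threshold, portions = pdf,
                 geoms = geoms, total_length = sum(pdf$to - pdf$from),
                 segments = unique(pdf$seg)),
            class = "catchment")
}

merge_intervals <- function(ivs) {
  m <- do.call(rbind, ivs)
  m <- m[order(m[, 1L]), , drop = FALSE]
  out <- list(m[1L, ])
  for (i in seq_len(nrow(m))[-1L]) {
    last <- out[[length(out)]]
    if (m[i, 1L] <= last[2L] + 1e-9) {
      out[[length(out)]] <- c(last[1L], max(last[2L], m[i, 2L]))
    } else {
      out[[length(out) + 1L]] <- m[i, ]
    }
  }
  out
}

#' @export
print.catchment <- function(x, ...) {
  cat(sprintf("catchment: threshold %g m, %.1f m reachable over %d portions\n",
              x$threshold, x$total_length, nrow(x$portions)))
  invisible(x)
}

#' Buffered corridor around a catchment
#'
#' @param catchment A `catchment`.
#' @param width Corridor half-width in meters (default 25).
#' @return A `zone_corridor` usable with [zonal_stat()] and [zone_area()].
#' @export
catchment_buffer <- function(catchment, width = 25) {
  if (width <= 0) stop("buffer width must be positive", call. = FALSE)
  zone_corridor(catchment$geoms, width)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Blocks ---------------------------------------------------------------------

#' Polygonize the street network into urban blocks
#'
#' Traces the minimal enclosed faces of the planar street arrangement; each
#' face becomes one block. Tree-like networks yield zero blocks.
#'
#' @param network A `street_network`.
#' @return A list of blocks, each with `id`, `ring` (coordinates), `area` (m2)
#'   and `segments` (bounding segment ids).
#' @export
polygonize_blocks <- function(network) {
  segs <- network$segments
  nseg <- nrow(segs)
  if (nseg == 0L) return(list())
  # directed half-edges: 2s-1 = u->v, 2s = v->u
  he_from <- c(rbind(segs$node_u, segs$node_v))
  he_to <- c(rbind(segs$node_v, segs$node_u))
  he_seg <- rep(segs$seg, each = 2L)
  bearing_at <- function(s, at_start) {
    d <- segment_direction_from(network$geoms[[s]], at_start)
    atan2(d[2L], d[1L])
  }
  # outgoing bearing of each half-edge at its from-node
  he_bear <- vapply(seq_along(he_from), function(h) {
    s <- he_seg[h]
    from_start <- (h %% 2L == 1L)  # odd half-edges start at node_u
    bearing_at(s, from_start)
  }, numeric(1))
  out_by_node <- split(seq_along(he_from), he_from)
  twin <- function(h) if (h %% 2L == 1L) h + 1L else h - 1L
  next_he <- integer(length(he_from))
  for (h in seq_along(he_from)) {
    n <- he_to[h]
    outs <- out_by_node[[as.character(n)]]
    tw <- twin(h)
    if (length(outs) == 1L) { next_he[h] <- outs; next }
    ref <- he_bear[tw]
    # next face edge: the clockwise-next outgoing edge from the reversed
    # incoming direction (largest CCW angle), so interior faces are traced
    # counter-clockwise and carry positive signed area
    cand <- outs[outs != tw]
    delta <- (he_bear[cand] - ref) %% (2 * pi)
    delta[delta < 1e-12] <- 2 * pi
    next_he[h] <- cand[which.max(delta)]
  }
  visited <- rep(FALSE, length(he_from))
  blocks <- list()
  for (h0 in seq_along(he_from)) {
    if (visited[h0]) next
    cycle <- integer(0)
    h <- h0
    repeat {
      visited[h] <- TRUE
      cycle <- c(cycle, h)
      h <- next_he[h]
      if (h == h0) break
      if (visited[h]) { cycle <- NULL; break }
    }
    if (is.null(cycle)) next
    ring <- do.call(rbind, lapply(cycle, function(hh) {
      g <- network$geoms[[he_seg[hh]]]
      if (hh %% 2L == 0L) g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
      g[-nrow(g), , drop = FALSE]
    }))
    a <- polygon_signed_area(ring)
    if (a > 1e-6) {
      blocks[[length(blocks) + 1L]] <-
        list(id = length(blocks) + 1L, ring = ring, area = a,
             segments = unique(he_seg[cycle]))
    }
  }
  blocks
}

#' Find the block containing a point
#' @param point Numeric length-2 (x, y).
#' @param blocks Result of [polygonize_blocks()].
#' @return The block id, or `NA_integer_` if none contains the point.
#' @export
block_containing <- function(point, blocks) {
  for (b in blocks) {
    if (point_in_polygon(point[1L], point[2L], b$ring)) return(b$id)
  }
  NA_integer_
}
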