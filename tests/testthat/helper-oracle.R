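# Brute-force oracles and toy-network builders shared across tests.

# Toy geometries ---------------------------------------------------------------

toy_cross <- function(arm = 100) {
  list(cbind(c(-arm, arm), c(0, 0)), cbind(c(0, 0), c(-arm, arm)))
}

toy_grid <- function(n = 2, sp = 100) {
  c(lapply(0:n, function(i) cbind(c(i * sp, i * sp), c(0, n * sp))),
    lapply(0:n, function(i) cbind(c(0, n * sp), c(i * sp, i * sp))))
}

# Random small street layouts: a few chords of a box, seeded.
random_toy_lines <- function(seed, box = 100) {
  set.seed(seed)
  n <- sample(3:5, 1)
  lapply(seq_len(n), function(i) {
    # chords anchored on the box edges so most pairs intersect
    side <- sample(1:4, 2)
    pt_on <- function(s) {
      t <- runif(1, 0.1, 0.9) * box
      switch(s, cbind(t, 0), cbind(t, box), cbind(0, t), cbind(box, t))
    }
    rbind(pt_on(side[1]), pt_on(side[2]))
  })
}

# Exhaustive segment-analysis oracle ------------------------------------------
# Enumerates all simple paths on the dual (segment adjacency) graph. For each
# source j: the metric reach set (minimum over simple paths of the
# midpoint-to-midpoint cost), then all simple paths to every k inside the
# induced subgraph; minimal angular cost, co-optimal paths within 1e-9, equal
# splitting for betweenness. Ordered pairs accumulated, halved at the end.
oracle_segment_analysis <- function(network, radius = Inf, tol = 1e-6) {
  adj <- network$adjacency
  lens <- network$segments$length
  nseg <- nrow(network$segments)
  # adjacency rows as edge list (both directions), possibly with parallels
  edges <- rbind(
    data.frame(from = adj$seg_i, to = adj$seg_j, ang = adj$angle / 90),
    data.frame(from = adj$seg_j, to = adj$seg_i, ang = adj$angle / 90)
  )
  edges$met <- (lens[edges$from] + lens[edges$to]) / 2

  all_paths <- function(from, allowed) {
    # returns list of list(path=..., ang=..., met=...)
    found <- list()
    walk <- function(path, ang, met) {
      found[[length(found) + 1L]] <<- list(path = path, ang = ang, met = met)
      v <- path[length(path)]
      nxt <- which(edges$from == v & allowed[edges$to])
      for (e in nxt) {
        w <- edges$to[e]
        if (w %in% path) next
        walk(c(path, w), ang + edges$ang[e], met + edges$met[e])
      }
    }
    walk(from, 0, 0)
    found
  }

  cc_sum <- rep(NA_real_, nseg)
  reach_n <- rep(0L, nseg)
  cb <- rep(0, nseg)
  for (j in seq_len(nseg)) {
    paths_all <- all_paths(j, rep(TRUE, nseg))
    dmet <- rep(Inf, nseg)
    for (p in paths_all) {
      k <- p$path[length(p$path)]
      dmet[k] <- min(dmet[k], p$met)
    }
    reach <- which(is.finite(dmet) & dmet <= radius + tol)
    reach_n[j] <- length(reach) - 1L
    if (length(reach) <= 1L) next
    allowed <- rep(FALSE, nseg)
    allowed[reach] <- TRUE
    paths_in <- all_paths(j, allowed)
    asum <- 0
    for (k in setdiff(reach, j)) {
      pk <- Filter(function(p) p$path[length(p$path)] == k, paths_in)
      angs <- vapply(pk, function(p) p$ang, numeric(1))
      mn <- min(angs)
      asum <- asum + mn
      co <- pk[angs <= mn + tol]
      for (p in co) {
        interior <- p$path[-c(1L, length(p$path))]
        for (i in interior) cb[i] <- cb[i] + 1 / length(co)
      }
    }
    cc_sum[j] <- asum
  }
  list(reach = reach_n,
       cc = ifelse(is.na(cc_sum) | cc_sum <= 0, NA_real_, 1 / cc_sum),
       cb = cb / 2,
       ang_sum = cc_sum)
}

# Brute-force accessibility oracle: nearest network distance per feature by
# direct nl_distance over every (feature, entrance) pair, one at a time.
oracle_feature_distances <- function(location, uf, network) {
  uf <- snap_entrances(uf, network)
  out <- stats::setNames(rep(Inf, nrow(uf$features)), uf$features$id)
  for (i in seq_len(nrow(uf$snapped))) {
    r <- uf$snapped[i, ]
    if (is.na(r$seg)) next
    ent <- network_location(r$seg, r$offset, r$connector, c(r$sx, r$sy),
                            c(r$x, r$y))
    d <- nl_distance(location, ent, network)
    f <- r$feature_id
    out[f] <- min(out[f], d)
  }
  out
}
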