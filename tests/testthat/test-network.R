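# Street-network model: dissection, snapping, routing, catchments, blocks.

test_that("crossing streets are noded and dissected into equal pieces", {
  # two perpendicular 100 m streets crossing at their midpoints: four 50 m
  # arms, each dissected into ceiling(50/20) = 3 equal pieces
  nw <- build_network(list(cbind(c(0, 100), c(50, 50)),
                           cbind(c(50, 50), c(0, 100))))
  expect_equal(nrow(nw$segments), 12)
  expect_true(all(abs(nw$segments$length - 50 / 3) < 1e-9))
  deg <- table(c(nw$segments$node_u, nw$segments$node_v))
  expect_equal(max(deg), 4)  # one four-way node at the crossing
  expect_equal(sum(deg == 4), 1)
})

test_that("short streets are kept whole and total length is conserved", {
  nw <- build_network(list(cbind(c(0, 15), c(0, 0))))
  expect_equal(nrow(nw$segments), 1)
  expect_equal(nw$segments$length, 15)
  for (seed in 1:5) {
    lines <- random_toy_lines(seed)
    nw <- build_network(lines)
    expect_lte(max(nw$segments$length), 20 + 1e-9)
    expect_lt(abs(sum(nw$segments$length) - nw$total_input_length) /
                nw$total_input_length, 1e-3)
  }
  expect_error(build_network(list()), "empty")
})

test_that("snapping returns the nearest on-network point", {
  nw <- build_network(list(cbind(c(0, 100), c(0, 0))), max_segment_length = 1000)
  loc <- snap_to_network(c(50, 10), nw)
  expect_equal(loc$connector, 10)
  expect_equal(loc$offset, 50)
  on_node <- snap_to_network(c(0, 0), nw)
  expect_equal(on_node$connector, 0)
  expect_error(snap_to_network(c(50, 600), nw, tolerance = 500),
               "unsnappable")
})

test_that("metric routes include connectors; angular routes count turns", {
  nw <- build_network(toy_cross(100))
  o <- snap_to_network(c(-100, 5), nw)   # west arm end, 5 m off
  d <- snap_to_network(c(5, -50), nw)    # south arm
  r <- shortest_path(o, d, nw, "metric")
  expect_equal(r$metric_length, 100 + 50 + 5 + 5)
  expect_equal(r$angular_cost, 1)  # one 90-degree turn
  ra <- shortest_path(o, d, nw, "angular")
  expect_equal(ra$angular_cost, 1)
  expect_equal(ra$metric_length, r$metric_length)
  # straight collinear route: zero angular cost regardless of length
  straight <- shortest_path(snap_to_network(c(-90, 0), nw),
                            snap_to_network(c(90, 0), nw), nw, "angular")
  expect_equal(straight$angular_cost, 0)
  expect_equal(straight$metric_length, 180)
  # origin == dest: metric length is the connectors only
  same <- shortest_path(o, o, nw, "metric")
  expect_equal(same$metric_length, 10)
  expect_equal(same$angular_cost, 0)
})

test_that("disconnected destinations are reported unreachable", {
  nw <- build_network(list(cbind(c(0, 100), c(0, 0)),
                           cbind(c(0, 100), c(1000, 1000))))
  o <- snap_to_network(c(50, 0), nw)
  d <- snap_to_network(c(50, 1000), nw)
  r <- shortest_path(o, d, nw, "metric")
  expect_false(r$reachable)
  expect_true(is.na(r$metric_length))
})

test_that("network distance dominates straight-line distance", {
  for (seed in 1:5) {
    nw <- build_network(random_toy_lines(seed))
    set.seed(seed)
    pts <- lapply(1:6, function(i) {
      s <- sample(nrow(nw$segments), 1)
      off <- runif(1) * nw$segments$length[s]
      p <- exposurekit:::interpolate_along(nw$geoms[[s]], off)
      network_location(s, off, 0, p, p)
    })
    D <- nl_distance_matrix(pts, pts, nw)
    for (i in 1:6) {
      for (j in 1:6) {
        if (!is.finite(D[i, j])) next
        eu <- sqrt(sum((pts[[i]]$snap_point - pts[[j]]$snap_point)^2))
        expect_gte(D[i, j] + 1e-9, eu)
        # triangle inequality through any third point
        for (k in 1:6) {
          if (is.finite(D[i, k]) && is.finite(D[k, j])) {
            expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-6)
          }
        }
      }
    }
  }
})

test_that("catchments cover exactly the reachable frontier", {
  nw <- build_network(toy_cross(100))
  center <- snap_to_network(c(0, 0), nw)
  ct <- network_catchment(center, 50, nw)
  expect_equal(ct$total_length, 200)  # four arms, 50 m each
  # threshold below the local segment: reachable length = 2 x threshold
  mid <- snap_to_network(c(50, 0), nw)
  small <- network_catchment(mid, 10, nw)
  expect_equal(small$total_length, 20)
  # threshold at least the network diameter: everything reachable
  all_ct <- network_catchment(center, 1e6, nw)
  expect_equal(all_ct$total_length, sum(nw$segments$length))
  expect_error(network_catchment(center, -5, nw), "threshold")
})

test_that("catchment reachable length is monotone in threshold", {
  for (seed in 1:5) {
    nw <- build_network(random_toy_lines(seed))
    loc <- snap_to_network(c(50, 50), nw)
    lens <- vapply(c(20, 50, 100, 200, 400), function(th) {
      network_catchment(loc, th, nw)$total_length
    }, numeric(1))
    expect_true(all(diff(lens) >= -1e-9))
  }
})

test_that("catchment buffers form corridors of the right size", {
  nw <- build_network(list(cbind(c(0, 100), c(0, 0))), max_segment_length = 1000)
  loc <- snap_to_network(c(0, 0), nw)
  ct <- network_catchment(loc, 100, nw)
  zone <- catchment_buffer(ct, width = 25)
  # straight 100 m corridor: rectangle + two half-disc caps
  expect_equal(zone_area(zone, cell = 0.25), 100 * 50 + pi * 25^2,
               tolerance = 0.01)
  # containment monotonicity in width
  narrow <- catchment_buffer(ct, width = 10)
  xs <- runif(200, -30, 130); ys <- runif(200, -30, 30)
  in_wide <- zone_contains(zone, xs, ys)
  in_narrow <- zone_contains(narrow, xs, ys)
  expect_true(all(!in_narrow | in_wide))
  # degenerate catchment (connector consumes the whole threshold) -> disc
  far <- snap_to_network(c(50, 40), nw, tolerance = 500)
  tiny <- network_catchment(far, 40, nw)
  expect_equal(tiny$total_length, 0)
  disc <- catchment_buffer(tiny, width = 25)
  expect_equal(zone_area(disc, cell = 0.25), pi * 25^2, tolerance = 0.02)
  expect_error(catchment_buffer(ct, width = 0), "width")
})

test_that("polygonization extracts the enclosed urban blocks", {
  # 3x3 orthogonal grid -> 4 blocks
  b <- polygonize_blocks(build_network(toy_grid(2)))
  expect_length(b, 4)
  expect_equal(sort(vapply(b, function(x) x$area, numeric(1))),
               rep(10000, 4))
  # a single street has no enclosed area
  expect_length(polygonize_blocks(build_network(cbind(c(0, 100), c(0, 0)))), 0)
  # unit square of four streets
  sq <- list(cbind(c(0, 100), c(0, 0)), cbind(c(100, 100), c(0, 100)),
             cbind(c(100, 0), c(100, 100)), cbind(c(0, 0), c(100, 0)))
  bs <- polygonize_blocks(build_network(sq))
  expect_length(bs, 1)
  expect_equal(bs[[1]]$area, 10000)
  expect_equal(block_containing(c(50, 50), bs), 1L)
  expect_true(is.na(block_containing(c(500, 500), bs)))
})
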