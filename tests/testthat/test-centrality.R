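# Angular segment centralities against exhaustive path enumeration.

test_that("perfectly straight streets have undefined closeness", {
  # one 60 m street dissected into 3 collinear segments: every turn cost is 0
  nw <- build_network(list(cbind(c(0, 60), c(0, 0))))
  res <- segment_centrality(nw, Inf)
  expect_true(all(is.na(res$cc)))
  expect_equal(unique(res$cc_reason), "undefined-closeness")
  # the middle segment still lies on the unique end-to-end shortest path
  expect_equal(res$cb, c(0, 1, 0))
  expect_equal(angular_closeness(nw)[["1"]], NA_real_)
})

test_that("a radius below every inter-segment distance empties the reach set", {
  nw <- build_network(toy_cross(100), max_segment_length = 1000)
  res <- segment_centrality(nw, radius = 1)
  expect_true(all(res$reach == 0))
  expect_true(all(is.na(res$cc)))
  expect_equal(unique(res$cc_reason), "empty-reach")
})

test_that("T-junction closeness equals the enumeration oracle", {
  # horizontal 200 m street + vertical 100 m stem at its midpoint
  nw <- build_network(list(cbind(c(0, 200), c(0, 0)),
                           cbind(c(100, 100), c(0, 100))),
                      max_segment_length = 1000)
  o <- oracle_segment_analysis(nw, Inf)
  im <- segment_centrality(nw, Inf)
  expect_equal(im$cc, o$cc, tolerance = 1e-12)
  expect_equal(im$cb, o$cb, tolerance = 1e-12)
})

test_that("terminal segments carry no betweenness; cross arms are symmetric", {
  nw <- build_network(toy_cross(100), max_segment_length = 1000)
  res <- segment_centrality(nw, Inf)
  expect_equal(length(unique(round(res$cb, 9))), 1)  # four equivalent arms
  # segments with a single dual neighbor can never be interior to a path
  nw2 <- build_network(list(cbind(c(0, 200), c(0, 0)),
                            cbind(c(100, 100), c(0, 100))),
                       max_segment_length = 50)
  da <- exposurekit:::dual_arrays(nw2)
  ndual <- table(factor(c(da$i, da$j), levels = nw2$segments$seg))
  tips <- nw2$segments$seg[ndual == 1]
  expect_gt(length(tips), 0)
  expect_true(all(segment_centrality(nw2, Inf)$cb[tips] == 0))
})

test_that("centralities match exhaustive enumeration on random toys", {
  checked <- 0
  seed <- 0
  while (checked < 12 && seed < 60) {
    seed <- seed + 1
    nw <- try(build_network(random_toy_lines(seed), max_segment_length = 60),
              silent = TRUE)
    if (inherits(nw, "try-error") || nrow(nw$segments) > 12) next
    checked <- checked + 1
    radius <- c(80, 200, Inf)[(checked %% 3) + 1]
    o <- oracle_segment_analysis(nw, radius)
    im <- segment_centrality(nw, radius)
    expect_equal(im$reach, o$reach)
    expect_equal(is.na(im$cc), is.na(o$cc))
    both <- !is.na(im$cc)
    if (any(both)) expect_equal(im$cc[both], o$cc[both], tolerance = 1e-9)
    expect_equal(im$cb, o$cb, tolerance = 1e-9)
  }
  expect_gte(checked, 10)
})

test_that("betweenness is radius-monotone and rigid-motion invariant", {
  nw <- build_network(toy_grid(2))
  cb1 <- segment_centrality(nw, 150)$cb
  cb2 <- segment_centrality(nw, 400)$cb
  cb3 <- segment_centrality(nw, Inf)$cb
  expect_true(all(cb2 - cb1 >= -1e-9))
  expect_true(all(cb3 - cb2 >= -1e-9))
  # rotate the whole city by 30 degrees and translate
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  moved <- lapply(toy_grid(2), function(m) sweep(m %*% t(R), 2, c(-500, 900),
                                                 `+`))
  nwm <- build_network(moved)
  expect_equal(segment_centrality(nwm, 400)$cb, cb2, tolerance = 1e-6)
})

test_that("address-level aggregation matches direct recomputation", {
  nw <- build_network(toy_grid(2))
  res <- segment_centrality(nw, Inf)
  vals <- stats::setNames(res$cb, res$seg)
  loc <- snap_to_network(c(100, 100), nw)
  at_street <- centrality_at_address(loc, vals, nw, "at-street")
  expect_equal(at_street, unname(vals[as.character(loc$seg)]))
  ct <- network_catchment(loc, 300, nw)
  segs <- unique(c(loc$seg, ct$segments))
  expect_equal(centrality_at_address(loc, vals, nw, "mean-300m"),
               mean(vals[as.character(segs)]))
  expect_equal(centrality_at_address(loc, vals, nw, "max-300m"),
               max(vals[as.character(segs)]))
  expect_lte(centrality_at_address(loc, vals, nw, "mean-300m"),
             centrality_at_address(loc, vals, nw, "max-300m"))
  # a tiny catchment with one segment: all aggregations coincide
  tip <- snap_to_network(c(0, 5), nw)
  ct1 <- network_catchment(tip, 4, nw)
  expect_length(ct1$segments, 1)
  expect_equal(centrality_at_address(tip, vals, nw, "mean-300m",
                                     catchment = ct1),
               centrality_at_address(tip, vals, nw, "max-300m",
                                     catchment = ct1))
})
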