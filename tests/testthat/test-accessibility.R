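# Feature accessibility measures against hand geometry and a brute-force
# entrance-enumeration oracle.

# straight 1000 m street with an address at the western end
line_city <- function() {
  nw <- build_network(list(cbind(c(0, 1000), c(0, 0))))
  home <- snap_to_network(c(0, 0), nw)
  list(nw = nw, home = home)
}

features_at <- function(dists, class = "public park or garden",
                        fast_food = FALSE, areas = NA_real_) {
  n <- length(dists)
  urban_features(
    data.frame(id = sprintf("F%02d", seq_len(n)),
               class = rep_len(class, n),
               fast_food = rep_len(fast_food, n),
               area_m2 = rep_len(areas, n), stringsAsFactors = FALSE),
    data.frame(feature_id = sprintf("F%02d", seq_len(n)), x = dists,
               y = rep_len(0, n), stringsAsFactors = FALSE)
  )
}

test_that("nearest-feature distance is the minimum over entrances", {
  lc <- line_city()
  uf <- features_at(c(320, 150, 900))
  expect_equal(distance_to_nearest(lc$home, uf, lc$nw), 150)
  # agreement with the one-at-a-time oracle
  d_oracle <- oracle_feature_distances(lc$home, uf, lc$nw)
  expect_equal(unname(sort(d_oracle)), c(150, 320, 900))
  # an entrance at the snap point: distance equals the connector length
  home_off <- snap_to_network(c(100, 30), lc$nw)
  uf0 <- features_at(100)
  expect_equal(distance_to_nearest(home_off, uf0, lc$nw), 30)
  # beyond cutoff
  v <- distance_to_nearest(lc$home, features_at(900), lc$nw, cutoff = 500)
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "beyond-cutoff")
  v2 <- distance_to_nearest(lc$home, features_at(numeric(0)), lc$nw)
  expect_equal(attr(v2, "reason"), "no-features-of-class")
})

test_that("counts dedupe multi-entrance features and are monotone in radius", {
  lc <- line_city()
  # one greenspace with three entrances inside the radius
  uf <- urban_features(
    data.frame(id = "G1", class = "public park or garden", fast_food = FALSE,
               area_m2 = 25000),
    data.frame(feature_id = rep("G1", 3), x = c(100, 150, 200), y = 0)
  )
  expect_equal(count_within(lc$home, uf, lc$nw, 300), 1L)
  expect_equal(count_within(lc$home, uf, lc$nw, 300, "euclidean"), 1L)
  multi <- features_at(c(100, 250, 400, 800))
  c300 <- count_within(lc$home, multi, lc$nw, 300)
  c500 <- count_within(lc$home, multi, lc$nw, 500)
  expect_lte(c300, c500)
  expect_equal(count_within(lc$home, multi, lc$nw, 1e6), 4L)
  expect_error(count_within(lc$home, multi, lc$nw, 0), "radius")
})

test_that("euclidean counts dominate metric-network counts", {
  nw <- build_network(toy_grid(3))
  set.seed(5)
  uf <- features_at(runif(8, 0, 300))
  uf$entrances$y <- runif(8, 0, 300)
  home <- snap_to_network(c(0, 0), nw)
  for (r in c(100, 200, 400)) {
    expect_gte(count_within(home, uf, nw, r, "euclidean"),
               count_within(home, uf, nw, r, "metric-network"))
  }
})

test_that("decay-weighted counts and areas match closed forms", {
  lc <- line_city()
  uf <- features_at(c(100, 200))
  expect_equal(decay_weighted_count(lc$home, uf, lc$nw, 0.01),
               exp(-1) + exp(-2))
  expect_equal(round(decay_weighted_count(lc$home, uf, lc$nw, 0.01), 6),
               0.503215)
  # k = 0 with a generous cutoff reduces to the plain count
  expect_equal(decay_weighted_count(lc$home, uf, lc$nw, 0, cutoff = 1e6), 2)
  # one feature at the home itself
  uf0 <- features_at(0)
  expect_equal(decay_weighted_count(lc$home, uf0, lc$nw, 0.004), 1)
  # areas
  ufa <- features_at(c(100, 200), areas = c(10000, 5000))
  expect_equal(decay_weighted_area(lc$home, ufa, lc$nw, 0.01),
               10000 * exp(-1) + 5000 * exp(-2))
  expect_equal(round(decay_weighted_area(lc$home, ufa, lc$nw, 0.01), 2),
               4355.47)
  expect_equal(decay_weighted_area(lc$home, features_at(0, areas = 20000),
                                   lc$nw, 0.002), 20000)
  # very fast decay drives everything to zero at positive distances
  expect_lt(decay_weighted_area(lc$home, ufa, lc$nw, 1), 1e-10)
  # missing area is an error naming the feature
  bad <- features_at(c(100, 200))
  expect_error(decay_weighted_area(lc$home, bad, lc$nw, 0.01), "F0")
})

test_that("decay-weighted count never exceeds the cutoff count", {
  lc <- line_city()
  set.seed(6)
  uf <- features_at(runif(10, 0, 900))
  for (k in default_k_grid()) {
    expect_lte(decay_weighted_count(lc$home, uf, lc$nw, k, cutoff = 500),
               count_within(lc$home, uf, lc$nw, 500))
  }
})

test_that("greenspace standards apply size and distance thresholds", {
  lc <- line_city()
  # 2.5 ha park with an entrance 250 m away -> only the 2 ha / 300 m bin
  expect_equal(
    unname(greenspace_standard_counts(lc$home, features_at(250, areas = 25000),
                                      lc$nw)),
    c(1L, 0L, 0L))
  # 1.9 ha park at 100 m: below every size threshold
  expect_equal(
    unname(greenspace_standard_counts(lc$home, features_at(100, areas = 19000),
                                      lc$nw)),
    c(0L, 0L, 0L))
  # 120 ha moor at 4800 m: only the 100 ha / 5000 m bin
  big_nw <- build_network(list(cbind(c(0, 5000), c(0, 0))))
  big_home <- snap_to_network(c(0, 0), big_nw)
  expect_equal(
    unname(greenspace_standard_counts(big_home,
                                      features_at(4800, areas = 1.2e6),
                                      big_nw)),
    c(0L, 0L, 1L))
})

test_that("outlet ratios handle fast-food flags and empty denominators", {
  lc <- line_city()
  uf <- features_at(c(50, 100, 150, 200), class = "non-fast-food food outlet")
  uf$features$fast_food <- c(TRUE, TRUE, FALSE, FALSE)
  uf$features$class[1:2] <- "fast-food outlet"
  expect_equal(outlet_ratio(lc$home, uf, lc$nw, 300), 0.5)
  all_ff <- features_at(c(50, 100), class = "fast-food outlet",
                        fast_food = TRUE)
  expect_equal(outlet_ratio(lc$home, all_ff, lc$nw, 300), 1.0)
  v <- outlet_ratio(lc$home, features_at(900, fast_food = TRUE), lc$nw, 300)
  expect_true(is.na(v))
  expect_equal(attr(v, "reason"), "zero-denominator")
})

test_that("route exposure counts entrances inside the corridor", {
  lc <- line_city()
  dest <- snap_to_network(c(500, 0), lc$nw)
  uf <- urban_features(
    data.frame(id = c("A", "B", "C", "D", "E"),
               class = "non-fast-food food outlet",
               fast_food = FALSE, area_m2 = NA_real_),
    data.frame(feature_id = c("A", "B", "C", "D", "E"),
               x = c(100, 250, 400, 300, 800), y = c(5, -5, 0, 30, 0))
  )
  # three outlets within 25 m of the route; one 30 m off; one beyond the end
  expect_equal(route_exposure(lc$home, dest, uf, lc$nw, buffer_width = 25), 3L)
  # widen the corridor and the 30 m outlet joins
  expect_equal(route_exposure(lc$home, dest, uf, lc$nw, buffer_width = 35), 4L)
})

test_that("measures are invariant to feature order and city translation", {
  lc <- line_city()
  set.seed(7)
  d <- runif(6, 0, 900)
  uf <- features_at(d, areas = runif(6, 1e3, 1e5))
  perm <- sample(6)
  uf2 <- urban_features(uf$features[perm, ], uf$entrances[perm, ])
  expect_equal(decay_weighted_count(lc$home, uf, lc$nw, 0.004),
               decay_weighted_count(lc$home, uf2, lc$nw, 0.004))
  expect_equal(count_within(lc$home, uf, lc$nw, 400),
               count_within(lc$home, uf2, lc$nw, 400))
  # translate everything by (+3200, -1500)
  dx <- c(3200, -1500)
  nw_t <- build_network(list(cbind(c(0, 1000) + dx[1], c(0, 0) + dx[2])))
  home_t <- snap_to_network(c(0, 0) + dx, nw_t)
  uf_t <- uf
  uf_t$entrances$x <- uf_t$entrances$x + dx[1]
  uf_t$entrances$y <- uf_t$entrances$y + dx[2]
  expect_equal(distance_to_nearest(home_t, uf_t, nw_t),
               distance_to_nearest(lc$home, uf, lc$nw))
  expect_equal(decay_weighted_area(home_t, uf_t, nw_t, 0.002),
               decay_weighted_area(lc$home, uf, lc$nw, 0.002))
})

test_that("feature distances agree with the brute-force oracle on toy cities", {
  for (seed in 1:4) {
    nw <- build_network(random_toy_lines(seed))
    set.seed(seed + 100)
    ents <- data.frame(
      feature_id = sprintf("F%d", sample(1:5, 8, replace = TRUE)),
      x = runif(8, 0, 100), y = runif(8, 0, 100), stringsAsFactors = FALSE)
    present <- unique(ents$feature_id)
    uf <- urban_features(
      data.frame(id = present, class = "bus", fast_food = FALSE,
                 area_m2 = NA_real_, stringsAsFactors = FALSE),
      ents)
    home <- snap_to_network(c(50, 50), nw)
    fast <- feature_distances(home, uf, nw)
    slow <- oracle_feature_distances(home, uf, nw)
    expect_equal(fast[order(names(fast))], slow[order(names(slow))],
                 tolerance = 1e-9)
  }
})
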