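# Shannon land-use diversity and the walkability composite.

test_that("Shannon diversity matches closed forms", {
  expect_equal(shannon_diversity(1), 0)
  expect_equal(shannon_diversity(c(0.5, 0.5)), log(2))
  expect_equal(round(shannon_diversity(c(0.5, 0.5)), 6), 0.693147)
  expect_equal(shannon_diversity(rep(0.25, 4)), log(4))
  expect_equal(round(shannon_diversity(rep(0.25, 4)), 6), 1.386294)
  # equal proportions maximize H for fixed s
  set.seed(8)
  for (i in 1:10) {
    p <- runif(4); p <- p / sum(p)
    expect_lte(shannon_diversity(p), log(4) + 1e-12)
  }
  expect_error(shannon_diversity(c(0.5, 0.4)), "sum to 1")
  expect_equal(shannon_diversity(c(3, 3), normalize = TRUE), log(2))
})

test_that("equitability is H normalized by ln(s), in [0, 1]", {
  expect_equal(shannon_equitability(c(0.5, 0.5)), 1)
  expect_equal(shannon_equitability(1), 0)
  set.seed(9)
  for (i in 1:10) {
    p <- runif(sample(2:6, 1)); p <- p / sum(p)
    e <- shannon_equitability(p)
    expect_gte(e, 0)
    expect_lte(e, 1)
  }
})

mini_features <- function(df) {
  urban_features(
    data.frame(id = sprintf("F%d", seq_len(nrow(df))), class = df$class,
               fast_food = FALSE, area_m2 = NA_real_),
    data.frame(feature_id = sprintf("F%d", seq_len(nrow(df))), x = df$x,
               y = df$y)
  )
}

test_that("land-use intensity surface rasterizes the class mix", {
  ext <- c(0, 0, 100, 100)
  single <- mini_features(data.frame(class = "shop", x = c(20, 60, 80),
                                     y = c(20, 60, 80)))
  s1 <- landuse_intensity_surface(single, ext, cell = 25, neighborhood = 200)
  expect_true(all(s1$values == 0))
  # two classes in equal counts around every cell
  two <- mini_features(data.frame(class = c("shop", "cafe"), x = c(40, 60),
                                  y = c(50, 50)))
  s2 <- landuse_intensity_surface(two, ext, cell = 50, neighborhood = 500)
  expect_true(all(abs(s2$values - log(2)) < 1e-12))
  eq <- landuse_intensity_surface(two, ext, cell = 50, neighborhood = 500,
                                  equitability = TRUE)
  expect_true(all(eq$values >= 0 & eq$values <= 1))
  # relabeling feature ids changes nothing
  two_relab <- two
  two_relab$features$id <- c("Z9", "Z1")
  two_relab$entrances$feature_id <- c("Z9", "Z1")
  s3 <- landuse_intensity_surface(two_relab, ext, cell = 50,
                                  neighborhood = 500)
  expect_equal(s3$values, s2$values)
})

test_that("walkability composite standardizes and weights components", {
  set.seed(10)
  mk <- function(v) raster_surface(matrix(v, 10, 10), 0, 0, 25)
  a <- mk(rnorm(100)); b <- mk(runif(100, 5, 9)); c2 <- mk(rnorm(100, 3, 2))
  d <- mk(rexp(100))
  w <- walkability_surface(list(a = a, b = b, c = c2, d = d))
  expect_s3_class(w$surface, "raster_surface")
  # each z-scored component has mean ~0, sd ~1; the equal-weight composite
  # therefore has mean ~0
  expect_equal(mean(w$surface$values), 0, tolerance = 1e-9)
  # uniform components are dropped with a warning
  expect_warning(w2 <- walkability_surface(list(a = a, flat = mk(7))),
                 "zero-variance")
  expect_equal(w2$surface$values,
               walkability_surface(list(a = a))$surface$values)
  # doubling a component's weight pulls the ranking toward that component
  w_eq <- walkability_surface(list(a = a, b = b), weights = c(1, 1))
  w_bb <- walkability_surface(list(a = a, b = b), weights = c(1, 10))
  r_b <- cor(as.vector(w_bb$surface$values), as.vector(b$values),
             method = "spearman")
  r_eq <- cor(as.vector(w_eq$surface$values), as.vector(b$values),
              method = "spearman")
  expect_gt(r_b, r_eq)
  off_grid <- raster_surface(matrix(1, 10, 10), 0, 0, 30)
  expect_error(walkability_surface(list(a = a, bad = off_grid)),
               "co-registered")
})
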