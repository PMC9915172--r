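# Building metrics, Spacematrix block density, dwelling-record passthrough.

test_that("building metrics follow the volume and floor-area arithmetic", {
  fp <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10))
  m <- building_metrics(fp, height = 6, floors = 2)
  expect_equal(unname(m), c(100, 6, 600, 200))
  one <- building_metrics(fp, height = 3, floors = 1)
  expect_equal(one[["floor_area"]], one[["footprint"]])
  tall <- building_metrics(fp, height = 12, floors = 2)
  expect_equal(tall[["volume"]], 2 * m[["volume"]])
  expect_equal(tall[["floor_area"]], m[["floor_area"]])
  expect_error(building_metrics(cbind(c(0, 10), c(0, 0)), 6, 2), "degenerate")
  expect_error(building_metrics(fp, -1, 2), "height")
  expect_error(building_metrics(fp, 6, 0), "floor")
})

unit_block <- function(side = 100) {
  ring <- cbind(c(0, side, side, 0), c(0, 0, side, side))
  list(id = 1L, ring = ring, area = side^2)
}

test_that("Spacematrix indices match hand arithmetic", {
  blk <- unit_block(100)  # 10,000 m2
  b <- data.frame(id = "B1", height_m = 12, floors = 4)
  b$footprint <- list(cbind(c(10, 60, 60, 10), c(10, 10, 60, 60)))  # 2500 m2
  d <- block_density(blk, b)
  expect_equal(unname(d), c(1.0, 0.25, 0.75, 4))
  # empty block
  e <- block_density(blk, b[0, , drop = FALSE])
  expect_equal(unname(e[c("fsi", "gsi")]), c(0, 0))
  expect_true(all(is.na(e[c("osr", "l")])))
})

test_that("the identity OSR * L = (1 - GSI) / GSI holds on random blocks", {
  set.seed(11)
  for (i in 1:10) {
    blk <- unit_block(runif(1, 50, 200))
    nb <- sample(1:4, 1)
    side <- sqrt(blk$area) * runif(nb, 0.1, 0.35)
    x0 <- runif(nb, 0, sqrt(blk$area) - side)
    y0 <- runif(nb, 0, sqrt(blk$area) - side)
    b <- data.frame(id = paste0("B", 1:nb), height_m = runif(nb, 3, 30),
                    floors = sample(1:8, nb, replace = TRUE))
    b$footprint <- lapply(1:nb, function(j) {
      cbind(x0[j] + c(0, side[j], side[j], 0), y0[j] + c(0, 0, side[j], side[j]))
    })
    d <- block_density(blk, b)
    expect_equal(d[["osr"]] * d[["l"]], (1 - d[["gsi"]]) / d[["gsi"]],
                 tolerance = 1e-9)
    expect_gte(d[["gsi"]], 0); expect_lte(d[["gsi"]], 1)
    expect_gte(d[["fsi"]], d[["gsi"]])  # floors >= 1
    # invariance under building order
    sh <- sample(nb)
    d2 <- block_density(blk, b[sh, , drop = FALSE])
    expect_equal(d, d2)
  }
})

test_that("straddling buildings are clipped and floor area pro-rated", {
  blk <- unit_block(100)
  b <- data.frame(id = "B1", height_m = 6, floors = 2)
  # 20 x 20 footprint, half inside the block
  b$footprint <- list(cbind(c(90, 110, 110, 90), c(0, 0, 20, 20)))
  d <- block_density(blk, b)
  expect_equal(d[["gsi"]], 200 / 10000)
  expect_equal(d[["fsi"]], 2 * 200 / 10000)
})

test_that("dwelling passthrough validates vocabularies and numerics", {
  rec <- data.frame(
    uprn = c(1L, 2L, 3L),
    built_form = c("mid-terrace", "semidetached", "castle"),
    dwelling_type = c("house", "flat", "house"),
    tenure = c("owner-occupied", "private rental", "rental (social)"),
    construction_age_band = c("1930-1949", "before 1900", "1976-1995"),
    storeys = c(2, 3, 2),
    floor_area = c(78, -5, 120),
    stringsAsFactors = FALSE
  )
  long <- dwelling_passthrough(rec)
  bf <- long[long$field == "built_form", ]
  expect_equal(bf$value[bf$uprn == 2], "semi-detached")  # alias normalized
  expect_equal(bf$reason[bf$uprn == 3], "invalid-category")
  expect_true(is.na(bf$reason[bf$uprn == 1]))
  ten <- long[long$field == "tenure", ]
  expect_equal(ten$value[ten$uprn == 2], "rental (private)")
  fa <- long[long$field == "floor_area", ]
  expect_equal(fa$reason[fa$uprn == 2], "negative-value")
  expect_true(is.na(fa$numeric[fa$uprn == 2]))
  expect_equal(fa$numeric[fa$uprn == 1], 78)
  # every (uprn, field) appears exactly once
  expect_false(any(duplicated(long[, c("uprn", "field")])))
  expect_warning(dwelling_passthrough(rec, known_uprns = c(1L, 2L)), "orphan")
})
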