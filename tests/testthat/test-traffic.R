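# Congestion ratio and period-stratified traffic aggregation.

test_that("congestion ratio follows its piecewise closed form", {
  expect_equal(congestion_ratio(50, 50), 1)
  expect_equal(congestion_ratio(60, 50), 1)
  expect_equal(congestion_ratio(25, 50), 0.5)
  expect_equal(congestion_ratio(0, 50), 0)
  # grid of speed pairs: capped at free flow, proportional below
  grid <- expand.grid(x = seq(0, 120, by = 7.5), a = seq(10, 100, by = 12.5))
  C <- congestion_ratio(grid$x, grid$a)
  expect_true(all(C >= 0 & C <= 1))
  expect_equal(C, ifelse(grid$x >= grid$a, 1, grid$x / grid$a))
  # monotone in x for fixed a
  expect_true(all(diff(congestion_ratio(seq(0, 80, 5), 60)) >= 0))
  expect_error(congestion_ratio(10, 0), "positive")
  expect_error(congestion_ratio(-1, 50), "non-negative")
})

test_that("sub-period records average to street-period records", {
  raw <- data.frame(street_id = c("S1", "S1", "S2"),
                    period = c("am", "am", "pm"),
                    count = c(100, 200, 50),
                    avg_speed = c(20, 40, 30),
                    freeflow_speed = c(50, 50, 45))
  agg <- aggregate_traffic_periods(raw)
  expect_equal(nrow(agg), 2)
  s1 <- agg[agg$street_id == "S1", ]
  expect_equal(s1$count, 150)
  expect_equal(s1$avg_speed, 30)
  expect_error(aggregate_traffic_periods(transform(raw, period = "lunch")),
               "period")
})

toy_traffic_city <- function() {
  nw <- build_network(list(cbind(c(0, 1000), c(0, 0)),
                           cbind(c(200, 200), c(0, 1000))),
                      street_ids = c("S1", "S2"))
  home <- snap_to_network(c(210, 0), nw)  # on street S1 near the junction
  list(nw = nw, home = home)
}

test_that("traffic indicators aggregate the street and the 300 m catchment", {
  tc <- toy_traffic_city()
  rec <- expand.grid(street_id = c("S1", "S2"),
                     period = c("am", "op", "pm"), stringsAsFactors = FALSE)
  rec$count <- ifelse(rec$street_id == "S1", 100, 300)
  rec$avg_speed <- 25
  rec$freeflow_speed <- 50
  ti <- traffic_indicators(tc$home, rec, tc$nw)
  expect_equal(nrow(ti), 18)  # 3 periods x (2 street + 4 catchment rows)
  street_am <- ti[ti$period == "am" & ti$relationship == "street", ]
  expect_equal(street_am$value[street_am$measure == "count"], 100)
  expect_equal(street_am$value[street_am$measure == "congestion"], 0.5)
  catch_am <- ti[ti$period == "am" & ti$relationship == "catchment", ]
  expect_equal(catch_am$value[catch_am$measure == "count" &
                                catch_am$stat == "avg"], 200)
  expect_equal(catch_am$value[catch_am$measure == "count" &
                                catch_am$stat == "max"], 300)
  # congestion everywhere within [0, 1]; mean <= max
  expect_true(all(ti$value[ti$measure == "congestion" & !is.na(ti$value)] <= 1))
  avg <- ti$value[ti$stat == "avg"]
  mx <- ti$value[ti$stat == "max"]
  expect_true(all(avg <= mx + 1e-12, na.rm = TRUE))
})

test_that("a catchment with a single recorded street collapses avg and max", {
  tc <- toy_traffic_city()
  rec <- data.frame(street_id = "S1", period = c("am", "op", "pm"),
                    count = 120, avg_speed = 50, freeflow_speed = 40)
  ti <- traffic_indicators(tc$home, rec, tc$nw)
  catch <- ti[ti$relationship == "catchment" & ti$period == "am", ]
  expect_equal(catch$value[catch$measure == "count" & catch$stat == "avg"],
               catch$value[catch$measure == "count" & catch$stat == "max"])
  # x > a caps congestion at 1
  expect_equal(unique(catch$value[catch$measure == "congestion"]), 1)
})

test_that("missing records yield reasons, not silent gaps", {
  tc <- toy_traffic_city()
  rec <- data.frame(street_id = "S2", period = "am", count = 10,
                    avg_speed = 10, freeflow_speed = 50)
  ti <- traffic_indicators(tc$home, rec, tc$nw)
  own <- ti[ti$relationship == "street" & ti$period == "am", ]
  expect_true(all(is.na(own$value)))
  expect_equal(unique(own$reason), "no-records-for-street")
  pm <- ti[ti$period == "pm" & ti$relationship == "catchment", ]
  expect_equal(unique(pm$reason), "no-records-in-catchment")
})
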