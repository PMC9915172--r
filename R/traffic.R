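# Road-traffic indicators: the congestion ratio and period-stratified
# aggregation at the address street and over a 300 m network catchment.
#
# Traffic records are keyed to streets (pre-dissection centerlines) for three
# weekday periods: AM peak 07:00-09:00 ("am"), off-peak 10:00-16:00 ("op") and
# PM peak 16:00-19:00 ("pm"). Records carry a bidirectional vehicle count, an
# average speed and a free-flow speed (km/h), assumed already aggregated to
# the period level upstream.

TRAFFIC_PERIODS <- c("am", "op", "pm")

#' Congestion ratio
#'
#' C = 1 when the average speed reaches or exceeds the free-flow speed, and
#' x / a otherwise, so C is always in the unit interval: 1 is free-flowing
#' traffic, 0 a standstill.
#'
#' @param x Average observed speed (km/h), `>= 0`; vectorized.
#' @param a Free-flow speed (km/h), `> 0`; vectorized.
#' @return Congestion index in the unit interval.
#' @export
congestion_ratio <- function(x, a) {
  if (any(a <= 0)) stop("free-flow speed must be positive", call. = FALSE)
  if (any(x < 0)) stop("average speed must be non-negative", call. = FALSE)
  ifelse(x >= a, 1, x / a)
}

#' Average raw traffic records to per-street period records
#'
#' Helper for inputs finer than the three analysis periods: averages speeds
#' and counts over all records sharing a street and period.
#'
#' @param records Data frame with `street_id`, `period`, `count`,
#'   `avg_speed`, `freeflow_speed`.
#' @export
aggregate_traffic_periods <- function(records) {
  check_traffic(records)
  agg <- stats::aggregate(
    records[, c("count", "avg_speed", "freeflow_speed")],
    by = list(street_id = records$street_id, period = records$period),
    FUN = mean
  )
  agg[order(agg$street_id, agg$period), , drop = FALSE]
}

check_traffic <- function(records) {
  req <- c("street_id", "period", "count", "avg_speed", "freeflow_speed")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("traffic records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(records$period %in% TRAFFIC_PERIODS)) {
    stop("traffic periods must be one of: ",
         paste(TRAFFIC_PERIODS, collapse = ", "), call. = FALSE)
  }
  if (any(records$count < 0) || any(records$avg_speed < 0) ||
      any(records$freeflow_speed <= 0)) {
    stop("invalid traffic record values", call. = FALSE)
  }
  invisible(records)
}

#' Traffic indicators at an address
#'
#' For each weekday period: the vehicle count and congestion at the address's
#' own street (spatial relationship: the residential street), and the mean and
#' maximum over streets with records inside the 300 m metric catchment
#' (relationship: features within a catchment). Streets without records are
#' excluded from the aggregation; an empty catchment yields missing values
#' with reasons.
#'
#' @param location Snapped address (`network_location`).
#' @param records Street-period traffic records (see
#'   [aggregate_traffic_periods()] for the schema).
#' @param network A `street_network` built with `street_ids` matching
#'   `records$street_id`.
#' @param catchment_radius Catchment threshold in meters (default 300).
#' @param catchment Optional precomputed catchment.
#' @return Long data frame: `period`, `relationship` (`street`/`catchment`),
#'   `measure`, `stat`, `value`, `reason`.
#' @export
traffic_indicators <- function(location, records, network,
                               catchment_radius = 300, catchment = NULL) {
  check_traffic(records)
  segs <- network$segments
  own_street <- segs$street[location$seg]
  if (is.null(catchment)) {
    catchment <- network_catchment(location, catchment_radius, network)
  }
  catch_streets <- unique(segs$street[catchment$segments])
  period <- c(); rel <- c(); measure <- c(); stat <- c()
  value <- c(); reason <- c()
  add <- function(p, r, m, s, v, rs = NA_character_) {
    period <<- c(period, p); rel <<- c(rel, r); measure <<- c(measure, m)
    stat <<- c(stat, s); value <<- c(value, v); reason <<- c(reason, rs)
  }
  for (p in TRAFFIC_PERIODS) {
    rp <- records[records$period == p, , drop = FALSE]
    cong <- congestion_ratio(rp$avg_speed, rp$freeflow_speed)
    own <- which(rp$street_id == own_street)
    if (length(own) > 0L) {
      add(p, "street", "count", "value", mean(rp$count[own]))
      add(p, "street", "congestion", "value", mean(cong[own]))
    } else {
      add(p, "street", "count", "value", NA_real_, "no-records-for-street")
      add(p, "street", "congestion", "value", NA_real_, "no-records-for-street")
    }
    inc <- which(rp$street_id %in% catch_streets)
    if (length(inc) > 0L) {
      add(p, "catchment", "count", "avg", mean(rp$count[inc]))
      add(p, "catchment", "count", "max", max(rp$count[inc]))
      add(p, "catchment", "congestion", "avg", mean(cong[inc]))
      add(p, "catchment", "congestion", "max", max(cong[inc]))
    } else {
      for (mm in c("count", "congestion")) {
        for (st in c("avg", "max")) {
          add(p, "catchment", mm, st, NA_real_, "no-records-in-catchment")
        }
      }
    }
  }
  data.frame(period = period, relationship = rel, measure = measure,
             stat = stat, value = value, reason = reason,
             stringsAsFactors = FALSE)
}
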