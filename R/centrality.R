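# Space-syntax angular segment centralities.
#
# Closeness ("integration"): CC(i) = 1 / sum_k d_ik, where d_ik is the least
# cumulative angular cost from segment i to every other segment k within a
# metric network radius. Betweenness ("choice"): CB(i) = sum over unordered
# pairs {j,k} (i not an endpoint) of the fraction of least-angular-cost paths
# between j and k that pass through i, with equal splitting across co-optimal
# paths (cost ties within 1e-9).
#
# Radius semantics are hybrid: the reach set of a source segment is limited by
# METRIC network distance (midpoint-to-midpoint step cost (len_i + len_j)/2)
# while path costs are ANGULAR, the convention of segment-analysis software.
# Paths for the pair (j, k) are computed on the subgraph induced by j's reach
# set; the unordered sum is the ordered sum halved.

#' Angular closeness and betweenness centrality per segment
#'
#' @param network A `street_network`.
#' @param radius Metric catchment radius in meters (`Inf` for global).
#' @return Data frame: `seg`, `radius`, `reach` (number of other segments in
#'   the metric radius), `cc` (closeness; `NA` when the reach set is empty or
#'   all angular distances are zero, i.e. a perfectly straight neighborhood),
#'   `cb` (betweenness), and `cc_reason` documenting why `cc` is missing.
#' @export
segment_centrality <- function(network, radius = Inf) {
  da <- dual_arrays(network)
  nseg <- nrow(network$segments)
  if (length(da$i) == 0L) {
    return(data.frame(seg = network$segments$seg, radius = radius,
                      reach = 0, cc = NA_real_, cb = 0,
                      cc_reason = "empty-reach"))
  }
  res <- segment_analysis_cpp(nseg, as.integer(da$i), as.integer(da$j),
                              da$ang, da$met, radius)
  cc <- ifelse(is.na(res$ang_sum) | res$ang_sum <= 0, NA_real_,
               1 / res$ang_sum)
  reason <- rep(NA_character_, nseg)
  reason[is.na(res$ang_sum)] <- "empty-reach"
  reason[!is.na(res$ang_sum) & res$ang_sum <= 0] <- "undefined-closeness"
  data.frame(seg = network$segments$seg, radius = radius,
             reach = res$reach, cc = cc, cb = res$betweenness,
             cc_reason = reason)
}

#' Angular closeness centrality
#' @inheritParams segment_centrality
#' @return Named numeric vector of CC per segment (`NA` where undefined).
#' @export
angular_closeness <- function(network, radius = Inf) {
  r <- segment_centrality(network, radius)
  stats::setNames(r$cc, r$seg)
}

#' Angular betweenness centrality
#' @inheritParams segment_centrality
#' @return Named numeric vector of CB per segment.
#' @export
angular_betweenness <- function(network, radius = Inf) {
  r <- segment_centrality(network, radius)
  stats::setNames(r$cb, r$seg)
}

#' Aggregate a segment centrality at an address
#'
#' Either the value at the address's own (snapped) street segment, or the mean
#' or maximum over all segments intersecting the 300 m metric catchment of the
#' address.
#'
#' @param location A `network_location` (snapped address).
#' @param values Named numeric vector of per-segment centrality values
#'   (names are segment ids), e.g. from [angular_closeness()].
#' @param network A `street_network`.
#' @param aggregation One of `"at-street"`, `"mean-300m"`, `"max-300m"`.
#' @param catchment Optional precomputed 300 m catchment (speed-up).
#' @return Numeric value (`NA` if undefined for every involved segment).
#' @export
centrality_at_address <- function(location, values, network,
                                  aggregation = c("at-street", "mean-300m",
                                                  "max-300m"),
                                  catchment = NULL) {
  aggregation <- match.arg(aggregation)
  if (aggregation == "at-street") {
    return(unname(values[as.character(location$seg)]))
  }
  if (is.null(catchment)) {
    catchment <- network_catchment(location, 300, network)
  }
  segs <- unique(c(location$seg, catchment$segments))
  v <- values[as.character(segs)]
  v <- v[!is.na(v)]
  if (length(v) == 0L) return(NA_real_)
  if (aggregation == "mean-300m") mean(v) else max(v)
}
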