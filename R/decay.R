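# Exponential distance decay: the fourth distance type. A feature d meters
# away (through the network) contributes weight e^(-k d), modelling the
# declining likelihood of interaction with distance.

#' Decay parameters
#'
#' @param k Decay parameter in 1/m; must be finite and non-negative. Larger k
#'   means faster decay (k = 0.002 halves the weight roughly every 350 m).
#' @return A `decay_params` object.
#' @export
decay_params <- function(k) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k < 0) {
    stop("decay parameter k must be a single finite non-negative number",
         call. = FALSE)
  }
  structure(list(k = k), class = "decay_params")
}

#' Default decay parameter grid
#'
#' Four decay rates spanning roughly 300 m to 2000 m walking scales, intended
#' to represent user groups with different mobility (children, families with
#' prams, the elderly). Configurable everywhere a `k` is accepted; the k value
#' is recorded in every output indicator.
#' @export
default_k_grid <- function() c(0.001, 0.002, 0.004, 0.008)

#' Exponential distance decay weight
#'
#' @param d Network distance(s) in meters, `>= 0`.
#' @param params A `decay_params` object, or a bare numeric k.
#' @return Weight(s) `exp(-k * d)` in (0, 1].
#' @export
decay <- function(d, params) {
  k <- if (inherits(params, "decay_params")) params$k else decay_params(params)$k
  if (any(d < 0, na.rm = TRUE)) {
    stop("distances must be non-negative", call. = FALSE)
  }
  exp(-k * d)
}
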