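# Bounded-rational self-learning: strategy probability adjustment and the
# random investment choice it drives.

# Table of update rows: each row moves (p_d, p_i, p_c) by multiples of epsilon
# and sums to zero, so the probability simplex is preserved before clipping.
.adjustment_rows <- list(
  increase.increase  = c(-0.5,  1.0, -0.5),
  increase.decrease  = c( 0.5, -1.0,  0.5),
  decrease.increase  = c( 1.0, -0.5, -0.5),
  decrease.decrease  = c(-1.0,  0.5,  0.5),
  unchanged.increase = c(-0.5, -0.5,  1.0),
  unchanged.decrease = c( 0.5,  0.5, -1.0)
)

#' Strategy probability vector
#'
#' Constructs the probability vector `(p_d, p_i, p_c)` of decreasing,
#' increasing, or keeping the safety investment next period.
#'
#' @param p_d,p_i,p_c Component probabilities; must sum to 1.
#' @return A named numeric vector of class `sse_strategy`.
#' @examples
#' strategy_probs()  # uniform start
#' @export
strategy_probs <- function(p_d = 1 / 3, p_i = 1 / 3, p_c = 1 / 3) {
  p <- c(p_d = p_d, p_i = p_i, p_c = p_c)
  if (any(p < 0 | p > 1) || abs(sum(p) - 1) > 1e-9) {
    rlang::abort("strategy probabilities must be in [0,1] and sum to 1",
                 class = "sse_domain_error")
  }
  structure(p, class = "sse_strategy")
}

#' Adjust strategy probabilities from last period's outcome
#'
#' Applies the self-learning update: the direction of last period's investment
#' change (`invest_change`) and profit change (`profit_change`) select one of
#' six rows, each shifting the components by `epsilon`-scaled amounts that sum
#' to zero. A change paired with a profit increase is reinforced (its
#' probability gains `epsilon`, the others lose `epsilon/2` each); paired with
#' a profit decrease or no change it is suppressed symmetrically. After the raw
#' update, components are clipped to `[p_floor, 1 - p_floor]` and renormalised
#' so no strategy is ever extinguished.
#'
#' @param p An `sse_strategy` (or named vector `p_d`, `p_i`, `p_c`).
#' @param invest_change One of `"increase"`, `"decrease"`, `"unchanged"`.
#' @param profit_change One of `"increase"`, `"decrease"` (the latter covers
#'   "decrease or no change").
#' @param epsilon Adjustment step.
#' @param p_floor Minimum retained probability per strategy.
#' @return An updated `sse_strategy`.
#' @examples
#' adjust_probabilities(strategy_probs(0.3, 0.4, 0.3), "increase", "increase",
#'                      epsilon = 0.1)
#' @export
adjust_probabilities <- function(p, invest_change, profit_change,
                                 epsilon = 0.05, p_floor = 0.01) {
  invest_change <- match.arg(invest_change,
                             c("increase", "decrease", "unchanged"))
  profit_change <- match.arg(profit_change, c("increase", "decrease"))
  row <- .adjustment_rows[[paste(invest_change, profit_change, sep = ".")]]
  raw <- unclass(p) + epsilon * row
  clipped <- pmin(pmax(raw, p_floor), 1 - p_floor)
  out <- clipped / sum(clipped)
  strategy_probs(out[[1]], out[[2]], out[[3]])
}

#' Per-class investment step sizes
#'
#' Returns the increment and decrement magnitudes for an SSE of class `c`.
#' Steps are proportional to the current investment (with an absolute floor):
#' high and medium classes (1-2) use a larger decrement fraction and smaller
#' increment fraction than the low classes (3-4), reflecting that well-invested
#' firms cut in larger and add in smaller relative moves.
#'
#' @param c Class in 1..4.
#' @param K Current safety investment.
#' @param cfg An `sse_config`.
#' @return A list with components `delta_inc` and `delta_dec` (both > 0).
#' @examples
#' deltas_for_class(1, K = 100)
#' deltas_for_class(4, K = 100)
#' @export
deltas_for_class <- function(c, K, cfg = default_config()) {
  if (!all(c %in% 1:4)) {
    rlang::abort("class must be in 1..4", class = "sse_domain_error")
  }
  high <- c %in% c(1, 2)
  inc_frac <- ifelse(high, cfg$delta_inc_frac_high, cfg$delta_inc_frac_low)
  dec_frac <- ifelse(high, cfg$delta_dec_frac_high, cfg$delta_dec_frac_low)
  list(
    delta_inc = pmax(cfg$delta_floor, inc_frac * K),
    delta_dec = pmax(cfg$delta_floor, dec_frac * K)
  )
}

#' Randomised investment choice
#'
#' Implements the strategy draw: a uniform number selects decrease
#' (`draw < p_d`), increase (`p_d <= draw < p_d + p_i`), or keep. The decrease
#' branch subtracts `delta_dec` (floored at `k_min`), the increase branch adds
#' `delta_inc`.
#'
#' @param K_prev Previous investment, non-negative.
#' @param p An `sse_strategy`.
#' @param draw Uniform(0,1) variate.
#' @param delta_inc,delta_dec Step magnitudes.
#' @param k_min Lower floor for the investment after a decrease.
#' @return New investment K.
#' @examples
#' choose_investment(10, strategy_probs(0.3, 0.5, 0.2), draw = 0.5,
#'                   delta_inc = 2, delta_dec = 1)  # 12
#' @export
choose_investment <- function(K_prev, p, draw, delta_inc, delta_dec,
                              k_min = 0) {
  if (K_prev < 0) {
    rlang::abort("investment must be non-negative", class = "sse_domain_error")
  }
  if (draw < 0 || draw >= 1) {
    rlang::abort("draw must lie in [0, 1)", class = "sse_domain_error")
  }
  pd <- unclass(p)[[1]]
  pi_ <- unclass(p)[[2]]
  if (draw < pd) {
    max(k_min, K_prev - delta_dec)
  } else if (draw < pd + pi_) {
    K_prev + delta_inc
  } else {
    K_prev
  }
}
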