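#' Safety level from safety investment
#'
#' Saturating response of the true safety level to the per-period safety
#' investment: `s = beta*K / (1 + beta*K)`. Strictly increasing in K,
#' approaching but never reaching 1.
#'
#' @param K Safety investment(s), currency, non-negative.
#' @param beta Control coefficient (> 0), per currency unit.
#' @return Safety level(s) in \[0, 1).
#' @examples
#' safety_level(1 / 0.33)  # 0.5
#' @export
safety_level <- function(K, beta = 0.33) {
  if (any(K < 0)) {
    rlang::abort("safety investment must be non-negative",
                 class = "sse_domain_error")
  }
  if (beta <= 0) {
    rlang::abort("beta must be positive", class = "sse_domain_error")
  }
  beta * K / (1 + beta * K)
}

#' Inverse of the safety-level response
#'
#' Investment required to sustain a given safety level: `K = s / (beta*(1-s))`.
#' Used to initialise the population census at target safety levels.
#'
#' @param s Safety level(s) in \[0, 1).
#' @param beta Control coefficient (> 0).
#' @return Investment(s) K.
#' @export
investment_for_level <- function(s, beta = 0.33) {
  if (any(s < 0 | s >= 1)) {
    rlang::abort("safety level must lie in [0, 1)", class = "sse_domain_error")
  }
  s / (beta * (1 - s))
}

#' Gross production value
#'
#' Per-period production value: product price x months x mean employee
#' efficiency x headcount x demand fraction x productivity scale (output units
#' per employee per month at unit efficiency).
#'
#' @param FP Product price, currency per unit.
#' @param T_months Period length in months.
#' @param mean_SV Mean safety production efficiency of the workforce.
#' @param EN Employee count.
#' @param PS Demand fraction in \[0, 1\].
#' @param productivity_scale Calibration factor, output units per employee.
#' @return Production value, currency per period.
#' @examples
#' gross_production(300, 3, 0.688, 40, 1, productivity_scale = 1)  # 24768
#' @export
gross_production <- function(FP, T_months, mean_SV, EN, PS,
                             productivity_scale = 1) {
  args <- c(FP, T_months, mean_SV, EN, PS, productivity_scale)
  if (any(args < 0)) {
    rlang::abort("production inputs must be non-negative",
                 class = "sse_domain_error")
  }
  if (any(PS > 1)) {
    rlang::abort("demand fraction PS must lie in [0, 1]",
                 class = "sse_domain_error")
  }
  FP * T_months * mean_SV * EN * PS * productivity_scale
}

#' Labor and total cost
#'
#' Labor cost is the monthly wage bill over the period: `LC = WE * EN *
#' T_months` (with per-employee wages, pass their sum via `wage_bill_month`).
#' Total cost adds the safety investment and fixed production cost:
#' `C = LC + K + PC`.
#'
#' @param WE Monthly wage per person (ignored when `wage_bill_month` given).
#' @param EN Employee count.
#' @param T_months Period length in months.
#' @param K Safety investment this period.
#' @param PC Fixed production cost per period.
#' @param wage_bill_month Optional total monthly wage bill overriding `WE * EN`
#'   (used when individual wages differ after raises).
#' @return A list with components `LC` and `C`.
#' @examples
#' total_cost(3000, 40, 3, K = 0, PC = 0)  # LC = C = 360000
#' @export
total_cost <- function(WE, EN, T_months, K, PC, wage_bill_month = NULL) {
  if (any(c(WE, EN, T_months, K, PC) < 0)) {
    rlang::abort("cost inputs must be non-negative", class = "sse_domain_error")
  }
  bill <- if (is.null(wage_bill_month)) WE * EN else wage_bill_month
  LC <- bill * T_months
  list(LC = LC, C = LC + K + PC)
}

#' Per-period profit
#'
#' `F = (1 - tax_rate) * production_value - C + transfer`, where `transfer` is
#' the signed reward-penalty amount (0 when no evaluation occurred).
#'
#' @param tax_rate Tax rate in \[0, 1\].
#' @param production_value Gross production value, currency.
#' @param C Total cost, currency.
#' @param transfer Signed government transfer, currency.
#' @return Profit, currency per period.
#' @examples
#' profit(0.05, 100000, 80000, 50000)  # 65000
#' @export
profit <- function(tax_rate, production_value, C, transfer = 0) {
  if (any(tax_rate < 0 | tax_rate > 1)) {
    rlang::abort("tax rate must lie in [0, 1]", class = "sse_domain_error")
  }
  (1 - tax_rate) * production_value - C + transfer
}

#' Four-class safety taxonomy
#'
#' Classifies the safety level into the four regulatory tiers using boundary
#' fractions of `s_max + s_min`: class 1 (high) at or above 0.8 of the scale,
#' class 2 (medium) on \[0.7, 0.8), class 3 (meets standard) on \[0.6, 0.7),
#' class 4 (below standard) underneath. At the defaults the boundaries are
#' 0.8 / 0.7 / 0.6, coinciding with the government thresholds T2 / T1 / T0.
#'
#' @param s Safety level(s) in `(s_min, s_max]`.
#' @param cfg An `sse_config` supplying the scale and boundary fractions.
#' @return Integer class(es) in 1..4 (1 = highest safety).
#' @examples
#' classify(c(0.85, 0.75, 0.65, 0.3))
#' @export
classify <- function(s, cfg = default_config()) {
  scale <- cfg$s_max + cfg$s_min
  if (any(s <= cfg$s_min | s > cfg$s_max)) {
    rlang::abort("safety level must lie in (s_min, s_max]",
                 class = "sse_domain_error")
  }
  b1 <- cfg$class_frac_c1 * scale
  b2 <- cfg$class_frac_c2 * scale
  b3 <- cfg$class_frac_c3 * scale
  ifelse(s >= b1, 1L, ifelse(s >= b2, 2L, ifelse(s >= b3, 3L, 4L)))
}
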