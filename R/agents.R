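#' Employee-perceived OSH level
#'
#' Employees read the true safety level of production through a cognitive-bias
#' coefficient theta: perceived OSH = theta * s. theta below 1 is a low-bias
#' perception, above 1 a high-bias perception.
#'
#' @param s True safety level(s) in \[0, 1\].
#' @param theta Perception coefficient(s), drawn uniformly on
#'   \[`theta_min`, `theta_max`\] by the engine.
#' @return `theta * s`, vectorised.
#' @examples
#' perceive_osh(0.5, 1.2)
#' @export
perceive_osh <- function(s, theta) {
  if (any(s < 0 | s > 1)) {
    rlang::abort("safety level must lie in [0, 1]", class = "sse_domain_error")
  }
  theta * s
}

#' Safety production efficiency
#'
#' Linear response of an employee's production efficiency to the perceived
#' OSH level: `SV = M * osh * eta + delta`. At the defaults (M = 0.22,
#' eta = 0.4, delta = 0.6) efficiency ranges from 0.6 (no perceived safety)
#' to 0.7056 (maximal high-bias perception of a fully safe workplace).
#'
#' @param osh Perceived OSH level(s), non-negative.
#' @param M,eta,delta Efficiency coefficients.
#' @return Efficiency value(s) `SV`.
#' @examples
#' production_efficiency(0)    # delta
#' production_efficiency(1)    # 0.688
#' @export
production_efficiency <- function(osh, M = 0.22, eta = 0.4, delta = 0.6) {
  if (any(osh < 0)) {
    rlang::abort("perceived OSH level must be non-negative",
                 class = "sse_domain_error")
  }
  M * osh * eta + delta
}

#' Sales response to public reputation
#'
#' Piecewise multiplier applied to the previous period's sales (or demand
#' fraction): unchanged at reputation `SC >= R1`; scaled by `SC*0.5 + 0.6` on
#' `[R0, R1)`; scaled by `SC*0.167 + 0.8` on `(0, R0)`. The multiplier is
#' near-continuous at the band edges and always lies in (0.8, 1].
#'
#' @param prev_sales Previous sales level(s), non-negative.
#' @param SC Public reputation value(s) in \[0, 1\].
#' @param R0,R1 Reputation thresholds.
#' @return Updated sales level(s).
#' @examples
#' apply_sales_response(1000, 0.9)  # carried forward
#' apply_sales_response(1000, 0.7)  # 950
#' @export
apply_sales_response <- function(prev_sales, SC, R0 = 0.6, R1 = 0.8) {
  if (any(prev_sales < 0)) {
    rlang::abort("sales must be non-negative", class = "sse_domain_error")
  }
  if (any(SC < 0 | SC > 1)) {
    rlang::abort("reputation value must lie in [0, 1]",
                 class = "sse_domain_error")
  }
  mult <- ifelse(SC >= R1, 1,
          ifelse(SC >= R0, SC * 0.5 + 0.6, SC * 0.167 + 0.8))
  prev_sales * mult
}

#' Government reward-penalty transfer
#'
#' Banded transfer keyed to the evaluated safety level: a penalty of
#' `-R_penalty` below `T0`, nothing on `[T0, T1)`, reward `P` on `[T1, T2)`,
#' and reward `B` at or above `T2`.
#'
#' @param system_value Evaluation result(s) in \[0, 1\].
#' @param cfg An `sse_config` supplying thresholds and amounts.
#' @return Signed transfer(s) in currency units.
#' @examples
#' reward_penalty(0.5)   # -10000
#' reward_penalty(0.85)  # +50000
#' @export
reward_penalty <- function(system_value, cfg = default_config()) {
  if (any(system_value < 0 | system_value > 1)) {
    rlang::abort("evaluation result must lie in [0, 1]",
                 class = "sse_domain_error")
  }
  ifelse(system_value < cfg$T0, -cfg$R_penalty,
  ifelse(system_value < cfg$T1, 0,
  ifelse(system_value < cfg$T2, cfg$P, cfg$B)))
}

#' Safety-graded tax rate
#'
#' Four-band tax schedule keyed to the evaluated safety level, decreasing from
#' `tax_band1` below `T0` to `tax_band4` at or above `T2`.
#'
#' @inheritParams reward_penalty
#' @return Tax rate(s) as fractions.
#' @examples
#' tax_rate(0.5)   # 0.2
#' tax_rate(0.85)  # 0.05
#' @export
tax_rate <- function(system_value, cfg = default_config()) {
  if (any(system_value < 0 | system_value > 1)) {
    rlang::abort("evaluation result must lie in [0, 1]",
                 class = "sse_domain_error")
  }
  ifelse(system_value < cfg$T0, cfg$tax_band1,
  ifelse(system_value < cfg$T1, cfg$tax_band2,
  ifelse(system_value < cfg$T2, cfg$tax_band3, cfg$tax_band4)))
}

#' Whistleblowing reward value
#'
#' Reward paid to an employee whose report is confirmed (the confirmed
#' evaluation falls below `T0`): the employee's safety production efficiency
#' plus 0.1. The value sits on the efficiency scale; the engine converts it to
#' currency with `whistle_reward_scale` when logging the transfer. It is a
#' government-to-employee payment and does not enter the SSE profit equation.
#'
#' @param efficiency_SV Safety production efficiency value(s), non-negative.
#' @return `efficiency_SV + 0.1`.
#' @examples
#' whistleblow_reward(0.6)  # 0.7
#' @export
whistleblow_reward <- function(efficiency_SV) {
  if (any(efficiency_SV < 0)) {
    rlang::abort("efficiency must be non-negative", class = "sse_domain_error")
  }
  efficiency_SV + 0.1
}

#' Employee action choice
#'
#' Decides, for one employee, which protective actions are taken this period.
#' Under scenario 1 the set is always empty. Where the scenario permits them,
#' exposure and whistleblowing are each chosen independently with the
#' configured propensity whenever the employee's perceived OSH level falls
#' below `action_threshold`. Turnover and raise demands are handled by the
#' engine's turnover step (scenario 5) and never returned here.
#'
#' @param osh_level The employee's perceived OSH level this period.
#' @param scenario An `sse_scenario`.
#' @param cfg An `sse_config`.
#' @return Character vector, a subset of `c("expose", "whistleblow")`.
#' @examples
#' decide_actions(0.9, scenario_spec(4))          # character(0)
#' withr::with_seed(1, decide_actions(0.4, scenario_spec(4),
#'                                    default_config(expose_prob = 1,
#'                                                   whistle_prob = 1)))
#' @export
decide_actions <- function(osh_level, scenario, cfg = default_config()) {
  stopifnot(inherits(scenario, "sse_scenario"))
  actions <- character(0)
  if (osh_level >= cfg$action_threshold) return(actions)
  if (scenario$allow_exposure && stats::runif(1) < cfg$expose_prob) {
    actions <- c(actions, "expose")
  }
  if (scenario$allow_whistleblowing && stats::runif(1) < cfg$whistle_prob) {
    actions <- c(actions, "whistleblow")
  }
  actions
}

#' Public reputation update
#'
#' With no exposures this period, reputation recovers additively at
#' `recovery_rate`, capped at 1. With exposures, reputation drops to the mean
#' perceived OSH level of the exposing employees (clamped to \[0, 1\]) unless it
#' is already lower.
#'
#' @param SC Previous reputation value in \[0, 1\].
#' @param exposures Numeric vector of exposing employees' perceived OSH levels
#'   (empty for none).
#' @param recovery_rate Additive recovery per period.
#' @return Updated reputation value in \[0, 1\].
#' @examples
#' update_reputation(0.9, numeric(0), 0.05)  # 0.95
#' update_reputation(0.9, c(0.3, 0.5))       # 0.4
#' @export
update_reputation <- function(SC, exposures = numeric(0),
                              recovery_rate = 0.05) {
  if (SC < 0 || SC > 1) {
    rlang::abort("reputation value must lie in [0, 1]",
                 class = "sse_domain_error")
  }
  if (length(exposures) == 0) {
    min(1, SC + recovery_rate)
  } else {
    min(SC, max(0, min(1, mean(exposures))))
  }
}

#' Government safety evaluation
#'
#' The regulator evaluates an SSE with certainty when triggered by a whistle,
#' otherwise with probability `inspection_prob` (a random inspection). When an
#' evaluation occurs, the evaluation result equals the true safety level and
#' the transfer and tax rate are filled from the banded schedules.
#'
#' @param sse_s True safety level in \[0, 1\].
#' @param triggered_by_whistle Logical; certain evaluation when `TRUE`.
#' @param cfg An `sse_config`.
#' @return `NULL` when no evaluation occurs, else a list with fields
#'   `system_value`, `transfer`, `tax_rate`, `inspected`.
#' @examples
#' evaluate_safety(0.85, triggered_by_whistle = TRUE)
#' @export
evaluate_safety <- function(sse_s, triggered_by_whistle = FALSE,
                            cfg = default_config()) {
  if (sse_s < 0 || sse_s > 1) {
    rlang::abort("safety level must lie in [0, 1]", class = "sse_domain_error")
  }
  occurs <- triggered_by_whistle || stats::runif(1) < cfg$inspection_prob
  if (!occurs) return(NULL)
  list(
    system_value = sse_s,
    transfer = reward_penalty(sse_s, cfg),
    tax_rate = tax_rate(sse_s, cfg),
    inspected = !triggered_by_whistle
  )
}
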