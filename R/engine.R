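# Scenario engine: per-period interaction loop over a population of SSEs.
#
# State is kept in flat vectors (one element per SSE) and an employee wage
# matrix (EN0 rows x n_sse columns, NA = vacant position) so every period step
# is vectorised. Employee actions taken in period t reach the public and the
# government in period t+1 (one-period information lag), which keeps the
# within-period computation acyclic.

init_population <- function(cfg) {
  n <- cfg$n_sse
  # initial census: classes uniform over 1..4, safety level drawn uniformly
  # within each class band
  cls <- rep_len(1:4, n)
  b1 <- cfg$class_frac_c1 * (cfg$s_max + cfg$s_min)
  b2 <- cfg$class_frac_c2 * (cfg$s_max + cfg$s_min)
  b3 <- cfg$class_frac_c3 * (cfg$s_max + cfg$s_min)
  lo <- c(b1, b2, b3, cfg$init_s_min)[cls]
  hi <- c(cfg$init_s_max, b1, b2, b3)[cls]
  s0 <- stats::runif(n, lo, hi)
  K <- investment_for_level(s0, cfg$beta)
  list(
    K = K,
    K_prev = K,              # for the investment-change sign at t >= 2
    F_prev = rep(NA_real_, n),
    PS = rep(1, n),          # demand fraction
    SC = rep(1, n),          # public reputation
    tax = rep(cfg$default_tax_rate, n),
    # working capital: bankruptcy fires when initial capital plus cumulative
    # profit stays negative for exit_periods consecutive periods
    cumF = rep(cfg$initial_capital, n),
    neg_streak = rep(0L, n),
    silent = rep(0L, n),     # consecutive periods without a K raise
    active = rep(TRUE, n),
    p = matrix(1 / 3, nrow = 3, ncol = n,
               dimnames = list(c("p_d", "p_i", "p_c"), NULL)),
    wages = matrix(cfg$WE, nrow = cfg$EN0, ncol = n),
    pending_expose_mean = rep(NA_real_, n),
    pending_whistles = rep(0L, n),
    pending_whistle_reward = rep(0, n)
  )
}

# Six-row update table used vectorised across SSEs (rows sum to zero).
.row_matrix <- function() {
  do.call(rbind, .adjustment_rows)
}

#' Advance the population by one period
#'
#' Executes the full interaction loop for every active SSE: safety level and
#' classification from investment; per-employee perception and efficiency
#' draws; employee action choices under the scenario flags; public reputation
#' and sales response (to last period's exposures); government evaluation
#' (whistle-triggered with certainty, otherwise random inspection), transfer,
#' tax and whistleblowing rewards; production, costs and profit; scenario-5
#' turnover and raises; the self-learning probability update and next-period
#' investment choice; and the bankruptcy exit check. Inactive SSEs are frozen.
#'
#' This is the engine's internal workhorse; it consumes and returns the flat
#' population state used by [run_simulation()]. Exposed primarily for
#' inspection and testing.
#'
#' @param state Population state list as produced by the engine.
#' @param scenario An `sse_scenario`.
#' @param cfg An `sse_config`.
#' @return A list with the updated `state` and a `record` list of per-SSE
#'   period outcomes (safety level, class, profit, events).
#' @keywords internal
#' @export
step_period <- function(state, scenario, cfg) {
  n <- cfg$n_sse
  act <- state$active
  if (!any(act)) {
    rlang::abort("no active SSEs remain", class = "sse_engine_error")
  }
  frozen <- !act

  # (1) safety level and class from current investment
  s <- safety_level(state$K, cfg$beta)
  cls <- classify(pmax(s, cfg$s_min + 1e-12), cfg)

  # (2) employee perception and efficiency
  employed <- !is.na(state$wages)
  theta <- matrix(stats::runif(cfg$EN0 * n, cfg$theta_min, cfg$theta_max),
                  nrow = cfg$EN0)
  osh <- sweep(theta, 2, s, `*`)
  SV <- cfg$M * osh * cfg$eta + cfg$delta
  EN <- colSums(employed)
  mean_SV <- ifelse(EN > 0, colSums(SV * employed) / EN, 0)

  # (3) employee actions this period (reach the system next period)
  dissatisfied <- employed & osh < cfg$action_threshold &
    matrix(act, nrow = cfg$EN0, ncol = n, byrow = TRUE)
  exposing <- whistling <- matrix(FALSE, cfg$EN0, n)
  if (scenario$allow_exposure) {
    exposing <- dissatisfied &
      matrix(stats::runif(cfg$EN0 * n), cfg$EN0) < cfg$expose_prob
  }
  if (scenario$allow_whistleblowing) {
    whistling <- dissatisfied &
      matrix(stats::runif(cfg$EN0 * n), cfg$EN0) < cfg$whistle_prob
  }
  n_expose <- colSums(exposing)
  n_whistle <- colSums(whistling)
  new_expose_mean <- ifelse(n_expose > 0,
                            colSums(osh * exposing) / pmax(n_expose, 1),
                            NA_real_)
  new_whistle_reward <- colSums((SV + 0.1) * whistling) *
    cfg$whistle_reward_scale

  # (4) reputation update and sales response from last period's exposures
  has_exp <- act & !is.na(state$pending_expose_mean)
  SC <- ifelse(has_exp,
               pmin(state$SC, pmax(0, pmin(1, state$pending_expose_mean))),
               pmin(1, state$SC + cfg$recovery_rate))
  PS <- apply_sales_response(state$PS, SC, cfg$R0, cfg$R1)
  # demand recovers toward normal market level while reputation is restored;
  # additive recovery so that the equilibrium demand fraction declines
  # smoothly with exposure frequency
  PS <- ifelse(SC >= cfg$R1, pmin(1, PS + cfg$sales_recovery_rate), PS)

  # market clearing: a fraction of the demand lost by disreputable SSEs is
  # captured by competitors whose reputation is intact (fixed market size)
  lost <- sum(ifelse(act, 1 - PS, 0))
  elig <- act & SC >= cfg$R1
  gain <- if (any(elig)) cfg$demand_redistribution * lost / sum(elig) else 0
  PS_eff <- ifelse(elig, pmin(cfg$demand_cap, PS + gain), PS)

  # (5) government evaluation: certain on last period's whistle; public
  # exposure (mass media) draws government attention with probability
  # expose_eval_prob; otherwise random inspection
  whistle_trig <- act & state$pending_whistles > 0
  expose_trig <- has_exp & stats::runif(n) < cfg$expose_eval_prob
  insp_draw <- stats::runif(n) < cfg$inspection_prob
  evaluated <- act & (whistle_trig | expose_trig | insp_draw)
  transfer <- ifelse(evaluated, reward_penalty(s, cfg), 0)
  tax <- ifelse(evaluated, tax_rate(s, cfg), state$tax)
  reward_paid <- ifelse(evaluated & whistle_trig & s < cfg$T0,
                        state$pending_whistle_reward, 0)

  # (6) production, costs, profit
  PV <- cfg$FP * cfg$T_months * mean_SV * EN * PS_eff * cfg$productivity_scale
  bill <- colSums(state$wages, na.rm = TRUE)
  LC <- bill * cfg$T_months
  C <- LC + state$K * cfg$K_cost_scale + cfg$PC
  F_t <- (1 - tax) * PV - C + transfer
  cumF <- state$cumF + ifelse(act, F_t, 0)

  # (7) scenario-5 turnover: dissatisfied employees of employers that kept
  # investment flat for >= silent_periods_trigger periods leave with
  # probability leave_prob, or stay and obtain a raise
  wages <- state$wages
  n_leave <- n_raise <- n_refill <- integer(n)
  if (scenario$allow_turnover_and_raise) {
    stale <- state$silent >= cfg$silent_periods_trigger
    eligible <- dissatisfied &
      matrix(stale, nrow = cfg$EN0, ncol = n, byrow = TRUE)
    leave_draw <- matrix(stats::runif(cfg$EN0 * n), cfg$EN0)
    leaving <- eligible & leave_draw < cfg$leave_prob
    raising <- eligible & !leaving
    wages[leaving] <- NA_real_
    wages[raising] <- wages[raising] * (1 + cfg$raise_rate)
    n_leave <- colSums(leaving)
    n_raise <- colSums(raising)
    # class-dependent recruitment: unsafe employers struggle to refill
    refill_p <- c(cfg$refill_prob_c1, cfg$refill_prob_c2,
                  cfg$refill_prob_c3, cfg$refill_prob_c4)[cls]
    vacant <- is.na(wages) & matrix(act, cfg$EN0, n, byrow = TRUE)
    refill_draw <- matrix(stats::runif(cfg$EN0 * n), cfg$EN0)
    refilled <- vacant & sweep(refill_draw, 2, refill_p, `<`)
    wages[refilled] <- cfg$WE
    n_refill <- colSums(refilled)
  }

  # (8) self-learning: adjust p from last period's (investment, profit) signs,
  # then draw next period's investment
  p <- state$p
  have_history <- act & !is.na(state$F_prev)
  if (any(have_history)) {
    dK <- state$K - state$K_prev
    dF <- F_t - state$F_prev
    inv_sign <- ifelse(dK > 1e-9, "increase",
                ifelse(dK < -1e-9, "decrease", "unchanged"))
    prof_sign <- ifelse(dF > cfg$profit_tol, "increase", "decrease")
    idx <- paste(inv_sign, prof_sign, sep = ".")
    deltas <- t(.row_matrix()[idx, , drop = FALSE]) * cfg$epsilon
    p_new <- p + deltas
    p_new <- pmin(pmax(p_new, cfg$p_floor), 1 - cfg$p_floor)
    p_new <- sweep(p_new, 2, colSums(p_new), `/`)
    p[, have_history] <- p_new[, have_history]
  }
  steps <- deltas_for_class(cls, state$K, cfg)
  draw <- stats::runif(n)
  K_next <- state$K
  dec_branch <- draw < p["p_d", ]
  inc_branch <- !dec_branch & draw < p["p_d", ] + p["p_i", ]
  K_next[dec_branch] <- pmax(cfg$k_min,
                             state$K[dec_branch] - steps$delta_dec[dec_branch])
  K_next[inc_branch] <- state$K[inc_branch] + steps$delta_inc[inc_branch]
  silent <- ifelse(K_next > state$K + 1e-9, 0L, state$silent + 1L)

  # (9) bankruptcy exit: sustained negative cumulative profit
  neg_streak <- ifelse(cumF < 0, state$neg_streak + 1L, 0L)
  exiting <- act & neg_streak >= cfg$exit_periods
  active_next <- act & !exiting

  # freeze inactive SSEs: restore their previous state wholesale
  restore <- function(new, old) {
    new[frozen] <- old[frozen]
    new
  }
  state_next <- list(
    K = restore(K_next, state$K),
    K_prev = restore(state$K, state$K_prev),
    F_prev = restore(F_t, state$F_prev),
    PS = restore(PS, state$PS),
    SC = restore(SC, state$SC),
    tax = restore(tax, state$tax),
    cumF = restore(cumF, state$cumF),
    neg_streak = restore(neg_streak, state$neg_streak),
    silent = restore(silent, state$silent),
    active = active_next,
    p = p,
    wages = state$wages,
    pending_expose_mean = ifelse(act, new_expose_mean,
                                 state$pending_expose_mean),
    pending_whistles = ifelse(act, n_whistle, state$pending_whistles),
    pending_whistle_reward = ifelse(act, new_whistle_reward,
                                    state$pending_whistle_reward)
  )
  state_next$p[, frozen] <- state$p[, frozen]
  if (scenario$allow_turnover_and_raise) {
    wages[, frozen] <- state$wages[, frozen]
    state_next$wages <- wages
  }

  record <- list(
    s = ifelse(act, s, NA_real_),
    class = ifelse(act, cls, NA_integer_),
    K = ifelse(act, state$K, NA_real_),
    F = ifelse(act, F_t, NA_real_),
    cumF = state_next$cumF,
    SC = ifelse(act, SC, NA_real_),
    PS = ifelse(act, PS, NA_real_),
    EN = ifelse(act, EN, NA_integer_),
    tax = ifelse(act, tax, NA_real_),
    active = act,
    exposures = ifelse(act, n_expose, 0L),
    whistleblows = ifelse(act, n_whistle, 0L),
    inspections = as.integer(act & insp_draw & !whistle_trig),
    evaluations = as.integer(evaluated),
    transfers = transfer,
    whistle_rewards = reward_paid,
    departures = n_leave,
    raises = n_raise,
    refills = n_refill,
    exits = as.integer(exiting)
  )
  list(state = state_next, record = record)
}

#' Run one scenario simulation
#'
#' Initialises a population of `cfg$n_sse` SSEs with classes uniform over the
#' four safety tiers, then iterates the period loop for `cfg$n_periods`
#' periods (one period = `cfg$T_months` months). All randomness flows through
#' `seed`; identical configuration and seed give bit-identical results.
#'
#' @param cfg An `sse_config` (validated before any simulation).
#' @param scenario An `sse_scenario` or a scenario id in 1..5.
#' @param seed Integer RNG seed.
#' @return An `sse_sim` object: a list with tibbles `trajectories` (per period
#'   x SSE state), `class_counts` (per period x class census plus exited
#'   count), `events` (long event log), and fields `scenario_id`, `seed`,
#'   `config`.
#' @examples
#' sim <- run_simulation(default_config(n_sse = 8, n_periods = 5), 1, seed = 1)
#' sim$class_counts
#' @export
run_simulation <- function(cfg, scenario, seed = cfg$rng_seed) {
  validate_config(cfg)
  if (!inherits(scenario, "sse_scenario")) scenario <- scenario_spec(scenario)
  n <- cfg$n_sse
  n_periods <- cfg$n_periods

  withr::with_seed(seed, {
    state <- init_population(cfg)
    records <- vector("list", n_periods)
    s0 <- safety_level(state$K, cfg$beta)
    cls0 <- classify(s0, cfg)
    t <- 1
    while (t <= n_periods && any(state$active)) {
      out <- step_period(state, scenario, cfg)
      state <- out$state
      records[[t]] <- out$record
      t <- t + 1
    }
    records <- records[!vapply(records, is.null, logical(1))]
  })

  n_done <- length(records)
  field <- function(name) {
    if (n_done == 0) return(numeric(0))
    as.vector(vapply(records, function(r) as.numeric(r[[name]]),
                     numeric(n)))
  }
  period_col <- rep(seq_len(n_done), each = n)
  sse_col <- rep(seq_len(n), times = n_done)

  trajectories <- dplyr::bind_rows(
    tibble::tibble(
      period = 0L, sse_id = seq_len(n),
      K = investment_for_level(s0, cfg$beta), s = s0, class = cls0,
      profit = NA_real_, cum_profit = cfg$initial_capital, SC = 1, PS = 1,
      EN = as.numeric(cfg$EN0), tax_rate = cfg$default_tax_rate, active = TRUE
    ),
    tibble::tibble(
      period = period_col, sse_id = sse_col,
      K = field("K"), s = field("s"), class = as.integer(field("class")),
      profit = field("F"), cum_profit = field("cumF"),
      SC = field("SC"), PS = field("PS"), EN = field("EN"),
      tax_rate = field("tax"), active = field("active") > 0
    )
  )

  class_counts <- trajectories |>
    dplyr::filter(.data$active, !is.na(.data$class)) |>
    dplyr::count(.data$period, .data$class, name = "count") |>
    tidyr::complete(period = 0:n_done, class = 1:4,
                    fill = list(count = 0L)) |>
    dplyr::left_join(
      trajectories |>
        dplyr::group_by(.data$period) |>
        dplyr::summarise(exited = sum(!.data$active)),
      by = "period"
    )

  event_fields <- c("exposures", "whistleblows", "inspections", "evaluations",
                    "transfers", "whistle_rewards", "departures", "raises",
                    "refills", "exits")
  events <- tibble::tibble(
    period = period_col, sse_id = sse_col,
    purrr::map_dfc(rlang::set_names(event_fields), field)
  ) |>
    tidyr::pivot_longer(dplyr::all_of(event_fields), names_to = "event",
                        values_to = "value") |>
    dplyr::filter(.data$value != 0)

  structure(list(
    trajectories = trajectories,
    class_counts = class_counts,
    events = events,
    scenario_id = scenario$scenario_id,
    seed = seed,
    config = cfg
  ), class = "sse_sim")
}

#' @export
print.sse_sim <- function(x, ...) {
  np <- max(x$trajectories$period)
  final <- dplyr::filter(x$class_counts, .data$period == np)
  cat("<sse_sim> scenario ", x$scenario_id, ", ", x$config$n_sse,
      " SSEs, ", np, " periods, seed ", x$seed, "\n", sep = "")
  cat("  final census: ",
      paste0("c", final$class, "=", final$count, collapse = " "),
      " exited=", final$exited[1], "\n", sep = "")
  invisible(x)
}
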