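#' Default simulation configuration
#'
#' Builds the full parameter set of the SSE safety-production model with the
#' model's published constants as defaults. Every key is a flat scalar so the
#' configuration round-trips through a flat YAML document and `--set key=value`
#' command-line overrides.
#'
#' The parameter groups are:
#'
#' * **Employee perception and efficiency** — `theta_min`, `theta_max` bound the
#'   random perception coefficient \eqn{\theta} (default \[0.8, 1.2\]); the
#'   perceived OSH level is \eqn{\theta s}. Safety production efficiency is
#'   \eqn{SV = M \cdot OSH \cdot \eta + \delta} with `M = 0.22`, `eta = 0.4`,
#'   `delta = 0.6`.
#' * **Public reputation and sales** — reputation thresholds `R0 = 0.6`,
#'   `R1 = 0.8`; below `R1` the demand fraction is scaled by the piecewise
#'   multipliers of the sales rule. `recovery_rate` restores reputation when no
#'   exposures occur, `sales_recovery_rate` restores demand toward normal
#'   market level while reputation is at or above `R1`. The market has fixed
#'   total size: a fraction `demand_redistribution` of the demand lost by
#'   disreputable SSEs is captured by competitors with intact reputation, up
#'   to `demand_cap` times normal demand per firm.
#' * **Government regulation** — evaluation thresholds `T0 = 0.6`, `T1 = 0.7`,
#'   `T2 = 0.8`; transfers `B = 50000` (high reward), `P = 5000` (reward),
#'   `R_penalty = 10000` (penalty, applied negatively); the four-band tax
#'   schedule `tax_band1..4 = 0.2, 0.15, 0.1, 0.05`; `default_tax_rate` paid by
#'   never-evaluated SSEs; `inspection_prob` for random inspections;
#'   `whistle_reward_scale` converts the whistleblowing reward value
#'   (efficiency + 0.1) to currency paid to the reporting employee.
#' * **SSE production economics** — safety level \eqn{s = \beta K/(1+\beta K)}
#'   with `beta = 0.33` per investment unit; `K_cost_scale` is the currency
#'   cost of one investment unit per period (safety investment enters total
#'   cost as `K * K_cost_scale`), making safety a genuine economic trade-off;
#'   product price `FP = 300`, period length `T_months = 3`, initial headcount
#'   `EN0 = 40`, monthly wage `WE = 3000`; `productivity_scale` (output units
#'   per employee per month at unit efficiency) calibrated jointly with
#'   `K_cost_scale` so that unregulated profit seeking favours sub-standard
#'   safety while regulated, reputation-sensitive firms can profitably sustain
#'   high safety; fixed per-period production cost `PC` (default 20% of the
#'   initial wage bill).
#' * **Self-learning** — probability step `epsilon`, probability floor
#'   `p_floor`, and per-class investment step fractions
#'   `delta_inc_frac_high/low`, `delta_dec_frac_high/low` ("high" = classes 1-2,
#'   "low" = classes 3-4) with absolute floor `delta_floor` and minimum
#'   investment `k_min`.
#' * **Scenario behaviour** — `action_threshold` (perceived OSH below which an
#'   employee acts, default equal to `T0`), `expose_prob`, `whistle_prob`,
#'   `expose_eval_prob` (probability that a public-exposure event in the media
#'   draws a government evaluation the following period),
#'   turnover parameters `leave_prob`, `raise_rate`, `silent_periods_trigger`,
#'   class-dependent refill probabilities `refill_prob_c1..c4`, and the
#'   bankruptcy rule `exit_periods` (consecutive periods of negative cumulative
#'   profit before exit).
#' * **Classification** — `s_min`, `s_max` and the class boundary fractions
#'   `class_frac_c1/c2/c3` (0.8/0.7/0.6 of `s_max + s_min`).
#' * **Experiment size** — `n_sse`, `n_periods`, `n_replicates`, `rng_seed`,
#'   and the initial safety-level draw bounds `init_s_min`, `init_s_max`.
#'
#' @param ... Named overrides of any default key. Unknown keys error.
#' @return A validated `sse_config` object (a named list).
#' @examples
#' cfg <- default_config()
#' cfg$T0
#' default_config(beta = 0.5)$beta
#' @export
default_config <- function(...) {
  cfg <- structure(list(
    # employee perception & efficiency
    theta_min = 0.8,
    theta_max = 1.2,
    M = 0.22,
    eta = 0.4,
    delta = 0.6,
    # public reputation & sales
    R0 = 0.6,
    R1 = 0.8,
    recovery_rate = 0.5,
    sales_recovery_rate = 0.12,
    # government regulation
    T0 = 0.6,
    T1 = 0.7,
    T2 = 0.8,
    B = 50000,
    P = 5000,
    R_penalty = 10000,
    tax_band1 = 0.2,
    tax_band2 = 0.15,
    tax_band3 = 0.1,
    tax_band4 = 0.05,
    default_tax_rate = 0.15,
    inspection_prob = 0.1,
    whistle_reward_scale = 3000,
    # SSE production economics
    beta = 0.33,
    FP = 300,
    T_months = 3,
    EN0 = 40,
    WE = 3000,
    productivity_scale = 24,
    PC = 72000,
    K_cost_scale = 5000,
    # self-learning
    epsilon = 0.15,
    p_floor = 0.01,
    delta_inc_frac_high = 0.05,
    delta_inc_frac_low = 0.10,
    delta_dec_frac_high = 0.10,
    delta_dec_frac_low = 0.04,
    delta_floor = 0.1,
    k_min = 0.1,
    profit_tol = 1,
    # scenario behaviour
    action_threshold = 0.6,
    expose_prob = 0.025,
    expose_eval_prob = 1,
    demand_redistribution = 0.5,
    demand_cap = 1.25,
    whistle_prob = 0.5,
    leave_prob = 0.3,
    raise_rate = 0.02,
    silent_periods_trigger = 2,
    refill_prob_c1 = 0.9,
    refill_prob_c2 = 0.7,
    refill_prob_c3 = 0.5,
    refill_prob_c4 = 0.2,
    exit_periods = 3,
    initial_capital = 60000,
    # classification
    s_min = 0,
    s_max = 1,
    class_frac_c1 = 0.8,
    class_frac_c2 = 0.7,
    class_frac_c3 = 0.6,
    # experiment size & initial census
    init_s_min = 0.5,
    init_s_max = 0.92,
    n_sse = 50,
    n_periods = 60,
    n_replicates = 20,
    rng_seed = 42
  ), class = "sse_config")
  overrides <- list(...)
  if (length(overrides) > 0) {
    cfg <- apply_overrides(cfg, overrides)
  }
  validate_config(cfg)
}

apply_overrides <- function(cfg, overrides) {
  if (length(overrides) == 0) return(cfg)
  nms <- names(overrides)
  if (is.null(nms) || any(!nzchar(nms))) {
    rlang::abort("All configuration overrides must be named.",
                 class = "sse_config_error")
  }
  unknown <- setdiff(nms, names(cfg))
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("Unknown configuration key(s): ", paste(unknown, collapse = ", ")),
      class = "sse_config_error"
    )
  }
  for (key in nms) {
    value <- overrides[[key]]
    if (!is.numeric(value) || length(value) != 1 || is.na(value)) {
      rlang::abort(
        paste0("Configuration key '", key, "' must be a single finite number, got: ",
               paste(format(value), collapse = ", ")),
        class = "sse_config_type_error"
      )
    }
    cfg[[key]] <- as.numeric(value)
  }
  cfg
}

#' Load a configuration from a flat YAML document
#'
#' Reads a flat key-value YAML file, overlays it on the defaults, then applies
#' `overrides` on top (command-line `--set` semantics). Keys not present in the
#' default configuration are rejected by name.
#'
#' @param path Path to a YAML file, or `NULL` for defaults only.
#' @param overrides Named list of final overrides applied after the file.
#' @return A validated `sse_config`.
#' @examples
#' cfg <- load_config(NULL, overrides = list(beta = 0.5))
#' cfg$beta
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- structure(unclass(default_config()), class = "sse_config")
  if (!is.null(path)) {
    if (!file.exists(path)) {
      rlang::abort(paste0("Configuration file not found: ", path),
                   class = "sse_config_error")
    }
    doc <- yaml::read_yaml(path)
    if (is.null(doc)) doc <- list()
    if (!is.list(doc)) {
      rlang::abort("Configuration file must be a flat key-value mapping.",
                   class = "sse_config_error")
    }
    cfg <- apply_overrides(cfg, doc)
  }
  cfg <- apply_overrides(cfg, overrides)
  validate_config(cfg)
}

#' Write a configuration to a flat YAML document
#'
#' @param cfg An `sse_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "sse_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Validate a simulation configuration
#'
#' Checks every structural invariant of the model parameters and returns the
#' configuration unchanged when all hold. Each violated invariant raises a
#' distinct, named error.
#'
#' @param cfg An `sse_config`.
#' @return `cfg`, unchanged.
#' @export
validate_config <- function(cfg) {
  if (!inherits(cfg, "sse_config")) {
    rlang::abort("Expected an 'sse_config' object; see default_config().",
                 class = "sse_config_error")
  }
  fail <- function(msg) {
    rlang::abort(paste0("Invalid configuration: ", msg),
                 class = "sse_config_invalid")
  }
  with(cfg, {
    if (!(theta_min <= theta_max)) {
      fail("theta_min must not exceed theta_max")
    }
    if (!(T0 > 0 && T0 < T1 && T1 < T2 && T2 < 1)) {
      fail("evaluation thresholds must satisfy 0 < T0 < T1 < T2 < 1")
    }
    if (!(R0 > 0 && R0 < R1 && R1 <= 1)) {
      fail("reputation thresholds must satisfy 0 < R0 < R1 <= 1")
    }
    taxes <- c(tax_band1, tax_band2, tax_band3, tax_band4)
    if (!all(diff(taxes) < 0)) {
      fail("tax schedule must be strictly decreasing across the four bands")
    }
    if (any(taxes < 0 | taxes > 1)) {
      fail("tax rates must lie in [0, 1]")
    }
    if (!(beta > 0)) fail("beta must be positive")
    if (!(K_cost_scale > 0)) fail("K_cost_scale must be positive")
    if (!(epsilon > 0)) fail("epsilon must be positive")
    # the raw Table-1 update moves a component by at most epsilon; it must not
    # be able to push an initially uniform vector out of [0,1]
    if (!(epsilon < 1 / 3)) {
      fail("epsilon must be smaller than the initial strategy probabilities (1/3)")
    }
    if (!(p_floor >= 0 && p_floor < 1 / 3)) {
      fail("p_floor must lie in [0, 1/3)")
    }
    currency <- c(B, P, R_penalty, FP, WE, PC, delta_floor,
                  whistle_reward_scale)
    if (any(currency < 0)) {
      fail("currency amounts (B, P, R_penalty, FP, WE, PC, delta_floor, whistle_reward_scale) must be non-negative")
    }
    probs <- c(inspection_prob, expose_prob, expose_eval_prob, whistle_prob,
               leave_prob,
               refill_prob_c1, refill_prob_c2, refill_prob_c3, refill_prob_c4,
               default_tax_rate)
    if (any(probs < 0 | probs > 1)) {
      fail("probabilities and rates must lie in [0, 1]")
    }
    if (!(demand_redistribution >= 0 && demand_redistribution <= 1)) {
      fail("demand_redistribution must lie in [0, 1]")
    }
    if (!(demand_cap >= 1)) {
      fail("demand_cap must be at least 1 (normal market demand)")
    }
    if (!(s_min < s_max)) fail("s_min must be below s_max")
    if (!(class_frac_c3 < class_frac_c2 && class_frac_c2 < class_frac_c1)) {
      fail("class boundary fractions must be strictly increasing c3 < c2 < c1")
    }
    fracs <- c(delta_inc_frac_high, delta_inc_frac_low,
               delta_dec_frac_high, delta_dec_frac_low)
    if (any(fracs <= 0)) fail("investment step fractions must be positive")
    if (!(delta_dec_frac_high > delta_dec_frac_low)) {
      fail("decrement fraction of high/medium classes must exceed that of low classes")
    }
    if (!(delta_inc_frac_low > delta_inc_frac_high)) {
      fail("increment fraction of low classes must exceed that of high/medium classes")
    }
    if (!(init_s_min > s_min && init_s_max < s_max && init_s_min < init_s_max)) {
      fail("initial safety-level bounds must satisfy s_min < init_s_min < init_s_max < s_max")
    }
    counts <- c(n_sse, n_periods, n_replicates, EN0, T_months,
                silent_periods_trigger, exit_periods)
    if (any(counts != round(counts)) || n_sse < 1 || n_replicates < 1 ||
        n_periods < 0 || EN0 < 1 || T_months < 1) {
      fail("n_sse, n_periods, n_replicates, EN0, T_months must be whole numbers (n_periods >= 0, others >= 1)")
    }
    if (!(k_min > 0)) fail("k_min must be positive")
  })
  cfg
}

#' @export
print.sse_config <- function(x, ...) {
  cat("<sse_config> ", length(x), " parameters\n", sep = "")
  cat("  thresholds: T0/T1/T2 = ", x$T0, "/", x$T1, "/", x$T2,
      ", R0/R1 = ", x$R0, "/", x$R1, "\n", sep = "")
  cat("  transfers: B = ", x$B, ", P = ", x$P, ", penalty = ", x$R_penalty,
      "\n", sep = "")
  cat("  economics: beta = ", x$beta, ", FP = ", x$FP, ", EN0 = ", x$EN0,
      ", WE = ", x$WE, "\n", sep = "")
  cat("  experiment: ", x$n_sse, " SSEs x ", x$n_periods, " periods x ",
      x$n_replicates, " replicates\n", sep = "")
  invisible(x)
}

#' Scenario specification
#'
#' Maps a scenario id to the employee-behaviour flags it enables:
#' 1. silence — employees take no action;
#' 2. public exposure only;
#' 3. whistleblowing to the government only;
#' 4. exposure and whistleblowing;
#' 5. exposure, whistleblowing, and turnover / raise demands.
#'
#' @param scenario_id Integer in 1..5.
#' @return An `sse_scenario` list with fields `scenario_id`, `allow_exposure`,
#'   `allow_whistleblowing`, `allow_turnover_and_raise`.
#' @examples
#' scenario_spec(4)
#' @export
scenario_spec <- function(scenario_id) {
  if (length(scenario_id) != 1 || !scenario_id %in% 1:5) {
    rlang::abort("scenario_id must be a single integer in 1..5",
                 class = "sse_scenario_error")
  }
  scenario_id <- as.integer(scenario_id)
  structure(list(
    scenario_id = scenario_id,
    allow_exposure = scenario_id %in% c(2L, 4L, 5L),
    allow_whistleblowing = scenario_id %in% c(3L, 4L, 5L),
    allow_turnover_and_raise = scenario_id == 5L
  ), class = "sse_scenario")
}

#' @export
print.sse_scenario <- function(x, ...) {
  acts <- c(
    if (x$allow_exposure) "exposure",
    if (x$allow_whistleblowing) "whistleblowing",
    if (x$allow_turnover_and_raise) "turnover/raise"
  )
  cat("<sse_scenario> ", x$scenario_id, ": ",
      if (length(acts)) paste(acts, collapse = " + ") else "no employee action",
      "\n", sep = "")
  invisible(x)
}
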