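#' Bankruptcy exit rule
#'
#' An SSE exits the market permanently once its cumulative profit has been
#' negative for `k` consecutive periods. Given a cumulative-profit history,
#' returns the 1-based period at which the exit fires, or `NA` if it never
#' does.
#'
#' @param cum_profits Numeric vector of cumulative profit by period.
#' @param k Consecutive-period threshold (default 3).
#' @return Integer period of exit, or `NA_integer_`.
#' @examples
#' check_exit(c(10, -5, -2, -1))       # exits at period 4
#' check_exit(c(-1, 5, -1, 5, -1))     # never exits
#' @export
check_exit <- function(cum_profits, k = 3) {
  streak <- 0L
  for (t in seq_along(cum_profits)) {
    streak <- if (cum_profits[t] < 0) streak + 1L else 0L
    if (streak >= k) return(t)
  }
  NA_integer_
}

#' Run a seeded replicate ensemble of one scenario
#'
#' Runs `n_replicates` independent simulations with seeds
#' `base_seed + 0:(n_replicates-1)` and collects per-period, per-replicate
#' population summaries: class counts, active-population safety-level totals,
#' and profit aggregates.
#'
#' @param cfg An `sse_config`.
#' @param scenario An `sse_scenario` or scenario id.
#' @param n_replicates Number of replicates (defaults to `cfg$n_replicates`).
#' @param base_seed First seed of the ensemble (defaults to `cfg$rng_seed`).
#' @return An `sse_ensemble` object with tibbles `by_period` (per replicate x
#'   period summaries) and `summary` (across-replicate means and standard
#'   errors), plus `scenario_id`, `seeds`, `config`.
#' @examples
#' ens <- run_replicates(default_config(n_sse = 8, n_periods = 5,
#'                                      n_replicates = 2), 1, base_seed = 1)
#' ens$summary
#' @export
run_replicates <- function(cfg, scenario,
                           n_replicates = cfg$n_replicates,
                           base_seed = cfg$rng_seed) {
  validate_config(cfg)
  if (!inherits(scenario, "sse_scenario")) scenario <- scenario_spec(scenario)
  if (n_replicates < 1) {
    rlang::abort("n_replicates must be >= 1", class = "sse_engine_error")
  }
  seeds <- base_seed + seq_len(n_replicates) - 1

  by_period <- purrr::map2_dfr(seeds, seq_along(seeds), function(sd, rep_id) {
    sim <- run_simulation(cfg, scenario, seed = sd)
    per <- sim$trajectories |>
      dplyr::filter(.data$period > 0) |>
      dplyr::group_by(.data$period) |>
      dplyr::summarise(
        n_active = sum(.data$active),
        sum_s_active = sum(.data$s[.data$active], na.rm = TRUE),
        mean_profit = ifelse(sum(.data$active) > 0,
                             mean(.data$profit[.data$active], na.rm = TRUE),
                             NA_real_),
        total_profit = sum(.data$profit[.data$active], na.rm = TRUE),
        exited = sum(!.data$active),
        .groups = "drop"
      )
    counts <- sim$class_counts |>
      dplyr::filter(.data$period > 0) |>
      dplyr::select("period", "class", "count") |>
      tidyr::pivot_wider(names_from = "class", values_from = "count",
                         names_prefix = "c")
    dplyr::left_join(per, counts, by = "period") |>
      dplyr::mutate(replicate = rep_id, seed = sd, .before = 1)
  })

  for (col in paste0("c", 1:4)) {
    if (!col %in% names(by_period)) by_period[[col]] <- 0L
    by_period[[col]][is.na(by_period[[col]])] <- 0L
  }

  summary <- by_period |>
    dplyr::group_by(.data$period) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(c(paste0("c", 1:4), "exited",
                                    "mean_profit", "total_profit")),
                    list(mean = ~mean(.x, na.rm = TRUE),
                         se = ~stats::sd(.x, na.rm = TRUE) /
                           sqrt(sum(!is.na(.x))))),
      mean_safety = sum(.data$sum_s_active) / pmax(sum(.data$n_active), 1),
      .groups = "drop"
    )

  structure(list(
    by_period = by_period,
    summary = summary,
    scenario_id = scenario$scenario_id,
    seeds = seeds,
    config = cfg
  ), class = "sse_ensemble")
}

#' @export
print.sse_ensemble <- function(x, ...) {
  cat("<sse_ensemble> scenario ", x$scenario_id, ", ",
      length(x$seeds), " replicates x ", x$config$n_sse, " SSEs x ",
      x$config$n_periods, " periods\n", sep = "")
  invisible(x)
}
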