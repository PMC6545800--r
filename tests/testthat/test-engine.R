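# small-population config: the fixed production cost is scaled with EN0 so the
# downsized economy stays viable (the default PC assumes EN0 = 40)
small_cfg <- function(n_sse = 10, n_periods = 12, EN0 = 8, ...) {
  default_config(n_sse = n_sse, n_periods = n_periods, EN0 = EN0,
                 PC = 1800 * EN0, ...)
}

# population entirely below the employee action threshold (s <= 0.45, so
# perceived OSH <= 0.54 < 0.6): class bands are compressed downward while
# keeping the required ordering init_s_min < b3 < b2 < b1 < init_s_max
low_cfg <- function(EN0 = 8, ...) {
  default_config(class_frac_c1 = 0.35, class_frac_c2 = 0.3,
                 class_frac_c3 = 0.25, init_s_min = 0.05, init_s_max = 0.45,
                 EN0 = EN0, PC = 1800 * EN0, ...)
}

test_that("run_simulation validates config and scenario first", {
  bad <- default_config()
  bad$T0 <- 0.9
  expect_error(run_simulation(bad, 1), class = "sse_config_invalid")
  expect_error(run_simulation(default_config(), 7),
               class = "sse_scenario_error")
})

test_that("n_periods = 0 returns only the initial census", {
  sim <- run_simulation(small_cfg(n_periods = 0), 1, seed = 1)
  expect_identical(unique(sim$trajectories$period), 0L)
  expect_equal(nrow(sim$trajectories), 10)
  expect_true(all(sim$trajectories$active))
  expect_equal(nrow(sim$events), 0)
})

test_that("initial census is uniform over the four classes", {
  sim <- run_simulation(default_config(n_sse = 40, n_periods = 0), 1, seed = 3)
  init <- dplyr::filter(sim$class_counts, period == 0)
  expect_equal(init$count, rep(10L, 4))
})

test_that("identical configuration and seed give bit-identical results", {
  cfg <- small_cfg()
  last <- NULL
  for (sc in c(1, 4, 5)) {
    a <- run_simulation(cfg, sc, seed = 11)
    b <- run_simulation(cfg, sc, seed = 11)
    expect_identical(a$trajectories, b$trajectories)
    expect_identical(a$class_counts, b$class_counts)
    expect_identical(a$events, b$events)
    last <- a
  }
  # different seeds differ
  c2 <- run_simulation(cfg, 5, seed = 12)
  expect_false(identical(last$trajectories, c2$trajectories))
})

test_that("population is conserved each period in every scenario", {
  cfg <- small_cfg(n_periods = 20)
  for (sc in 1:5) {
    sim <- run_simulation(cfg, sc, seed = 5 + sc)
    census <- sim$class_counts |>
      dplyr::group_by(period) |>
      dplyr::summarise(total = sum(count) + exited[1])
    expect_true(all(census$total == cfg$n_sse))
    per_period <- sim$trajectories |>
      dplyr::count(period)
    expect_true(all(per_period$n == cfg$n_sse))
  }
})

test_that("scenario 1 with inspection_prob = 0 has frozen null dynamics", {
  cfg <- small_cfg(inspection_prob = 0)
  sim <- run_simulation(cfg, 1, seed = 2)
  tr <- dplyr::filter(sim$trajectories, period > 0, active)
  expect_true(all(tr$SC == 1))
  expect_true(all(tr$PS == 1))
  expect_true(all(tr$tax_rate == cfg$default_tax_rate))
  evts <- unique(sim$events$event)
  expect_false(any(c("transfers", "inspections", "evaluations",
                     "exposures", "whistleblows") %in% evts))
})

test_that("whistled sub-standard SSE is penalised next period", {
  cfg <- low_cfg(n_sse = 4, n_periods = 3, EN0 = 5,
                 inspection_prob = 0, whistle_prob = 1)
  sim <- run_simulation(cfg, 3, seed = 7)
  # every firm is whistled in period 1 (all perceived OSH < 0.6), so period 2
  # logs the sub-standard penalty for each and refreshes the tax to band 1
  tr2 <- dplyr::filter(sim$events, period == 2, event == "transfers")
  expect_equal(nrow(tr2), 4)
  expect_true(all(tr2$value == -10000))
  t2 <- dplyr::filter(sim$trajectories, period == 2, active)
  expect_true(all(t2$tax_rate == cfg$tax_band1))
})

test_that("public exposure degrades reputation and sales with one-period lag", {
  cfg <- low_cfg(n_sse = 4, n_periods = 3, EN0 = 5,
                 inspection_prob = 0, expose_prob = 1, expose_eval_prob = 0,
                 recovery_rate = 0, sales_recovery_rate = 0)
  sim <- run_simulation(cfg, 2, seed = 9)
  tr <- sim$trajectories
  # period 1: exposures happen but reputation and sales are unaffected yet
  p1 <- dplyr::filter(tr, period == 1)
  expect_true(all(p1$SC == 1))
  expect_true(all(p1$PS == 1))
  # period 2: SC dropped to the exposers' mean perceived OSH, sales follow
  p2 <- dplyr::filter(tr, period == 2, active)
  expect_true(all(p2$SC < 0.55))
  expect_true(all(p2$PS < 1))
  # with expose_eval_prob = 0 and no inspections the tax is never refreshed
  expect_true(all(p2$tax_rate == cfg$default_tax_rate))
})

test_that("exited SSEs are frozen permanently and leave the census", {
  cfg <- small_cfg(n_periods = 40)
  found_exit <- FALSE
  for (sc in c(1, 4)) {
    sim <- run_simulation(cfg, sc, seed = 100 + sc)
    tr <- sim$trajectories
    gone <- tr |>
      dplyr::filter(!active) |>
      dplyr::distinct(sse_id)
    for (id in gone$sse_id) {
      found_exit <- TRUE
      rows <- dplyr::filter(tr, sse_id == id, !active)
      first_gone <- min(rows$period)
      later <- dplyr::filter(tr, sse_id == id, period >= first_gone)
      expect_true(all(!later$active))
      expect_equal(length(unique(later$cum_profit)), 1)
      expect_true(all(is.na(later$s)))
      expect_true(all(is.na(later$profit)))
    }
  }
  expect_true(found_exit)
})

test_that("the bankruptcy rule follows the consecutive-negative contract", {
  expect_equal(check_exit(c(10, -5, -2, -1)), 4L)
  expect_equal(check_exit(c(1, 2, -1, -1, -1, 5), k = 3), 5L)
  expect_true(is.na(check_exit(c(-1, 5, -1, 5, -1), k = 3)))
  expect_equal(check_exit(rep(-1, 3)), 3L)
  expect_true(is.na(check_exit(numeric(0))))
})

test_that("scenario 5 generates turnover events; scenario 4 does not", {
  cfg <- low_cfg(n_sse = 10, n_periods = 10, EN0 = 10, leave_prob = 0.5)
  s5 <- run_simulation(cfg, 5, seed = 21)
  s4 <- run_simulation(cfg, 4, seed = 21)
  e5 <- unique(s5$events$event)
  expect_true(any(c("departures", "raises") %in% e5))
  e4 <- unique(s4$events$event)
  expect_false(any(c("departures", "raises", "refills") %in% e4))
})

test_that("with certain departures and no refills, headcount shrinks", {
  cfg <- low_cfg(n_sse = 6, n_periods = 8, EN0 = 10, leave_prob = 1,
                 refill_prob_c1 = 0, refill_prob_c2 = 0,
                 refill_prob_c3 = 0, refill_prob_c4 = 0)
  sim <- run_simulation(cfg, 5, seed = 33)
  en <- sim$trajectories |>
    dplyr::filter(active) |>
    dplyr::group_by(period) |>
    dplyr::summarise(EN = mean(EN), .groups = "drop")
  expect_lt(dplyr::last(en$EN), dplyr::first(en$EN))
})

test_that("step_period errors when no SSE is active", {
  cfg <- small_cfg()
  state <- withr::with_seed(1, ssesim:::init_population(cfg))
  state$active[] <- FALSE
  expect_error(step_period(state, scenario_spec(1), cfg),
               class = "sse_engine_error")
})
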