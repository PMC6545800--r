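test_that("perceive_osh scales the true safety level by theta", {
  expect_equal(perceive_osh(0.5, 1.2), 0.6)
  expect_equal(perceive_osh(c(0.2, 0.8), c(0.8, 1.0)), c(0.16, 0.8))
  expect_error(perceive_osh(1.1, 1), class = "sse_domain_error")
})

test_that("production_efficiency is linear with intercept delta", {
  expect_equal(production_efficiency(0), 0.6)
  expect_equal(production_efficiency(1), 0.22 * 0.4 + 0.6)
  expect_equal(production_efficiency(1.2), 0.22 * 1.2 * 0.4 + 0.6)
  expect_error(production_efficiency(-0.1), class = "sse_domain_error")
})

test_that("apply_sales_response implements the three reputation bands", {
  # carried forward unchanged at SC >= R1
  expect_equal(apply_sales_response(1000, 0.8), 1000)
  expect_equal(apply_sales_response(1000, 1.0), 1000)
  # middle band: SC * 0.5 + 0.6
  expect_equal(apply_sales_response(1000, 0.7), 1000 * (0.7 * 0.5 + 0.6))
  expect_equal(apply_sales_response(1000, 0.6), 1000 * 0.9)
  # low band: SC * 0.167 + 0.8
  expect_equal(apply_sales_response(1000, 0.3), 1000 * (0.3 * 0.167 + 0.8))
  expect_error(apply_sales_response(-1, 0.5), class = "sse_domain_error")
  expect_error(apply_sales_response(1, 1.5), class = "sse_domain_error")
})

test_that("sales multipliers are near-continuous and bounded in (0.8, 1]", {
  sc <- seq(0.001, 1, by = 0.001)
  mult <- apply_sales_response(rep(1, length(sc)), sc)
  expect_true(all(mult > 0.8 & mult <= 1))
  # jump across each band edge is small
  expect_lt(abs(apply_sales_response(1, 0.6) -
                apply_sales_response(1, 0.5999)), 0.001)
  expect_lt(abs(apply_sales_response(1, 0.8) -
                apply_sales_response(1, 0.7999)), 0.055)
})

test_that("reward_penalty reproduces the banded transfer schedule", {
  expect_equal(reward_penalty(0.5), -10000)
  expect_equal(reward_penalty(0.65), 0)
  expect_equal(reward_penalty(0.75), 5000)
  expect_equal(reward_penalty(0.85), 50000)
  # band edges are inclusive on the left
  expect_equal(reward_penalty(0.6), 0)
  expect_equal(reward_penalty(0.7), 5000)
  expect_equal(reward_penalty(0.8), 50000)
  expect_error(reward_penalty(1.2), class = "sse_domain_error")
})

test_that("tax_rate reproduces the four-band schedule", {
  expect_equal(tax_rate(c(0.5, 0.65, 0.75, 0.85)),
               c(0.2, 0.15, 0.1, 0.05))
  expect_equal(tax_rate(c(0.6, 0.7, 0.8)), c(0.15, 0.1, 0.05))
  expect_error(tax_rate(-0.1), class = "sse_domain_error")
})

test_that("whistleblow_reward adds 0.1 to the efficiency value", {
  expect_equal(whistleblow_reward(0.6), 0.7)
  expect_error(whistleblow_reward(-1), class = "sse_domain_error")
})

test_that("decide_actions respects scenario flags and the threshold", {
  cfg <- default_config(expose_prob = 1, whistle_prob = 1)
  # scenario 1: never any action
  expect_identical(decide_actions(0.1, scenario_spec(1), cfg), character(0))
  # above threshold: no action in any scenario
  expect_identical(decide_actions(0.9, scenario_spec(4), cfg), character(0))
  # at-certainty propensities below threshold
  expect_identical(decide_actions(0.4, scenario_spec(2), cfg), "expose")
  expect_identical(decide_actions(0.4, scenario_spec(3), cfg), "whistleblow")
  expect_setequal(decide_actions(0.4, scenario_spec(4), cfg),
                  c("expose", "whistleblow"))
  zero <- default_config(expose_prob = 0, whistle_prob = 0)
  expect_identical(decide_actions(0.4, scenario_spec(4), zero), character(0))
})

test_that("update_reputation recovers without exposures and drops with them", {
  expect_equal(update_reputation(0.9, numeric(0), 0.05), 0.95)
  expect_equal(update_reputation(0.99, numeric(0), 0.05), 1)   # capped
  expect_equal(update_reputation(0.9, c(0.3, 0.5)), 0.4)
  # never increases on exposure: stays at the lower current value
  expect_equal(update_reputation(0.2, c(0.9)), 0.2)
  # exposure means are clamped into [0, 1]
  expect_equal(update_reputation(1, c(1.4)), 1)
  expect_error(update_reputation(1.2), class = "sse_domain_error")
})

test_that("evaluate_safety is certain on whistle and banded on output", {
  res <- evaluate_safety(0.85, triggered_by_whistle = TRUE)
  expect_equal(res$system_value, 0.85)
  expect_equal(res$transfer, 50000)
  expect_equal(res$tax_rate, 0.05)
  expect_false(res$inspected)
  # no whistle, inspection_prob = 0: never evaluates
  cfg0 <- default_config(inspection_prob = 0)
  expect_null(evaluate_safety(0.5, FALSE, cfg0))
  # no whistle, inspection_prob = 1: always evaluates, flagged as inspection
  cfg1 <- default_config(inspection_prob = 1)
  res2 <- evaluate_safety(0.5, FALSE, cfg1)
  expect_equal(res2$transfer, -10000)
  expect_true(res2$inspected)
  expect_error(evaluate_safety(-0.1), class = "sse_domain_error")
})
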