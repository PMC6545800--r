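test_that("survey_reference stores the printed constants verbatim", {
  ref <- survey_reference()
  expect_equal(ref$survey_mean, c(1.78, 2.48, 3.63, 4.04, NA_real_))
  expect_equal(ref$survey_sd, c(0.797, 0.588, 0.615, 0.767, NA_real_))
  expect_equal(ref$model_label,
               c("Very low", "Medium", "Low", "High", "Very high"))
  expect_equal(ref$survey_label,
               c("Very low", "Medium", "Low", "High", NA_character_))
})

test_that("impact_score matches hand-computed windows", {
  cfg <- default_config(n_sse = 6, n_periods = 8, EN0 = 4, PC = 7200,
                        n_replicates = 2)
  ens <- run_replicates(cfg, 1, base_seed = 5)
  # manual recomputation: active-weighted mean s per replicate, then averaged
  # (the window start is anchored on the last recorded period, which can be
  # earlier than n_periods when a replicate's population went extinct)
  np <- max(ens$by_period$period)
  start <- floor(np * 0.75) + 1
  manual <- ens$by_period |>
    dplyr::filter(period >= start, n_active > 0) |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(score = sum(sum_s_active) / sum(n_active),
                     .groups = "drop")
  expect_equal(impact_score(ens), mean(manual$score))
  # window_fraction = 1 equals the full-horizon mean
  manual_full <- ens$by_period |>
    dplyr::filter(n_active > 0) |>
    dplyr::group_by(replicate) |>
    dplyr::summarise(score = sum(sum_s_active) / sum(n_active),
                     .groups = "drop")
  expect_equal(impact_score(ens, window_fraction = 1), mean(manual_full$score))
  expect_error(impact_score(ens, window_fraction = 0),
               class = "sse_domain_error")
})

test_that("assign_ordinal_labels maps ranks onto the five classes", {
  lab <- assign_ordinal_labels(c(0.2, 0.5, 0.4, 0.7, 0.8))
  expect_equal(as.character(lab$ordinal_label),
               c("Very low", "Medium", "Low", "High", "Very high"))
  # tie-break by scenario id: lower id gets the lower label
  tied <- assign_ordinal_labels(c(0.5, 0.5, 0.5, 0.5, 0.5))
  expect_equal(as.character(tied$ordinal_label),
               c("Very low", "Low", "Medium", "High", "Very high"))
  # any permutation of scores yields a bijection with the five classes
  perm <- assign_ordinal_labels(c(0.9, 0.1, 0.5, 0.3, 0.7))
  expect_setequal(as.character(perm$ordinal_label),
                  c("Very low", "Low", "Medium", "High", "Very high"))
  expect_error(assign_ordinal_labels(c(0.1, 0.2)),
               class = "sse_validation_error")
})

test_that("label assignment is scale-free", {
  scores <- c(0.21, 0.47, 0.38, 0.66, 0.71)
  a <- assign_ordinal_labels(scores)
  b <- assign_ordinal_labels(scores * 7.3)
  expect_identical(as.character(a$ordinal_label),
                   as.character(b$ordinal_label))
})

test_that("compare_with_reference flags matches and survey verifiability", {
  perfect <- assign_ordinal_labels(c(0.1, 0.5, 0.3, 0.7, 0.9))
  agree <- compare_with_reference(perfect)
  expect_equal(attr(agree, "n_model_match"), 5)
  expect_equal(attr(agree, "n_survey_match"), 4)
  expect_true(is.na(agree$survey_match[5]))
  expect_false(agree$survey_verifiable[5])
  # S2/S3 swapped: exactly two mismatches
  swapped <- assign_ordinal_labels(c(0.1, 0.3, 0.5, 0.7, 0.9))
  agree2 <- compare_with_reference(swapped)
  expect_equal(attr(agree2, "n_model_match"), 3)
  expect_equal(sum(!agree2$model_match), 2)
})

test_that("write_reports emits JSON and markdown deterministically", {
  dir <- withr::local_tempdir()
  agree <- compare_with_reference(
    assign_ordinal_labels(c(0.1, 0.5, 0.3, 0.7, 0.9))
  )
  files <- write_reports(agree, dir)
  expect_true(all(file.exists(files)))
  js <- jsonlite::read_json(file.path(dir, "validation.json"))
  expect_equal(length(js$scenarios), 5)
  expect_equal(js$n_model_match, 5)
  md <- readLines(file.path(dir, "validation.md"))
  expect_true(any(grepl("1.78", md, fixed = TRUE)))
  expect_true(any(grepl("0.797", md, fixed = TRUE)))
  expect_true(any(grepl("could not be verified by the survey", md)))
  # re-running overwrites identically
  before <- readLines(file.path(dir, "validation.md"))
  write_reports(agree, dir)
  expect_identical(readLines(file.path(dir, "validation.md")), before)
  # empty input errors before writing
  empty <- agree[0, ]
  class(empty) <- class(agree)
  expect_error(write_reports(empty, dir), class = "sse_validation_error")
})
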