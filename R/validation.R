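# Ordinal impact validation: scores ensembles on the safety-level scale,
# ranks the five scenarios onto a five-level ordinal scale, and compares the
# ranking with the stored survey reference constants.

.ordinal_levels <- c("Very low", "Low", "Medium", "High", "Very high")

#' Survey reference constants
#'
#' The stored per-scenario reference: the model's expected ordinal label, the
#' survey's ordinal label, and the survey item mean and standard deviation on
#' the 1-5 agreement scale. Scenario 5 has no survey value because departed
#' employees could not be surveyed.
#'
#' @return A tibble with columns `scenario_id`, `description`, `model_label`,
#'   `survey_label`, `survey_mean`, `survey_sd`.
#' @export
survey_reference <- function() {
  tibble::tibble(
    scenario_id = 1:5,
    description = c(
      "Average impact of employees taking no action",
      "Average impact of employees exposing safety occurrences",
      "Average impact of employees blowing the whistle on illegal production behavior",
      "Average impact of employees both exposing and blowing the whistle",
      "Average impact of employees adding turnover and demanding for a raise"
    ),
    model_label = c("Very low", "Medium", "Low", "High", "Very high"),
    survey_label = c("Very low", "Medium", "Low", "High", NA_character_),
    survey_mean = c(1.78, 2.48, 3.63, 4.04, NA_real_),
    survey_sd = c(0.797, 0.588, 0.615, 0.767, NA_real_)
  )
}

#' Ensemble impact score
#'
#' Scores an ensemble on the safety-level scale: within the late-horizon
#' window (the last `window_fraction` of periods), the active-population
#' -weighted mean safety level is computed per replicate, then averaged across
#' replicates. Periods with no active SSEs are excluded; it is an error if no
#' window period has an active SSE in some replicate.
#'
#' @param ensemble An `sse_ensemble` from [run_replicates()].
#' @param window_fraction Fraction of the horizon scored, default 0.25.
#' @return A single numeric score in (0, 1).
#' @export
impact_score <- function(ensemble, window_fraction = 0.25) {
  stopifnot(inherits(ensemble, "sse_ensemble"))
  if (window_fraction <= 0 || window_fraction > 1) {
    rlang::abort("window_fraction must lie in (0, 1]",
                 class = "sse_domain_error")
  }
  n_periods <- max(ensemble$by_period$period)
  start <- floor(n_periods * (1 - window_fraction)) + 1
  scores <- ensemble$by_period |>
    dplyr::filter(.data$period >= start, .data$n_active > 0) |>
    dplyr::group_by(.data$replicate) |>
    dplyr::summarise(score = sum(.data$sum_s_active) / sum(.data$n_active),
                     .groups = "drop")
  if (nrow(scores) < length(ensemble$seeds)) {
    rlang::abort("some replicates have no active SSEs in the scoring window",
                 class = "sse_validation_error")
  }
  mean(scores$score)
}

#' Map five scenario scores onto the ordinal impact scale
#'
#' Ranks the five scenarios by ascending score and assigns the labels
#' Very low, Low, Medium, High, Very high to ranks 1-5. Ties are broken by
#' scenario id (lower id receives the lower label).
#'
#' @param scores Numeric vector of five per-scenario impact scores, ordered by
#'   scenario id 1..5 (or named `"1"`..`"5"`).
#' @return A tibble with columns `scenario_id`, `impact_score`,
#'   `ordinal_label` (factor over the five levels).
#' @examples
#' assign_ordinal_labels(c(0.2, 0.5, 0.4, 0.7, 0.8))
#' @export
assign_ordinal_labels <- function(scores) {
  if (length(scores) != 5) {
    rlang::abort("exactly five per-scenario scores are required",
                 class = "sse_validation_error")
  }
  ranks <- rank(scores, ties.method = "first")  # ties: lower id, lower label
  tibble::tibble(
    scenario_id = 1:5,
    impact_score = as.numeric(scores),
    ordinal_label = factor(.ordinal_levels[ranks], levels = .ordinal_levels)
  )
}

#' Compare simulated ordinal labels with the reference columns
#'
#' Joins the simulated labels against the stored reference and flags, per
#' scenario, agreement with the model column and with the survey column.
#' Scenario 5 is marked survey-unverifiable (no survey value exists).
#'
#' @param labels Tibble from [assign_ordinal_labels()].
#' @param reference Reference tibble, default [survey_reference()].
#' @return An `sse_agreement` tibble adding `model_match`, `survey_match`
#'   (NA where unverifiable), `survey_mean`, `survey_sd`, plus attributes
#'   `n_model_match` and `n_survey_match`.
#' @export
compare_with_reference <- function(labels, reference = survey_reference()) {
  stopifnot(all(c("scenario_id", "ordinal_label") %in% names(labels)))
  out <- reference |>
    dplyr::left_join(
      labels |> dplyr::mutate(ordinal_label = as.character(.data$ordinal_label)),
      by = "scenario_id"
    ) |>
    dplyr::mutate(
      model_match = .data$ordinal_label == .data$model_label,
      survey_match = ifelse(is.na(.data$survey_label), NA,
                            .data$ordinal_label == .data$survey_label),
      survey_verifiable = !is.na(.data$survey_label)
    ) |>
    dplyr::select("scenario_id", "description", "impact_score",
                  "ordinal_label", "model_label", "survey_label",
                  "model_match", "survey_match", "survey_verifiable",
                  "survey_mean", "survey_sd")
  attr(out, "n_model_match") <- sum(out$model_match)
  attr(out, "n_survey_match") <- sum(out$survey_match, na.rm = TRUE)
  class(out) <- c("sse_agreement", class(out))
  out
}

#' Run the full five-scenario validation
#'
#' Runs a replicate ensemble for each scenario with a shared configuration and
#' seed ladder, scores them, assigns ordinal labels, and compares against the
#' reference.
#'
#' @param cfg An `sse_config`.
#' @param base_seed First seed; scenario k's ensemble uses seeds
#'   `base_seed + (k-1)*n_replicates + 0:(n_replicates-1)` so replicates are
#'   independent across scenarios.
#' @param window_fraction Scoring window fraction, default 0.25.
#' @return A list with `ensembles` (list of 5), `labels`, and `agreement`.
#' @export
validate_scenarios <- function(cfg, base_seed = cfg$rng_seed,
                               window_fraction = 0.25) {
  validate_config(cfg)
  ensembles <- purrr::map(1:5, function(k) {
    run_replicates(cfg, scenario_spec(k),
                   base_seed = base_seed + (k - 1) * cfg$n_replicates)
  })
  scores <- purrr::map_dbl(ensembles, impact_score,
                           window_fraction = window_fraction)
  labels <- assign_ordinal_labels(scores)
  agreement <- compare_with_reference(labels)
  list(ensembles = ensembles, labels = labels, agreement = agreement)
}

#' Write validation reports
#'
#' Writes `validation.json` (scores, labels, agreement flags) and
#' `validation.md` (a human-readable table mirroring the reference layout)
#' into `out_dir`.
#'
#' @param agreement An `sse_agreement` from [compare_with_reference()].
#' @param out_dir Output directory (created if missing).
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(agreement, out_dir) {
  stopifnot(inherits(agreement, "sse_agreement"))
  if (nrow(agreement) == 0) {
    rlang::abort("agreement report is empty; nothing to write",
                 class = "sse_validation_error")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  json_path <- file.path(out_dir, "validation.json")
  md_path <- file.path(out_dir, "validation.md")

  payload <- list(
    scenarios = agreement,
    n_model_match = attr(agreement, "n_model_match"),
    n_survey_match = attr(agreement, "n_survey_match"),
    note = "Scenario 5 could not be verified by the survey."
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)

  fmt <- function(x) ifelse(is.na(x), "-", format(x))
  lines <- c(
    "# Scenario validation",
    "",
    "| Simulated scenario | Model | Survey | Mean | SD | Simulated | Match |",
    "|---|---|---|---|---|---|---|",
    purrr::pmap_chr(agreement, function(scenario_id, description,
                                        impact_score, ordinal_label,
                                        model_label, survey_label,
                                        model_match, survey_match,
                                        survey_verifiable, survey_mean,
                                        survey_sd, ...) {
      sprintf("| Scenario %d: %s | %s | %s | %s | %s | %s (%.3f) | %s |",
              scenario_id, description, model_label, fmt(survey_label),
              fmt(survey_mean), fmt(survey_sd), ordinal_label, impact_score,
              if (isTRUE(model_match)) "yes" else "NO")
    }),
    "",
    sprintf("Model-column agreement: %d/5. Survey-column agreement: %d/4.",
            attr(agreement, "n_model_match"),
            attr(agreement, "n_survey_match")),
    "Scenario 5 could not be verified by the survey."
  )
  writeLines(lines, md_path)
  invisible(c(json_path, md_path))
}
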