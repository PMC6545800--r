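#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single simulation
#'
#' Returns the long per-period, per-SSE trajectory tibble.
#'
#' @param x An `sse_sim`.
#' @param ... Unused.
#' @return A tibble with one row per period x SSE.
#' @export
tidy.sse_sim <- function(x, ...) {
  x$trajectories
}

#' One-row summary of a simulation
#'
#' @param x An `sse_sim`.
#' @param ... Unused.
#' @return A tibble with the final census, exit count, and late profit.
#' @export
glance.sse_sim <- function(x, ...) {
  np <- max(x$trajectories$period)
  final <- dplyr::filter(x$trajectories, .data$period == np)
  counts <- dplyr::filter(x$class_counts, .data$period == np)
  tibble::tibble(
    scenario_id = x$scenario_id,
    n_periods = np,
    n_sse = x$config$n_sse,
    n_active = sum(final$active),
    n_exited = sum(!final$active),
    c1 = counts$count[counts$class == 1],
    c2 = counts$count[counts$class == 2],
    c3 = counts$count[counts$class == 3],
    c4 = counts$count[counts$class == 4],
    mean_safety = mean(final$s[final$active], na.rm = TRUE),
    mean_profit = mean(final$profit[final$active], na.rm = TRUE),
    seed = x$seed
  )
}

#' Tidy an ensemble
#'
#' @param x An `sse_ensemble`.
#' @param ... Unused.
#' @return The per-replicate, per-period summary tibble.
#' @export
tidy.sse_ensemble <- function(x, ...) {
  x$by_period
}

#' One-row summary of an ensemble
#'
#' @param x An `sse_ensemble`.
#' @param ... Unused.
#' @return A tibble with the late-horizon impact score and profit.
#' @export
glance.sse_ensemble <- function(x, ...) {
  np <- max(x$by_period$period)
  start <- floor(np * 0.75) + 1
  late <- dplyr::filter(x$by_period, .data$period >= start)
  tibble::tibble(
    scenario_id = x$scenario_id,
    n_replicates = length(x$seeds),
    n_periods = np,
    impact_score = impact_score(x),
    late_mean_profit = mean(late$mean_profit, na.rm = TRUE),
    mean_exited = mean(late$exited[late$period == np])
  )
}

#' Plot class-count trajectories of a simulation
#'
#' @param object An `sse_sim`.
#' @param ... Unused.
#' @return A ggplot of active-SSE counts per class over periods.
#' @export
autoplot.sse_sim <- function(object, ...) {
  ggplot2::ggplot(
    object$class_counts,
    ggplot2::aes(x = .data$period, y = .data$count,
                 colour = factor(.data$class,
                                 labels = paste0("c", 1:4)))
  ) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Period", y = "Active SSEs", colour = "Class",
      title = paste0("Safety-class evolution, scenario ",
                     object$scenario_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot across-replicate class-count means of an ensemble
#'
#' @param object An `sse_ensemble`.
#' @param ... Unused.
#' @return A ggplot with ribbons of +/- one standard error.
#' @export
autoplot.sse_ensemble <- function(object, ...) {
  long <- object$summary |>
    tidyr::pivot_longer(
      dplyr::matches("^c[1-4]_(mean|se)$"),
      names_to = c("class", "stat"), names_sep = "_"
    ) |>
    tidyr::pivot_wider(names_from = "stat", values_from = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$period, y = .data$mean,
                                     colour = .data$class,
                                     fill = .data$class)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$se,
                                      ymax = .data$mean + .data$se),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "Period", y = "Active SSEs (ensemble mean)",
      colour = "Class", fill = "Class",
      title = paste0("Ensemble class evolution, scenario ",
                     object$scenario_id)
    ) +
    ggplot2::theme_minimal()
}

#' Plot ensemble profit trajectories
#'
#' @param ensemble An `sse_ensemble`.
#' @return A ggplot of the across-replicate mean per-SSE profit by period.
#' @export
plot_profit <- function(ensemble) {
  stopifnot(inherits(ensemble, "sse_ensemble"))
  ggplot2::ggplot(ensemble$summary,
                  ggplot2::aes(x = .data$period,
                               y = .data$mean_profit_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_profit_mean - .data$mean_profit_se,
                   ymax = .data$mean_profit_mean + .data$mean_profit_se),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "Period", y = "Mean profit per active SSE",
                  title = paste0("Profit trajectory, scenario ",
                                 ensemble$scenario_id)) +
    ggplot2::theme_minimal()
}
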