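# broom-style accessors and ggplot2 plot methods for run objects.

#' Tidy a study run into its scenario risk table
#'
#' @param x An `rpra_run` from [run_study()].
#' @param ... Unused.
#' @return The per-scenario THQ summary tibble (mean, p50, p95, CV,
#'   exceedance probability, bootstrap SE of the p95).
#' @export
tidy.rpra_run <- function(x, ...) {
  tibble::as_tibble(x$scenario_summary)
}

#' One-row overview of a study run
#'
#' @param x An `rpra_run` from [run_study()].
#' @param ... Unused.
#' @return A one-row tibble: seed, iterations, scenario count, the highest-
#'   risk scenario with its p95 THQ, and how many scenarios exceed the
#'   threshold at the 95th percentile.
#' @export
glance.rpra_run <- function(x, ...) {
  s <- x$scenario_summary
  top <- which.max(s$p95)
  tibble::tibble(
    seed = x$config$seed,
    n_iterations = x$config$n_iterations,
    n_scenarios = nrow(s),
    top_scenario = s$scenario[top],
    top_p95 = s$p95[top],
    n_exceeding = sum(s$p95 > x$config$threshold)
  )
}

#' Plot scenario risk distributions
#'
#' Bar chart of the 95th-percentile total hazard quotient per scenario with
#' the mean overplotted and the safety threshold marked.
#'
#' @param object An `rpra_run` from [run_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rpra_run <- function(object, ...) {
  s <- object$scenario_summary
  s$scenario <- factor(s$scenario, levels = s$scenario[order(s$p95)])
  ggplot2::ggplot(s, ggplot2::aes(x = .data$scenario)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$p95), fill = "steelblue",
                      alpha = 0.8) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean), size = 2) +
    ggplot2::geom_hline(yintercept = object$config$threshold,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Total hazard quotient",
                  title = "Scenario risk: 95th percentile (bars) and mean (points)") +
    ggplot2::theme_minimal()
}

#' Plot a sensitivity ranking
#'
#' Tornado-style bar chart of signed correlation coefficients, faceted by
#' scenario when the table covers several.
#'
#' @param object An `rpra_sensitivity` tibble from [sensitivity_ranking()]
#'   or [study_sensitivity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rpra_sensitivity <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0(df$parameter, " (", df$rank, ")")
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$label, abs(.data$rho)),
    y = .data$rho, fill = .data$rho > 0
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL,
                  y = paste0("Correlation with THQ (",
                             attr(object, "method") %||% "spearman", ")")) +
    ggplot2::theme_minimal()
  if ("scenario" %in% names(df)) {
    p <- p + ggplot2::facet_wrap(~scenario, scales = "free_y")
  }
  p
}

#' Plot cumulative-probability risk curves
#'
#' Empirical cumulative distributions of the per-iteration hazard quotients
#' for selected scenario-route cells, with the safety threshold marked --
#' the standard way to read exceedance probabilities off a probabilistic
#' assessment.
#'
#' @param run An `rpra_run` from [run_study()].
#' @param scenarios,routes Optional filters (character vectors).
#' @return A ggplot object.
#' @export
plot_cumulative_probability <- function(run, scenarios = NULL, routes = NULL) {
  curves <- cumulative_probability(run$hq, by = c("scenario", "route"))
  if (!is.null(scenarios)) curves <- curves[curves$scenario %in% scenarios, ]
  if (!is.null(routes)) curves <- curves[curves$route %in% routes, ]
  if (!nrow(curves)) abort("no scenario/route cells left after filtering")
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$hq, y = .data$cum_prob,
                                       colour = paste(.data$scenario,
                                                      .data$route, sep = " / "))) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = run$config$threshold,
                        linetype = "dashed", colour = "grey40") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard quotient", y = "Cumulative probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
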