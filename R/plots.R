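# ggplot2 displays for each result type.

#' Plot a simulation trace
#'
#' One facet per unit, one line per signal (perception, reference, error,
#' output).
#'
#' @param object A `pct_trace` tibble.
#' @param signals Signals to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_trace
#' @export
autoplot.pct_trace <- function(object, signals = c("p", "r", "e", "qo"),
                               ...) {
  long <- object |>
    tidyr::pivot_longer(cols = dplyr::all_of(signals), names_to = "signal",
                        values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time_s, y = .data$value,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$unit), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL, colour = "signal")
}

#' Plot WMRSE trajectories of a conflict-reorganization experiment
#'
#' Per-agent trajectories (thin) and condition medians (thick).
#'
#' @param object A `pct_experiment`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_experiment
#' @export
autoplot.pct_experiment <- function(object, ...) {
  med <- object$trajectories |>
    dplyr::group_by(.data$condition, .data$window_start) |>
    dplyr::summarise(wmrse = stats::median(.data$wmrse), .groups = "drop")
  ggplot2::ggplot(object$trajectories,
                  ggplot2::aes(x = .data$window_start, y = .data$wmrse)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$agent), alpha = 0.2) +
    ggplot2::geom_line(data = med, colour = "firebrick", linewidth = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "iteration (window start)", y = "WMRSE")
}

#' Plot a simulated therapy cohort
#'
#' A sample of individual case trajectories with the cohort mean overlaid.
#'
#' @param object A `pct_cohort`.
#' @param n_cases Number of individual cases to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_cohort
#' @export
autoplot.pct_cohort <- function(object, n_cases = 30, ...) {
  long <- tidy(object)
  shown <- long |>
    dplyr::filter(.data$case %in% seq_len(min(n_cases, nrow(object$scores))))
  ggplot2::ggplot(shown, ggplot2::aes(x = .data$session, y = .data$score)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$case), alpha = 0.25) +
    ggplot2::geom_line(data = object$mean_trajectory,
                       ggplot2::aes(y = .data$mean_score), colour = "firebrick",
                       linewidth = 1.2) +
    ggplot2::labs(x = "session", y = "symptom score")
}

#' Plot the two-agent conflict episode
#'
#' @param object A `pct_two_agent`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_two_agent
#' @export
autoplot.pct_two_agent <- function(object, ...) {
  long <- object$trace |>
    tidyr::pivot_longer(cols = c("x_a", "x_b"), names_to = "agent",
                        values_to = "position")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$position,
                                     colour = .data$agent)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$goal_A, linetype = "dashed") +
    ggplot2::labs(title = paste("outcome:", object$outcome), x = "iteration",
                  y = "position")
}

#' Plot the approach-avoidance distance trace
#'
#' @param object A `pct_approach_avoidance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_approach_avoidance
#' @export
autoplot.pct_approach_avoidance <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step,
                                             y = .data$distance)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = c(object$r_approach, object$r_safe),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = object$virtual_reference,
                        colour = "firebrick", linetype = "dashed") +
    ggplot2::labs(x = "iteration", y = "distance")
}

#' Plot a tracking fit
#'
#' Observed cursor, fitted model cursor and the target.
#'
#' @param object A `pct_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pct_fit
#' @export
autoplot.pct_fit <- function(object, ...) {
  df <- tibble::tibble(
    step = object$data$step,
    target = object$data$target,
    observed = object$data$cursor,
    fitted = object$fitted
  ) |>
    tidyr::pivot_longer(-"step", names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$value,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "position", colour = NULL)
}
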