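# broom-style tidy()/glance() methods and print methods for result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted tracking model
#'
#' @param x A `pct_fit` from [fit_unit()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`, and
#'   `truth` when the data carry generator metadata.
#' @method tidy pct_fit
#' @export
tidy.pct_fit <- function(x, ...) {
  truth <- attr(x$data, "true_params")
  out <- tibble::tibble(term = names(x$estimates),
                        estimate = unname(x$estimates))
  if (!is.null(truth) && attr(x$data, "model_kind") == x$model_kind) {
    out$truth <- unname(truth[out$term])
  }
  out
}

#' One-row summary of a fitted tracking model
#'
#' @param x A `pct_fit`.
#' @param ... Unused.
#' @return A tibble with `rmse`, `correlation`, `model_kind`, `converged`,
#'   `n_evaluations`.
#' @method glance pct_fit
#' @export
glance.pct_fit <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, correlation = x$correlation,
                 model_kind = x$model_kind, converged = x$converged,
                 n_evaluations = x$n_evaluations)
}

#' Tidy a conflict-reorganization experiment
#'
#' @param x A `pct_experiment`.
#' @param ... Unused.
#' @return The per-agent, per-condition final-WMRSE tibble.
#' @method tidy pct_experiment
#' @export
tidy.pct_experiment <- function(x, ...) x$final

#' Condition medians of a conflict-reorganization experiment
#'
#' @param x A `pct_experiment`.
#' @param ... Unused.
#' @return The condition-median tibble with agent counts.
#' @method glance pct_experiment
#' @export
glance.pct_experiment <- function(x, ...) x$medians

#' Long per-case scores of a simulated therapy cohort
#'
#' @param x A `pct_cohort`.
#' @param ... Unused.
#' @return A tibble with columns `case`, `session`, `score`.
#' @method tidy pct_cohort
#' @export
tidy.pct_cohort <- function(x, ...) {
  tibble::tibble(
    case = rep(seq_len(nrow(x$scores)), ncol(x$scores)),
    session = rep(seq_len(ncol(x$scores)), each = nrow(x$scores)),
    score = as.vector(x$scores)
  )
}

#' One-row summary of a simulated therapy cohort
#'
#' @param x A `pct_cohort`.
#' @param ... Unused.
#' @return A tibble with cohort size, session count, baseline and final
#'   mean scores and the two change-pattern rates.
#' @method glance pct_cohort
#' @export
glance.pct_cohort <- function(x, ...) {
  tibble::tibble(
    n_cases = nrow(x$scores),
    n_sessions = ncol(x$scores),
    baseline_mean = mean(x$scores[, 1]),
    final_mean = mean(x$scores[, ncol(x$scores)]),
    early_response_rate = mean(x$flags$early_response),
    sudden_gain_rate = mean(x$flags$sudden_gain)
  )
}

#' @export
print.pct_fit <- function(x, ...) {
  cat(sprintf("<pct_fit: %s>\n", x$model_kind))
  cat(sprintf("  RMSE %.6g, correlation %.4f, %s\n", x$rmse, x$correlation,
              if (x$converged) "converged" else "not converged"))
  est <- paste(sprintf("%s=%.4g", names(x$estimates), x$estimates),
               collapse = ", ")
  cat("  estimates:", est, "\n")
  invisible(x)
}

#' @export
print.pct_experiment <- function(x, ...) {
  cat(sprintf("<pct_experiment: %d agents x %d conditions, %d iterations>\n",
              x$n_agents, length(x$conditions), x$iterations))
  print(x$medians)
  invisible(x)
}

#' @export
print.pct_cohort <- function(x, ...) {
  cat(sprintf("<pct_cohort: %d cases x %d sessions>\n",
              nrow(x$scores), ncol(x$scores)))
  print(glance(x))
  invisible(x)
}

#' @export
print.pct_two_agent <- function(x, ...) {
  cat(sprintf(
    "<pct_two_agent: gains %.2g/%.2g -> %s>\n  err_a=%.3g err_b=%.3g late_variance=%.3g\n",
    x$gain_A, x$gain_B, x$outcome, x$err_a, x$err_b, x$late_variance
  ))
  invisible(x)
}

#' @export
print.pct_approach_avoidance <- function(x, ...) {
  cat(sprintf(
    "<pct_approach_avoidance>\n  equilibrium %.4g (virtual reference %.4g); relative position %.3f\n",
    x$equilibrium, x$virtual_reference, x$relative_position
  ))
  invisible(x)
}

#' @export
print.pct_trajectory_summary <- function(x, ...) {
  cat("<pct_trajectory_summary>\n")
  print(x$fits[, c("model", "rmse")])
  cat(sprintf("  mean |change|: first sessions %.3f, last sessions %.3f%s\n",
              x$early_mean_abs_change, x$late_mean_abs_change,
              if (x$degenerate) " (degenerate: constant cohort)" else ""))
  invisible(x)
}
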