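# Session-level reorganization model of psychotherapy outcome trajectories.

#' Configure a simulated therapy cohort
#'
#' Each simulated case carries a symptom score on a bounded clinical scale
#' (default 0-40, as for the CORE-10 measure; higher = more distress). The
#' reference for symptoms is zero, so the current score is the error
#' signal. Between sessions the error tunes trial-and-error change: the
#' probability of a change and its magnitude both increase with the current
#' error, severity carries over from session to session, and no single step
#' is guaranteed to improve matters.
#'
#' @param n_cases Number of simulated cases (default 5613).
#' @param n_sessions Number of sessions recorded per case (>= 2).
#' @param baseline_mean,baseline_sd Mean and SD of the truncated-normal
#'   baseline severity sampler (truncated to `score_scale`). The defaults
#'   (20, 7) emulate a primary-care cohort with moderate average severity;
#'   the source cohort's severity distribution is not published, so this
#'   stands in as a synthetic severity distribution.
#' @param score_scale Closed interval of the score scale.
#' @param change_sd_coef Change magnitude is drawn from a zero-mean normal
#'   with SD `change_sd_coef * error` (error = current score).
#' @param biased_step If `TRUE`, change draws get a small downward mean
#'   `-bias_coef * error` (explicitly helpful exploration); the default
#'   `FALSE` variant is unbiased, improvement emerging only from the error
#'   tuning of change.
#' @param bias_coef See `biased_step`.
#' @param rng_seed Integer seed.
#' @return A list of class `pct_cohort_config`.
#' @export
cohort_config <- function(n_cases = 5613, n_sessions = 26,
                          baseline_mean = 20, baseline_sd = 7,
                          score_scale = c(0, 40), change_sd_coef = 0.5,
                          biased_step = FALSE, bias_coef = 0.1,
                          rng_seed = 1) {
  n_cases <- check_scalar(n_cases, "n_cases")
  n_sessions <- check_scalar(n_sessions, "n_sessions")
  if (n_cases < 1) abort_config("`n_cases` must be >= 1.")
  if (n_sessions < 2) abort_config("`n_sessions` must be >= 2.")
  if (length(score_scale) != 2 || score_scale[1] >= score_scale[2]) {
    abort_config("`score_scale` must be c(lo, hi) with lo < hi.")
  }
  if (baseline_sd < 0) abort_config("`baseline_sd` must be >= 0.")
  if (change_sd_coef < 0) abort_config("`change_sd_coef` must be >= 0.")
  structure(
    list(n_cases = as.integer(n_cases), n_sessions = as.integer(n_sessions),
         baseline_mean = check_scalar(baseline_mean, "baseline_mean"),
         baseline_sd = check_scalar(baseline_sd, "baseline_sd"),
         score_scale = as.numeric(score_scale),
         change_sd_coef = check_scalar(change_sd_coef, "change_sd_coef"),
         biased_step = isTRUE(biased_step),
         bias_coef = check_scalar(bias_coef, "bias_coef"),
         rng_seed = rng_seed),
    class = "pct_cohort_config"
  )
}

# Truncated-normal sampler via inverse-CDF on the truncated quantile range.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(clip(mean, lo, hi), n))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Simulate a therapy-outcome cohort by session-level reorganization
#'
#' For each case a baseline severity is drawn; at each subsequent session a
#' random change in the case's state occurs with probability
#' `min(1, error / scale_max)` and, when it occurs, moves the score by a
#' draw from `Normal(0, change_sd_coef * error)` (optionally with a small
#' downward bias, see [cohort_config()]). Scores are clipped to the scale.
#' Because large errors both invite change and produce large moves - and
#' near-zero error produces quiescence - cohort mean severity falls along a
#' negatively decelerating curve, with abrupt stable drops (sudden gains)
#' in individual cases.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pct_cohort`: `scores` (matrix, cases x
#'   sessions), `mean_trajectory` (tibble: session, mean_score), `flags`
#'   (tibble: case, early_response, sudden_gain) and `config`. Use
#'   [generics::tidy()] for a long per-case tibble.
#' @examples
#' res <- simulate_therapy_cohort(cohort_config(n_cases = 200,
#'                                              rng_seed = 7))
#' res$mean_trajectory
#' @export
simulate_therapy_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "pct_cohort_config"))
  lo <- config$score_scale[1]; hi <- config$score_scale[2]
  scores <- with_seed(config$rng_seed, {
    m <- matrix(0, config$n_cases, config$n_sessions)
    m[, 1] <- rtruncnorm(config$n_cases, config$baseline_mean,
                         config$baseline_sd, lo, hi)
    for (s in seq_len(config$n_sessions)[-1]) {
      err <- m[, s - 1] - lo  # reference for symptoms is the scale floor
      changes <- stats::runif(config$n_cases) < pmin(1, err / (hi - lo))
      mu <- if (config$biased_step) -config$bias_coef * err else 0
      delta <- stats::rnorm(config$n_cases, mu, config$change_sd_coef * err)
      m[, s] <- clip(m[, s - 1] + delta * changes, lo, hi)
    }
    m
  })
  mean_traj <- tibble::tibble(
    session = seq_len(config$n_sessions),
    mean_score = colMeans(scores)
  )
  flags <- tibble::tibble(
    case = seq_len(config$n_cases),
    early_response = apply(scores, 1, detect_early_response),
    sudden_gain = apply(scores, 1,
                        function(x) length(detect_sudden_gains(x)) > 0)
  )
  structure(
    list(scores = scores, mean_trajectory = mean_traj, flags = flags,
         config = config),
    class = "pct_cohort"
  )
}

#' Summarize cohort change trajectories
#'
#' Reports the cohort mean trajectory, the per-session mean absolute
#' change, and a comparison of an exponential-decay fit
#' (`a * exp(-b (t-1)) + c`, fitted by profiling the rate over a grid with
#' the linear coefficients solved exactly) against a straight-line fit of
#' the mean curve, each summarized by its RMSE. A negatively decelerating
#' cohort yields a smaller exponential RMSE and early mean changes larger
#' than late ones.
#'
#' @param result A `pct_cohort` from [simulate_therapy_cohort()], or a
#'   cases-x-sessions score matrix.
#' @return A list of class `pct_trajectory_summary`: `mean_trajectory`,
#'   `session_change` (tibble: session, mean_abs_change),
#'   `fits` (tibble: model, rmse, parameters), `early_mean_abs_change`,
#'   `late_mean_abs_change` (means over the first and last 3 transitions),
#'   `degenerate` (TRUE when the mean curve is constant).
#' @export
summarize_trajectories <- function(result) {
  scores <- if (inherits(result, "pct_cohort")) result$scores else as.matrix(result)
  if (ncol(scores) < 2) abort_config("need at least 2 sessions.")
  y <- colMeans(scores)
  t <- seq_along(y)
  n_tr <- length(y) - 1
  abs_change <- colMeans(abs(scores[, -1, drop = FALSE] -
                               scores[, -ncol(scores), drop = FALSE]))
  k <- min(3, n_tr)
  degenerate <- stats::sd(y) == 0

  lin <- stats::lm.fit(cbind(1, t), y)
  lin_rmse <- sqrt(mean(lin$residuals^2))

  if (degenerate) {
    exp_rmse <- 0
    exp_par <- c(a = 0, b = 0, c = y[1])
    lin_rmse <- 0
  } else {
    rmse_at <- function(b) {
      fit <- stats::lm.fit(cbind(1, exp(-b * (t - 1))), y)
      list(rmse = sqrt(mean(fit$residuals^2)), cf = fit$coefficients)
    }
    rates <- exp(seq(log(1e-3), log(2), length.out = 100))
    grid_rmse <- vapply(rates, function(b) rmse_at(b)$rmse, numeric(1))
    b0 <- rates[which.min(grid_rmse)]
    # profile the decay rate: refine around the best grid point
    opt <- stats::optimize(function(lb) rmse_at(exp(lb))$rmse,
                           log(b0) + c(-0.25, 0.25), tol = 1e-10)
    b_hat <- exp(opt$minimum)
    best <- rmse_at(b_hat)
    exp_rmse <- best$rmse
    exp_par <- c(a = unname(best$cf[2]), b = b_hat, c = unname(best$cf[1]))
  }
  structure(
    list(
      mean_trajectory = tibble::tibble(session = t, mean_score = y),
      session_change = tibble::tibble(session = seq_len(n_tr) + 1L,
                                      mean_abs_change = abs_change),
      fits = tibble::tibble(
        model = c("exponential_decay", "linear"),
        rmse = c(exp_rmse, lin_rmse),
        parameters = list(exp_par, c(intercept = unname(lin$coefficients[1]),
                                     slope = unname(lin$coefficients[2])))
      ),
      early_mean_abs_change = mean(abs_change[seq_len(k)]),
      late_mean_abs_change = mean(abs_change[seq.int(n_tr - k + 1, n_tr)]),
      degenerate = degenerate
    ),
    class = "pct_trajectory_summary"
  )
}

#' Detect sudden gains in a session-by-session score series
#'
#' Session `t` is flagged when the score drops by at least
#' `drop_threshold` between sessions `t` and `t + 1` and the mean score
#' over the following `stability_window` sessions does not rebound above
#' `score[t] - drop_threshold / 2`.
#'
#' @param series Numeric score series (one case).
#' @param drop_threshold Minimum between-session drop (default 6 scale
#'   points, a reliable-change-sized drop on a 0-40 scale).
#' @param stability_window Number of post-gain sessions that must hold the
#'   gain.
#' @return Integer vector of gain sessions (possibly empty). Series shorter
#'   than `stability_window + 2` give an empty result with a warning.
#' @examples
#' detect_sudden_gains(c(30, 29, 28, 27, 17, 16, 16, 15))
#' @export
detect_sudden_gains <- function(series, drop_threshold = 6,
                                stability_window = 2) {
  n <- length(series)
  if (n < stability_window + 2) {
    rlang::warn("series too short for sudden-gain detection; returning none.")
    return(integer())
  }
  gains <- integer()
  for (t in seq_len(n - 1 - stability_window)) {
    if (series[t + 1] <= series[t] - drop_threshold) {
      post <- mean(series[t + 1 + seq_len(stability_window)])
      if (post <= series[t] - drop_threshold / 2) {
        gains <- c(gains, t)
      }
    }
  }
  gains
}

#' Detect an early response in a score series
#'
#' Flags a case whose score has dropped from baseline by at least
#' `min_drop` points by session `by_session`.
#'
#' @param series Numeric score series (one case).
#' @param min_drop Minimum improvement from baseline (default 6 points).
#' @param by_session Session by which the drop must have occurred.
#' @return `TRUE` or `FALSE`.
#' @export
detect_early_response <- function(series, min_drop = 6, by_session = 3) {
  k <- min(by_session, length(series))
  (series[1] - min(series[seq_len(k)])) >= min_drop
}
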