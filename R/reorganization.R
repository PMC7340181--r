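#' Configure trial-and-error reorganization
#'
#' Reorganization is the stochastic learning process that perturbs
#' designated connection strengths while control is poor. Windowed squared
#' error is compared between consecutive windows: when error increased, a
#' new random direction is drawn and the step size is set proportional to
#' the increase ("tumble"); when error decreased or held, the previous
#' direction and step size are kept ("run") - the bacterial chemotaxis
#' scheme. When current window error falls at or below `error_tolerance`,
#' parameters are left untouched.
#'
#' @param window Window length in iterations over which error is
#'   accumulated; one reorganization decision is taken per window.
#' @param step_coefficient Positive scalar mapping the increase in windowed
#'   squared error to the perturbation step size.
#' @param target_set Which parameters may change: `"none"`,
#'   `"mid_level_weights"` (reference weights out of the level below the
#'   top), `"top_level_weights"` (reference weights out of the top level),
#'   or `"mid_level_gains"` (output gains of the level below the top).
#' @param error_tolerance Windowed squared error at or below which the
#'   system is quiescent (no parameter change).
#' @param bound Perturbed parameters are clipped to `[-bound, bound]`;
#'   clipping is flagged in the event log.
#' @param max_step Upper bound on the step size: a single error spike
#'   cannot fling the parameters arbitrarily far (`Inf` disables the cap,
#'   recovering strict proportionality for all error increases).
#' @param rng_seed Optional seed applied by [run_with_reorg()].
#' @return A list of class `pct_reorg_config`.
#' @export
reorg_config <- function(window = 100, step_coefficient = 0.01,
                         target_set = c("none", "mid_level_weights",
                                        "top_level_weights",
                                        "mid_level_gains"),
                         error_tolerance = 0, bound = 100, max_step = Inf,
                         rng_seed = NULL) {
  target_set <- match.arg(target_set)
  window <- check_scalar(window, "window")
  if (window < 1 || window != round(window)) {
    abort_config("`window` must be a positive integer.")
  }
  step_coefficient <- check_scalar(step_coefficient, "step_coefficient")
  if (step_coefficient <= 0) abort_config("`step_coefficient` must be > 0.")
  error_tolerance <- check_scalar(error_tolerance, "error_tolerance")
  if (error_tolerance < 0) abort_config("`error_tolerance` must be >= 0.")
  structure(
    list(window = as.integer(window), step_coefficient = step_coefficient,
         target_set = target_set, error_tolerance = error_tolerance,
         bound = check_scalar(bound, "bound"),
         max_step = check_scalar(max_step, "max_step", finite = FALSE),
         rng_seed = rng_seed),
    class = "pct_reorg_config"
  )
}

# Access / replace the targeted parameter vector of a network.
reorg_target_get <- function(net, target_set) {
  L <- length(net$levels)
  switch(target_set,
    none = numeric(),
    top_level_weights = as.numeric(net$ref_w[[L - 1]]),
    mid_level_weights = {
      if (L < 3) abort_config("mid_level_weights requires >= 3 levels.")
      as.numeric(net$ref_w[[L - 2]])
    },
    mid_level_gains = net$levels[[L - 1]]$ko
  )
}

reorg_target_set <- function(net, target_set, value) {
  L <- length(net$levels)
  switch(target_set,
    none = net,
    top_level_weights = {
      net$ref_w[[L - 1]][] <- value
      net
    },
    mid_level_weights = {
      net$ref_w[[L - 2]][] <- value
      net
    },
    mid_level_gains = {
      net$levels[[L - 1]]$ko <- value
      net
    }
  )
}

#' Apply one reorganization decision
#'
#' Compares the current window error with the previous one and perturbs the
#' targeted parameters accordingly (see [reorg_config()]). Uses the current
#' RNG stream; seed it (or use [run_with_reorg()]) for reproducibility.
#'
#' @param net A [network_spec()].
#' @param reorg A [reorg_config()].
#' @param state Internal reorganization state from the previous call, or
#'   `NULL` at the first decision.
#' @param current_window_error Non-negative scalar: total squared error over
#'   the window that just elapsed.
#' @return A list with elements `net` (possibly perturbed), `state`, and
#'   `event` (a one-row record: `delta_error`, `tumbled`, `step_size`,
#'   `clipped`).
#' @export
reorg_step <- function(net, reorg, state = NULL, current_window_error) {
  current_window_error <- check_scalar(current_window_error,
                                       "current_window_error")
  if (current_window_error < 0) {
    abort_config("`current_window_error` must be >= 0.")
  }
  k <- length(reorg_target_get(net, reorg$target_set))
  if (is.null(state)) {
    state <- list(previous_window_error = 0, direction = numeric(k),
                  step_size = 0)
  }
  dE <- current_window_error - state$previous_window_error
  tumbled <- FALSE
  clipped <- FALSE
  if (reorg$target_set != "none" && k > 0 &&
      current_window_error > reorg$error_tolerance) {
    if (dE > 0) {
      v <- stats::rnorm(k)
      state$direction <- v / sqrt(sum(v^2))
      state$step_size <- min(reorg$step_coefficient * dE, reorg$max_step)
      tumbled <- TRUE
    }
    if (state$step_size > 0) {
      theta <- reorg_target_get(net, reorg$target_set) +
        state$step_size * state$direction
      theta_c <- clip(theta, -reorg$bound, reorg$bound)
      clipped <- any(theta_c != theta)
      net <- reorg_target_set(net, reorg$target_set, theta_c)
    }
  }
  state$previous_window_error <- current_window_error
  list(
    net = net, state = state,
    event = list(delta_error = dE, tumbled = tumbled,
                 step_size = state$step_size, clipped = clipped)
  )
}

#' Simulate a network while reorganizing
#'
#' Runs [propagate()] dynamics with one reorganization decision per
#' `reorg$window` iterations, applied between windows.
#'
#' @inheritParams propagate
#' @param reorg A [reorg_config()].
#' @param seed Seed for the reorganization draws; falls back to
#'   `reorg$rng_seed`.
#' @return A list of class `pct_reorg_run`: `trace` (a `pct_trace`),
#'   `net` (the final, possibly reorganized network), and `events` (tibble
#'   with one row per reorganization decision: `step`, `delta_error`,
#'   `tumbled`, `step_size`, `clipped`).
#' @export
run_with_reorg <- function(net, env = loop_environment(), n_iterations = 5000,
                           reorg = reorg_config(), dt = 0.016,
                           seed = reorg$rng_seed) {
  sim <- with_seed(seed, simulate_network(net, env, n_iterations, dt, reorg))
  structure(
    list(trace = engine_trace(sim), net = sim$net, events = sim$events),
    class = "pct_reorg_run"
  )
}

#' Windowed mean root squared error (WMRSE)
#'
#' The control-quality metric: squared error terms across all control units
#' are averaged over `window` iteration cycles, and the square root of this
#' figure is taken. Computed on a sliding window (stride 1) by default; set
#' `stride = window` for non-overlapping windows.
#'
#' @param trace A `pct_trace` tibble (any number of units).
#' @param window Window length in iterations (default 10).
#' @param stride Step between successive window starts.
#' @return A tibble with columns `window_start` and `wmrse`.
#' @export
wmrse <- function(trace, window = 10, stride = 1) {
  emat <- trace_error_matrix(trace)
  wmrse_matrix(emat, window, stride)
}

# steps x units error matrix from a tidy trace
trace_error_matrix <- function(trace) {
  units <- unique(trace$unit)
  n <- max(trace$step)
  m <- matrix(NA_real_, n, length(units), dimnames = list(NULL, units))
  for (u in seq_along(units)) {
    rows <- trace$unit == units[u]
    m[trace$step[rows], u] <- trace$e[rows]
  }
  m
}

wmrse_matrix <- function(emat, window = 10, stride = 1) {
  n <- nrow(emat)
  window <- as.integer(window)
  if (is.na(window) || window < 1 || window > n) {
    abort_config("`window` must be a positive integer no longer than the trace.")
  }
  msq <- rowMeans(emat^2)
  run_mean <- stats::filter(msq, rep(1 / window, window), sides = 1)
  starts <- seq.int(1L, n - window + 1L, by = stride)
  tibble::tibble(
    window_start = starts,
    wmrse = sqrt(as.numeric(run_mean[starts + window - 1L]))
  )
}
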