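# Control-model fitting to tracking trajectories, with synthetic data
# generation for parameter-recovery studies.

# Simulate a tracking model against a target series.
# one_level_position: the cursor position is the (leaky, amplified) output
#   of a proximity controller.
# two_level_velocity: a proximity controller sets the reference for a
#   velocity controller whose output is integrated into cursor position.
simulate_tracking <- function(params, target, model_kind) {
  n <- length(target)
  x <- numeric(n)
  delay <- as.integer(params[["delay"]])
  if (model_kind == "one_level_position") {
    gain <- params[["gain"]]; slow <- params[["slowing"]]
    qo <- 0; xp <- 0
    for (t in seq_len(n)) {
      xlag <- if (t - 1 - delay >= 1) x[t - 1 - delay] else 0
      e <- target[t] - xlag
      qo <- qo + (gain * e - qo) / slow
      x[t] <- qo
      if (!is.finite(qo) || abs(qo) > .instability_limit) {
        abort_instability(t, "tracking model")
      }
    }
  } else {
    gp <- params[["gain_p"]]; sp <- params[["slowing_p"]]
    gv <- params[["gain_v"]]; sv <- params[["slowing_v"]]
    rv <- 0; qv <- 0; v <- 0; pos <- 0
    for (t in seq_len(n)) {
      xlag <- if (t - 1 - delay >= 1) x[t - 1 - delay] else 0
      ep <- target[t] - xlag           # proximity error
      rv <- rv + (gp * ep - rv) / sp   # sets velocity reference
      ev <- rv - v
      qv <- qv + (gv * ev - qv) / sv
      v <- qv
      pos <- pos + v
      x[t] <- pos
      if (!is.finite(pos) || abs(pos) > .instability_limit) {
        abort_instability(t, "tracking model")
      }
    }
  }
  x
}

default_true_params <- function(model_kind) {
  if (model_kind == "one_level_position") {
    c(gain = 4, slowing = 8, delay = 2)
  } else {
    c(gain_p = 0.5, slowing_p = 3, gain_v = 3, slowing_v = 3,
      delay = 2)
  }
}

#' Generate a synthetic tracking dataset from a known control model
#'
#' Simulates a known controller tracking a moving target and adds optional
#' observation noise to the simulated cursor; the ground-truth parameters
#' are stored so fits can be scored for parameter recovery.
#'
#' @param true_params Named numeric vector of generator parameters:
#'   `gain`, `slowing`, `delay` for `"one_level_position"`; `gain_p`,
#'   `slowing_p`, `gain_v`, `slowing_v`, `delay` for
#'   `"two_level_velocity"`. `NULL` uses documented defaults.
#' @param model_kind `"one_level_position"` or `"two_level_velocity"`.
#' @param target_kind `"sinusoid"` (predictable) or `"pseudorandom"`
#'   (smoothed noise, less predictable).
#' @param noise_sd SD of Gaussian observation noise added to the cursor.
#' @param n Series length (>= 100).
#' @param amplitude,period Target parameters.
#' @param seed RNG seed (target noise and observation noise).
#' @return A tibble of class `pct_tracking` with columns `step`, `target`,
#'   `cursor`, and attributes `true_params`, `model_kind`, `noise_sd`,
#'   `seed`.
#' @export
generate_tracking_data <- function(true_params = NULL,
                                   model_kind = c("one_level_position",
                                                  "two_level_velocity"),
                                   target_kind = c("sinusoid",
                                                   "pseudorandom"),
                                   noise_sd = 0, n = 800, amplitude = 10,
                                   period = 200, seed = 1) {
  model_kind <- match.arg(model_kind)
  target_kind <- match.arg(target_kind)
  n <- as.integer(n)
  if (n < 100) abort_config("`n` must be >= 100.")
  if (is.null(true_params)) true_params <- default_true_params(model_kind)
  seeds <- derive_seeds(seed, 2)
  target <- switch(target_kind,
    sinusoid = generate_disturbance("sinusoid", n, amplitude = amplitude,
                                    period = period),
    pseudorandom = generate_disturbance("pseudorandom", n,
                                        amplitude = amplitude, smooth = 20,
                                        seed = seeds[1])
  )
  cursor <- simulate_tracking(true_params, target, model_kind)
  if (noise_sd > 0) {
    cursor <- cursor + with_seed(seeds[2], stats::rnorm(n, 0, noise_sd))
  }
  out <- tibble::tibble(step = seq_len(n), target = target, cursor = cursor)
  class(out) <- c("pct_tracking", class(out))
  attr(out, "true_params") <- true_params
  attr(out, "model_kind") <- model_kind
  attr(out, "noise_sd") <- noise_sd
  attr(out, "seed") <- seed
  out
}

# RMSE objective for a candidate parameter vector (continuous part) at a
# fixed integer delay; instability maps to a large finite penalty so the
# simplex can retreat.
tracking_objective <- function(theta, target, cursor, model_kind, delay) {
  params <- untransform_params(theta, model_kind)
  params[["delay"]] <- delay
  sim <- tryCatch(simulate_tracking(params, target, model_kind),
                  pctsim_instability_error = function(e) NULL)
  if (is.null(sim)) return(1e6)
  sqrt(mean((sim - cursor)^2))
}

# Continuous parameters are optimized on log scales (gains > 0,
# slowing >= 1 via log(slowing - 1 + eps)).
transform_params <- function(params, model_kind) {
  if (model_kind == "one_level_position") {
    c(log(params[["gain"]]), log(params[["slowing"]] - 1 + 1e-6))
  } else {
    c(log(params[["gain_p"]]), log(params[["slowing_p"]] - 1 + 1e-6),
      log(params[["gain_v"]]), log(params[["slowing_v"]] - 1 + 1e-6))
  }
}

untransform_params <- function(theta, model_kind) {
  if (model_kind == "one_level_position") {
    c(gain = exp(theta[1]), slowing = 1 - 1e-6 + exp(theta[2]))
  } else {
    c(gain_p = exp(theta[1]), slowing_p = 1 - 1e-6 + exp(theta[2]),
      gain_v = exp(theta[3]), slowing_v = 1 - 1e-6 + exp(theta[4]))
  }
}

#' Fit a control model to tracking data
#'
#' Minimizes the RMSE between the simulated and observed cursor over the
#' model's continuous parameters (gain and slowing per level, on log
#' scales) by Nelder-Mead simplex search with deterministic multistarts,
#' with the whole-iteration transport delay fitted over a small integer
#' grid. The objective is simulation-defined and non-smooth in the delay,
#' hence the derivative-free strategy.
#'
#' @param data A `pct_tracking` tibble (or any tibble with `target` and
#'   `cursor` columns).
#' @param model_kind `"one_level_position"` or `"two_level_velocity"`.
#' @param n_multistart Number of random starting points per delay value.
#' @param max_delay Largest delay considered (grid `0:max_delay`).
#' @param seed Seed for the multistart draws (fit is deterministic given
#'   data and seed).
#' @return A list of class `pct_fit`: `estimates` (named vector),
#'   `rmse`, `correlation` (model vs observed cursor), `model_kind`,
#'   `converged`, `n_evaluations`, `fitted` (simulated cursor under the
#'   estimates) and `data`.
#' @seealso [generics::tidy()] and [generics::glance()] methods.
#' @export
fit_unit <- function(data, model_kind = c("one_level_position",
                                          "two_level_velocity"),
                     n_multistart = 8, max_delay = 4, seed = 42) {
  model_kind <- match.arg(model_kind)
  target <- data$target
  cursor <- data$cursor
  if (length(target) != length(cursor) || anyNA(target) || anyNA(cursor)) {
    abort_config("`data` must hold equal-length, complete target/cursor series.")
  }
  k <- if (model_kind == "one_level_position") 2L else 4L
  starts <- with_seed(seed, matrix(stats::runif(n_multistart * k, -1.5, 2),
                                   n_multistart, k))
  best <- NULL
  n_eval <- 0L
  any_converged <- FALSE
  for (delay in 0:max_delay) {
    for (s in seq_len(n_multistart)) {
      opt <- stats::optim(starts[s, ], tracking_objective, target = target,
                          cursor = cursor, model_kind = model_kind,
                          delay = delay, method = "Nelder-Mead",
                          control = list(maxit = 400, reltol = 1e-10))
      n_eval <- n_eval + opt$counts[1]
      if (opt$convergence == 0) any_converged <- TRUE
      if (is.null(best) || opt$value < best$value) {
        best <- list(value = opt$value, par = opt$par, delay = delay)
      }
    }
  }
  est <- untransform_params(best$par, model_kind)
  est[["delay"]] <- best$delay
  params <- est
  fitted <- simulate_tracking(params, target, model_kind)
  corr <- if (stats::sd(fitted) > 0 && stats::sd(cursor) > 0) {
    stats::cor(fitted, cursor)
  } else {
    NA_real_
  }
  structure(
    list(estimates = est, rmse = best$value, correlation = corr,
         model_kind = model_kind, converged = any_converged,
         n_evaluations = as.integer(n_eval), fitted = fitted, data = data),
    class = "pct_fit"
  )
}
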