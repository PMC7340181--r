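#' Define the parameters of a single negative-feedback control unit
#'
#' A control unit perceives an environmental input quantity through an input
#' gain, compares the perception against a reference value, and converts the
#' error into an output quantity through an amplifying, slowed ("leaky
#' integrator") output function. The discrete update used throughout the
#' package is, per iteration:
#'
#' \deqn{p_t = K_i \, Q_{i,t-1-d}, \quad e_t = r - p_t, \quad
#'       Q_{o,t} = Q_{o,t-1} + \frac{1}{S}\,(K_o e_t - Q_{o,t-1})}
#'
#' after which the environment closes the loop with
#' \eqn{Q_{i,t} = K_f Q_{o,t} + D_t}.
#'
#' @param input_gain Input function gain \eqn{K_i} mapping the environmental
#'   quantity into the perceptual signal.
#' @param output_gain Output function gain \eqn{K_o} (error amplification).
#' @param slowing Leaky-integrator time constant \eqn{S} in iterations;
#'   must be >= 1. Larger values slow the output response. The discrete
#'   update is stable only when \eqn{S > (1 + K_i K_f K_o)/2}; divergent
#'   loops raise an instability error naming the step.
#' @param transport_delay Whole-iteration transport delay (>= 0) applied on
#'   the perceptual path: the unit perceives the input quantity as it was
#'   `transport_delay` iterations earlier. For loop dynamics a pure delay is
#'   equivalent wherever it is placed along the loop.
#' @param reference Reference value \eqn{r} for the perception. In a
#'   hierarchy this is overwritten each step by higher-level outputs.
#' @return An object of class `pct_unit`.
#' @examples
#' u <- control_unit(output_gain = 10, slowing = 20, reference = 5)
#' analytic_steady_state(u, loop_environment())
#' @export
control_unit <- function(input_gain = 1, output_gain = 10, slowing = 20,
                         transport_delay = 0, reference = 0) {
  slowing <- check_scalar(slowing, "slowing")
  if (slowing < 1) abort_config("`slowing` must be >= 1 iteration.")
  transport_delay <- check_scalar(transport_delay, "transport_delay")
  if (transport_delay < 0 || transport_delay != round(transport_delay)) {
    abort_config("`transport_delay` must be a non-negative integer.")
  }
  structure(
    list(
      input_gain = check_scalar(input_gain, "input_gain"),
      output_gain = check_scalar(output_gain, "output_gain"),
      slowing = slowing,
      transport_delay = as.integer(transport_delay),
      reference = check_scalar(reference, "reference")
    ),
    class = "pct_unit"
  )
}

#' Define the environmental side of a control loop
#'
#' The environment feeds the unit's output back into its input quantity
#' through a feedback gain \eqn{K_f} and adds a disturbance series \eqn{D}:
#' \eqn{Q_{i,t} = K_f Q_{o,t} + D_t}.
#'
#' @param feedback_gain Feedback function gain \eqn{K_f}.
#' @param disturbance Disturbance \eqn{D}: a single number (held constant) or
#'   a numeric vector giving the value at every iteration (see
#'   [generate_disturbance()]).
#' @param init_input Initial value of the input quantity \eqn{Q_i}.
#' @return An object of class `pct_env`.
#' @export
loop_environment <- function(feedback_gain = 1, disturbance = 0,
                             init_input = 0) {
  if (!is.numeric(disturbance) || anyNA(disturbance) ||
      !all(is.finite(disturbance))) {
    abort_config("`disturbance` must be finite numeric values.")
  }
  structure(
    list(
      feedback_gain = check_scalar(feedback_gain, "feedback_gain"),
      disturbance = as.numeric(disturbance),
      init_input = check_scalar(init_input, "init_input")
    ),
    class = "pct_env"
  )
}

# Expand a disturbance spec to length n (scalars are recycled).
disturbance_series <- function(disturbance, n) {
  if (length(disturbance) == 1) return(rep(disturbance, n))
  if (length(disturbance) < n) {
    abort_config(sprintf(
      "disturbance series has length %d but %d iterations were requested.",
      length(disturbance), n
    ))
  }
  disturbance[seq_len(n)]
}

#' Initial state of a control unit
#'
#' @param p,e,qo,qi Initial perception, error, output quantity and input
#'   quantity. Defaults are all zero.
#' @param qi_lag Numeric vector of earlier input-quantity values used when
#'   `transport_delay > 0` (most recent first); defaults to zeros.
#' @return A list of class `pct_state`.
#' @export
unit_state <- function(p = 0, e = 0, qo = 0, qi = 0, qi_lag = numeric()) {
  structure(
    list(p = p, e = e, qo = qo, qi = qi, qi_lag = as.numeric(qi_lag)),
    class = "pct_state"
  )
}

#' Advance a single control loop by exactly one iteration
#'
#' Applies the discrete update documented in [control_unit()]: perceive,
#' compare, output, then let the environment update the input quantity.
#'
#' @param unit A [control_unit()].
#' @param env A [loop_environment()].
#' @param state A [unit_state()]; the state before this iteration.
#' @param disturbance_value Disturbance value for this iteration. Defaults to
#'   the first element of `env$disturbance`.
#' @param step Iteration index, used only in instability diagnostics.
#' @return The next `pct_state`.
#' @export
step_unit <- function(unit, env, state = unit_state(qi = env$init_input),
                      disturbance_value = env$disturbance[1], step = 1L) {
  d <- unit$transport_delay
  if (d > 0 && length(state$qi_lag) < d) {
    state$qi_lag <- c(state$qi_lag, rep(0, d - length(state$qi_lag)))
  }
  src <- if (d == 0) state$qi else state$qi_lag[d]
  p <- unit$input_gain * src
  e <- unit$reference - p
  qo <- state$qo + (unit$output_gain * e - state$qo) / unit$slowing
  qi <- env$feedback_gain * qo + disturbance_value
  vals <- c(p, e, qo, qi)
  if (anyNA(vals) || !all(is.finite(vals)) || max(abs(vals)) > .instability_limit) {
    abort_instability(step, "unit1")
  }
  qi_lag <- if (d > 0) c(state$qi, state$qi_lag)[seq_len(d)] else numeric()
  unit_state(p = p, e = e, qo = qo, qi = qi, qi_lag = qi_lag)
}

#' Simulate a single control loop closed through its environment
#'
#' Runs the circular perceive-compare-act process for `n_iterations` steps
#' and returns a tidy trace. The per-step identity `e == r - p` holds exactly
#' in the returned trace.
#'
#' @inheritParams step_unit
#' @param n_iterations Number of iterations to simulate (>= 1).
#' @param dt Seconds per iteration; bookkeeping for the `time_s` column only
#'   (the slowing constant is expressed in iterations). Default 0.016 s,
#'   i.e. a 16 ms refresh.
#' @return A tibble of class `pct_trace` with columns `step`, `time_s`,
#'   `level`, `unit`, `p`, `r`, `e`, `qo`, `qi`, `d`.
#' @examples
#' u <- control_unit(output_gain = 20, slowing = 20)
#' tr <- run_single_loop(u, loop_environment(disturbance = 3), 400)
#' tail(tr$p, 1) # disturbance resisted: |p| well below |D|
#' @export
run_single_loop <- function(unit, env = loop_environment(),
                            n_iterations = 1000, dt = 0.016) {
  net <- unit_network(unit)
  propagate(net, env, n_iterations = n_iterations, dt = dt)
}

#' Closed-form steady state of a single control loop
#'
#' For constant reference and disturbance the discrete loop converges (when
#' stable) to the fixed point
#' \deqn{e^\* = \frac{r - K_i D}{1 + K_i K_f K_o}, \quad p^\* = r - e^\*,
#'       \quad Q_o^\* = K_o e^\*.}
#' Used as the analytic oracle for simulated loops.
#'
#' @inheritParams step_unit
#' @param constant_disturbance Constant disturbance value \eqn{D}.
#' @return A tibble with one row: `p_star`, `e_star`, `qo_star`, `qi_star`.
#' @export
analytic_steady_state <- function(unit, env = loop_environment(),
                                  constant_disturbance = env$disturbance[1]) {
  G <- unit$input_gain * env$feedback_gain * unit$output_gain
  denom <- 1 + G
  if (abs(denom) < 1e-8) {
    rlang::abort(
      "Degenerate loop: 1 + Ki*Kf*Ko is (numerically) zero; no fixed point.",
      class = "pctsim_degenerate_loop_error"
    )
  }
  D <- check_scalar(constant_disturbance, "constant_disturbance")
  e_star <- (unit$reference - unit$input_gain * D) / denom
  qo_star <- unit$output_gain * e_star
  tibble::tibble(
    p_star = unit$reference - e_star,
    e_star = e_star,
    qo_star = qo_star,
    qi_star = env$feedback_gain * qo_star + D
  )
}
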