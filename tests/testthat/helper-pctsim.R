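# Shared helpers: independent oracles and randomized-but-seeded draws.

# Naive double-loop WMRSE oracle: computed directly from the definition,
# independent of the package's filtered implementation.
naive_wmrse <- function(emat, window) {
  n <- nrow(emat)
  k <- ncol(emat)
  starts <- seq_len(n - window + 1)
  out <- numeric(length(starts))
  for (s in starts) {
    acc <- 0
    for (t in s:(s + window - 1)) {
      for (u in seq_len(k)) {
        acc <- acc + emat[t, u]^2
      }
    }
    out[s] <- sqrt(acc / (window * k))
  }
  out
}

# Draw a single-loop parameter set that is stable under the discrete
# update: Ki*Kf*Ko > 0 and slowing > (1 + loop gain) / 2, with margin so a
# moderate run converges well within tolerance.
draw_stable_loop <- function() {
  ki <- stats::runif(1, 0.5, 2)
  kf <- stats::runif(1, 0.5, 2)
  ko <- stats::runif(1, 1, 20)
  G <- ki * kf * ko
  slowing <- max(1, (1 + G) / 2) * stats::runif(1, 1.3, 3)
  list(
    unit = control_unit(input_gain = ki, output_gain = ko,
                        slowing = slowing,
                        reference = stats::runif(1, -5, 5)),
    env = loop_environment(feedback_gain = kf,
                           disturbance = stats::runif(1, -3, 3))
  )
}

# Small synthetic multi-unit trace with prescribed per-unit error series,
# for exercising trace-level metrics without running a simulation.
trace_from_errors <- function(emat) {
  n <- nrow(emat)
  k <- ncol(emat)
  out <- tibble::tibble(
    step = rep(seq_len(n), k),
    time_s = rep(seq_len(n), k) * 0.016,
    level = 1,
    unit = rep(sprintf("U%d", seq_len(k)), each = n),
    p = 0, r = as.vector(emat), e = as.vector(emat), qo = 0,
    qi = NA_real_, d = NA_real_
  )
  class(out) <- c("pct_trace", class(out))
  out
}
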