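# Conflict-and-reorganization experiment, two-agent conflict demo, and the
# approach-avoidance compromise-distance model.

# Specialized scalar simulator for the 4-unit conflict architecture.
# Mirrors simulate_network() operation-for-operation (same update order,
# same RNG usage for reorganization) but avoids per-step allocation; an
# equivalence test pins it against the generic engine. Returns the error
# matrix (steps x units), the final network and the reorganization events.
simulate_conflict_fast <- function(net, env, n_iterations, reorg = NULL) {
  n <- as.integer(n_iterations)
  D <- disturbance_series(env$disturbance, n)
  lev1 <- net$levels[[1]]; lev2 <- net$levels[[2]]; lev3 <- net$levels[[3]]
  ki1 <- lev1$ki; ko1 <- lev1$ko; s1 <- lev1$slowing
  kiA <- lev2$ki[1]; koA <- lev2$ko[1]; sA <- lev2$slowing[1]
  kiB <- lev2$ki[2]; koB <- lev2$ko[2]; sB <- lev2$slowing[2]
  kiT <- lev3$ki; koT <- lev3$ko; sT <- lev3$slowing
  w_lA <- net$ref_w[[1]][1, 1]; w_lB <- net$ref_w[[1]][1, 2]
  w_tA <- net$ref_w[[2]][1, 1]; w_tB <- net$ref_w[[2]][2, 1]
  pwA <- net$per_w[[2]][1, 1]; pwB <- net$per_w[[2]][2, 1]
  pwT1 <- net$per_w[[3]][1, 1]; pwT2 <- net$per_w[[3]][1, 2]
  r_top <- net$top_ref
  kf <- env$feedback_gain
  qi <- env$init_input
  p1 <- pA <- pB <- pT <- 0
  qo1 <- qoA <- qoB <- qoT <- 0
  E <- matrix(0.0, n, 4,
              dimnames = list(NULL, c("L1U1", "L2U1", "L2U2", "L3U1")))
  do_reorg <- !is.null(reorg) && reorg$target_set != "none"
  reorg_state <- NULL
  events <- if (do_reorg) vector("list", n %/% reorg$window) else list()
  n_ev <- 0L
  lim <- .instability_limit

  for (t in seq_len(n)) {
    r1 <- w_lA * qoA + w_lB * qoB
    p1n <- ki1 * qi
    e1 <- r1 - p1n
    qo1n <- qo1 + (ko1 * e1 - qo1) / s1
    rA <- w_tA * qoT; rB <- w_tB * qoT
    pAn <- kiA * (pwA * p1); pBn <- kiB * (pwB * p1)
    eA <- rA - pAn; eB <- rB - pBn
    qoAn <- qoA + (koA * eA - qoA) / sA
    qoBn <- qoB + (koB * eB - qoB) / sB
    pTn <- kiT * (pwT1 * pA + pwT2 * pB)
    eT <- r_top - pTn
    qoTn <- qoT + (koT * eT - qoT) / sT
    qin <- kf * qo1n + D[t]
    if (is.na(qo1n) || is.na(qoAn) || is.na(qoBn) || is.na(qoTn) ||
        abs(qo1n) > lim || abs(qoAn) > lim || abs(qoBn) > lim ||
        abs(qoTn) > lim || abs(p1n) > lim || abs(qin) > lim) {
      abort_instability(t, "conflict architecture")
    }
    E[t, 1] <- e1; E[t, 2] <- eA; E[t, 3] <- eB; E[t, 4] <- eT
    p1 <- p1n; pA <- pAn; pB <- pBn; pT <- pTn
    qo1 <- qo1n; qoA <- qoAn; qoB <- qoBn; qoT <- qoTn
    qi <- qin

    if (do_reorg && t %% reorg$window == 0L) {
      win <- (t - reorg$window + 1L):t
      win_err <- sum(E[win, 1]^2) + (sum(E[win, 2]^2) + sum(E[win, 3]^2)) +
        sum(E[win, 4]^2)
      res <- reorg_step(net, reorg, reorg_state, win_err)
      net <- res$net
      reorg_state <- res$state
      w_lA <- net$ref_w[[1]][1, 1]; w_lB <- net$ref_w[[1]][1, 2]
      w_tA <- net$ref_w[[2]][1, 1]; w_tB <- net$ref_w[[2]][2, 1]
      koA <- net$levels[[2]]$ko[1]; koB <- net$levels[[2]]$ko[2]
      n_ev <- n_ev + 1L
      events[[n_ev]] <- c(step = t, delta_error = res$event$delta_error,
                          tumbled = res$event$tumbled,
                          step_size = res$event$step_size,
                          clipped = res$event$clipped)
    }
  }
  ev <- if (n_ev) {
    m <- do.call(rbind, events[seq_len(n_ev)])
    tibble::tibble(step = as.integer(m[, "step"]),
                   delta_error = m[, "delta_error"],
                   tumbled = m[, "tumbled"] > 0,
                   step_size = m[, "step_size"],
                   clipped = m[, "clipped"] > 0)
  } else {
    tibble::tibble(step = integer(), delta_error = numeric(),
                   tumbled = logical(), step_size = numeric(),
                   clipped = logical())
  }
  list(E = E, net = net, events = ev)
}

#' Run the three-condition conflict-reorganization experiment
#'
#' For each agent a random three-level conflict architecture is drawn (see
#' [build_three_level_conflict()]) and the identical architecture and
#' disturbance are simulated under each reorganization condition (paired
#' design): `"none"` (no reorganization), `"mid"` (mid-level connection
#' strengths may change) and `"top"` (the top level's two reference-setting
#' strengths may change). Control quality is summarized by the final
#' sliding-window WMRSE (see [wmrse()]).
#'
#' Agents whose simulation diverges in any condition are flagged
#' `divergent` and excluded from the condition medians.
#'
#' @param n_agents Number of agents (the demo default is 20).
#' @param conditions Subset of `c("none", "mid", "top")`.
#' @param iterations Iterations per run.
#' @param window Reorganization window (iterations per decision).
#' @param step_coefficient,error_tolerance,max_step Passed to
#'   [reorg_config()].
#' @param weight_range,dead_zone Passed to [build_three_level_conflict()].
#' @param wmrse_window WMRSE window (default 10 iterations).
#' @param trajectory_stride Stride for the stored WMRSE trajectories.
#' @param seed Base seed; agent seeds and per-condition reorganization seeds
#'   are derived from it deterministically.
#' @return A list of class `pct_experiment`: `final` (tibble: agent,
#'   condition, final_wmrse, n_tumbles, divergent), `medians` (tibble:
#'   condition, median_final_wmrse, n_agents), `trajectories` (tibble:
#'   agent, condition, window_start, wmrse), `events` (tibble of
#'   reorganization decisions: agent, condition, step, delta_error,
#'   tumbled, step_size, clipped) and the call parameters.
#' @examples
#' \donttest{
#' ex <- run_conflict_reorg_experiment(n_agents = 8, iterations = 3000,
#'                                     seed = 1)
#' ex$medians
#' }
#' @export
run_conflict_reorg_experiment <- function(n_agents = 20,
                                          conditions = c("none", "mid", "top"),
                                          iterations = 8000, window = 200,
                                          step_coefficient = 0.005,
                                          error_tolerance = 5,
                                          max_step = 0.3,
                                          weight_range = c(0.5, 5),
                                          dead_zone = 0.1,
                                          wmrse_window = 10,
                                          trajectory_stride = 50,
                                          seed = 1) {
  conditions <- match.arg(conditions, several.ok = TRUE)
  target_of <- c(none = "none", mid = "mid_level_weights",
                 top = "top_level_weights")
  seeds <- derive_seeds(seed, 2L * n_agents)
  agent_seeds <- seeds[seq_len(n_agents)]
  reorg_seeds <- seeds[n_agents + seq_len(n_agents)]

  rows <- list()
  traj <- list()
  evs <- list()
  for (i in seq_len(n_agents)) {
    net <- build_three_level_conflict(agent_seeds[i], weight_range, dead_zone)
    dist <- generate_disturbance("pseudorandom", iterations, amplitude = 1,
                                 smooth = 20, seed = agent_seeds[i])
    env <- loop_environment(disturbance = dist)
    for (j in seq_along(conditions)) {
      cond <- conditions[j]
      rc <- reorg_config(window = window,
                         step_coefficient = step_coefficient,
                         target_set = target_of[[cond]],
                         error_tolerance = error_tolerance,
                         max_step = max_step)
      sim <- tryCatch(
        with_seed(reorg_seeds[i] + j,
                  simulate_conflict_fast(net, env, iterations, rc)),
        pctsim_instability_error = function(e) NULL
      )
      if (is.null(sim)) {
        rows[[length(rows) + 1L]] <- tibble::tibble(
          agent = i, condition = cond, final_wmrse = NA_real_,
          n_tumbles = NA_integer_, divergent = TRUE
        )
        next
      }
      if (nrow(sim$events)) {
        evs[[length(evs) + 1L]] <- dplyr::mutate(sim$events, agent = i,
                                                 condition = cond,
                                                 .before = 1)
      }
      wm <- wmrse_matrix(sim$E, wmrse_window, stride = 1)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        agent = i, condition = cond,
        final_wmrse = wm$wmrse[nrow(wm)],
        n_tumbles = sum(sim$events$tumbled), divergent = FALSE
      )
      keep <- seq(1, nrow(wm), by = trajectory_stride)
      traj[[length(traj) + 1L]] <- tibble::tibble(
        agent = i, condition = cond,
        window_start = wm$window_start[keep], wmrse = wm$wmrse[keep]
      )
    }
  }
  final <- dplyr::bind_rows(rows)
  bad <- unique(final$agent[final$divergent])
  ok <- dplyr::filter(final, !.data$agent %in% bad)
  medians <- ok |>
    dplyr::group_by(condition = factor(.data$condition, levels = conditions)) |>
    dplyr::summarise(median_final_wmrse = stats::median(.data$final_wmrse),
                     n_agents = dplyr::n(), .groups = "drop")
  structure(
    list(final = final, medians = medians,
         trajectories = dplyr::bind_rows(traj),
         events = dplyr::bind_rows(evs),
         conditions = conditions, n_agents = n_agents,
         iterations = iterations, window = window, seed = seed),
    class = "pct_experiment"
  )
}

#' Paired sign tests for the condition ordering
#'
#' Tests, over agents, whether final WMRSE under one condition is smaller
#' than under another (one-sided sign test via [stats::binom.test()]),
#' for `top < mid` and `mid < none`.
#'
#' @param experiment A `pct_experiment` from
#'   [run_conflict_reorg_experiment()].
#' @return A tibble with columns `comparison`, `n_pairs`, `n_smaller`,
#'   `p_value`.
#' @export
condition_ordering_test <- function(experiment) {
  wide <- experiment$final |>
    dplyr::filter(!.data$divergent) |>
    tidyr::pivot_wider(id_cols = "agent", names_from = "condition",
                       values_from = "final_wmrse") |>
    stats::na.omit()
  one <- function(a, b) {
    d <- wide[[a]] - wide[[b]]
    d <- d[d != 0]
    tibble::tibble(
      comparison = paste(a, "<", b),
      n_pairs = length(d),
      n_smaller = sum(d < 0),
      p_value = stats::binom.test(sum(d < 0), length(d), p = 0.5,
                                  alternative = "greater")$p.value
    )
  }
  pairs <- list(c("top", "mid"), c("mid", "none"))
  pairs <- Filter(function(p) all(p %in% names(wide)), pairs)
  dplyr::bind_rows(lapply(pairs, function(p) one(p[1], p[2])))
}

#' Two-agent goal-conflict demonstration
#'
#' A one-dimensional rendering of the classic two-agent conflict: agent A
#' controls its position toward a fixed goal location while also keeping a
#' safe distance from agent B; agent B controls its proximity to A. Both
#' agents act through slowed velocity outputs. Depending on the two gains
#' the episode ends with goals effectively met, with A blocked away from its
#' goal, or with wide mutual oscillation.
#'
#' Classification thresholds (documented, configurable): `goals_met` when
#' both final errors (A's position error and B's distance error) are below
#' 5\% of the goal separation; `oscillation` when the late-half variance of
#' A's position exceeds 10\% of the squared goal separation; otherwise
#' `blocked`.
#'
#' @param gain_A,gain_B Positive gains ("effort") of the two agents.
#' @param goal_A A's goal position. A starts at 0, B at `start_B`.
#' @param start_B B's starting position.
#' @param d_safe A's preferred minimum distance from B.
#' @param r_B B's preferred distance from A.
#' @param slowing Output slowing of both agents, iterations.
#' @param eta Integration rate of position per unit velocity output.
#' @param v_max Speed limit: velocity commands saturate at `[-v_max,
#'   v_max]`, so high-gain instability expresses itself as bounded, wide
#'   oscillation rather than numerical divergence.
#' @param reaction_delay Whole iterations by which each agent's perception
#'   of the other's position lags reality (a reaction time); combined with
#'   high gain this produces wide limit-cycle oscillation.
#' @param iterations Episode length.
#' @param seed Seed for the small symmetry-breaking positional jitter.
#' @return A list of class `pct_two_agent`: `outcome`
#'   (`"goals_met"`, `"blocked"` or `"oscillation"`), `trace` (tibble:
#'   step, x_a, x_b, distance), and the diagnostic quantities used by the
#'   classifier.
#' @export
run_two_agent_conflict <- function(gain_A, gain_B, goal_A = 10,
                                   start_B = 20, d_safe = 6, r_B = 6,
                                   slowing = 1, eta = 0.1, v_max = 20,
                                   reaction_delay = 5,
                                   iterations = 4000, seed = 1) {
  if (gain_A <= 0 || gain_B <= 0) abort_config("gains must be > 0.")
  n <- as.integer(iterations)
  del <- as.integer(reaction_delay)
  jitter <- with_seed(seed, stats::rnorm(n, 0, 0.005))
  x_a <- 0; x_b <- start_B
  v_a <- 0; v_b <- 0
  xs_a <- numeric(n); xs_b <- numeric(n)
  for (t in seq_len(n)) {
    # each agent reacts to the configuration as of `reaction_delay` steps ago
    xa_lag <- if (t - del >= 1) xs_a[t - del] else 0
    xb_lag <- if (t - del >= 1) xs_b[t - del] else start_B
    d <- abs(xa_lag - xb_lag)
    u <- if (xa_lag >= xb_lag) 1 else -1 # direction away from B, tie: positive
    v_des_a <- clip(gain_A * (goal_A - xa_lag) +
                      gain_A * max(0, d_safe - d) * u, -v_max, v_max)
    v_des_b <- clip(gain_B * (d - r_B) * u, -v_max, v_max) # u: B toward A
    v_a <- v_a + (v_des_a - v_a) / slowing
    v_b <- v_b + (v_des_b - v_b) / slowing
    x_a <- x_a + eta * v_a + jitter[t]
    x_b <- x_b + eta * v_b
    if (!is.finite(x_a) || !is.finite(x_b) ||
        max(abs(x_a), abs(x_b)) > .instability_limit) {
      abort_instability(t, "two-agent demo")
    }
    xs_a[t] <- x_a; xs_b[t] <- x_b
  }
  sep <- abs(goal_A)  # A starts at 0
  tail_idx <- seq.int(max(1L, n - n %/% 10L), n)
  late_idx <- seq.int(n %/% 2L + 1L, n)
  err_a <- abs(mean(xs_a[tail_idx]) - goal_A)
  err_b <- abs(mean(abs(xs_a[tail_idx] - xs_b[tail_idx])) - r_B)
  var_late <- stats::var(xs_a[late_idx])
  outcome <- if (var_late > 0.10 * sep^2) {
    "oscillation"
  } else if (err_a < 0.05 * sep && err_b < 0.05 * sep) {
    "goals_met"
  } else {
    "blocked"
  }
  structure(
    list(
      outcome = outcome,
      trace = tibble::tibble(step = seq_len(n), x_a = xs_a, x_b = xs_b,
                             distance = abs(xs_a - xs_b)),
      err_a = err_a, err_b = err_b,
      late_variance = var_late, goal_A = goal_A,
      gain_A = gain_A, gain_B = gain_B
    ),
    class = "pct_two_agent"
  )
}

#' Approach-avoidance compromise distance
#'
#' Two control systems with integrating outputs hold opposing references for
#' the same perceived distance: a defensive ("stay safe") system preferring
#' a large distance and an approach system preferring a small one. The
#' distance settles at the gain-weighted virtual reference
#' \deqn{d^\* = \frac{g_s r_s + g_a r_a}{g_s + g_a},}
#' a compromise lying between the two references and closer to the
#' reference of the higher-gain system.
#'
#' @param g_safe,r_safe Gain and reference distance of the defensive system
#'   (`r_safe` must exceed `r_approach`).
#' @param g_approach,r_approach Gain and reference of the approach system
#'   (`r_approach >= 0`).
#' @param disturbance Scalar or per-iteration series added to the distance
#'   each step (scaled by `eta`).
#' @param d0 Starting distance.
#' @param eta Integration rate; must satisfy
#'   `eta * (g_safe + g_approach) < 2` for stability.
#' @param iterations Number of iterations.
#' @return A list of class `pct_approach_avoidance`: `equilibrium` (mean of
#'   the final 10\% of the distance trace), `virtual_reference` (the closed
#'   form above), `relative_position` (0 at `r_approach`, 1 at `r_safe`) and
#'   `trace`.
#' @examples
#' aa <- run_approach_avoidance(g_safe = 3, r_safe = 10,
#'                              g_approach = 1, r_approach = 2)
#' aa$equilibrium # 8 = (3*10 + 1*2) / 4
#' @export
run_approach_avoidance <- function(g_safe = 3, r_safe = 10, g_approach = 1,
                                   r_approach = 2, disturbance = 0, d0 = 0,
                                   eta = 0.02, iterations = 2000) {
  if (g_safe <= 0 || g_approach <= 0) abort_config("gains must be > 0.")
  if (!(r_safe > r_approach) || r_approach < 0) {
    abort_config("need r_safe > r_approach >= 0.")
  }
  n <- as.integer(iterations)
  D <- disturbance_series(disturbance, n)
  d <- d0
  ds <- numeric(n)
  for (t in seq_len(n)) {
    e_s <- r_safe - d
    e_a <- r_approach - d
    d <- d + eta * (g_safe * e_s + g_approach * e_a) + eta * D[t]
    if (!is.finite(d) || abs(d) > .instability_limit) {
      abort_instability(t, "approach-avoidance distance")
    }
    ds[t] <- d
  }
  tail_idx <- seq.int(max(1L, n - n %/% 10L), n)
  eq <- mean(ds[tail_idx])
  vref <- (g_safe * r_safe + g_approach * r_approach) / (g_safe + g_approach)
  structure(
    list(
      equilibrium = eq,
      virtual_reference = vref,
      relative_position = (eq - r_approach) / (r_safe - r_approach),
      trace = tibble::tibble(step = seq_len(n), distance = ds),
      g_safe = g_safe, r_safe = r_safe,
      g_approach = g_approach, r_approach = r_approach
    ),
    class = "pct_approach_avoidance"
  )
}
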