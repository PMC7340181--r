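#' Specify a hierarchy of control units
#'
#' Units are grouped into levels (level 1 = lowest, closed through the
#' environment). Each non-top unit's reference value at step `t` is the
#' weighted sum of its superiors' outputs at step `t - 1`; each level-`l`
#' unit's perception (`l >= 2`) is a weighted sum of level-`l-1` perceptions
#' at step `t - 1`. All units update synchronously: every unit reads
#' previous-step values and writes next-step values (double-buffering, as in
#' parallel neural processing).
#'
#' @param levels A list of levels, lowest first; each level is a list of
#'   [control_unit()] objects.
#' @param reference_weights A list of matrices, `reference_weights[[l]]`
#'   (for `l < L`) of dimension `n_l x n_{l+1}`, mapping level-`l+1` outputs
#'   to level-`l` references. Signed; weights only connect adjacent levels.
#' @param perception_weights A list of matrices, `perception_weights[[l]]`
#'   (for `l >= 2`) of dimension `n_l x n_{l-1}`, mapping level-`l-1`
#'   perceptions into level-`l` perceptual inputs. Level-1 units perceive
#'   their own environmental input quantity directly.
#' @param top_references Numeric vector of fixed references for the top
#'   level, recycled to its size.
#' @return An object of class `pct_network`.
#' @examples
#' # Two-level chain: the top unit sets the bottom unit's reference.
#' net <- network_spec(
#'   levels = list(
#'     list(control_unit(output_gain = 20, slowing = 20)),
#'     list(control_unit(output_gain = 2, slowing = 40))
#'   ),
#'   reference_weights = list(matrix(1)),
#'   perception_weights = list(NULL, matrix(1)),
#'   top_references = 5
#' )
#' @export
network_spec <- function(levels, reference_weights = list(),
                         perception_weights = list(),
                         top_references = 0) {
  if (!is.list(levels) || length(levels) < 1) {
    abort_config("`levels` must be a non-empty list of levels.")
  }
  L <- length(levels)
  nl <- integer(L)
  lev <- vector("list", L)
  labels <- vector("list", L)
  for (l in seq_len(L)) {
    units <- levels[[l]]
    if (inherits(units, "pct_unit")) units <- list(units)
    if (!length(units) || !all(vapply(units, inherits, logical(1), "pct_unit"))) {
      abort_config(sprintf("level %d must contain control_unit objects.", l))
    }
    nl[l] <- length(units)
    lev[[l]] <- list(
      ki = vapply(units, `[[`, numeric(1), "input_gain"),
      ko = vapply(units, `[[`, numeric(1), "output_gain"),
      slowing = vapply(units, `[[`, numeric(1), "slowing"),
      delay = vapply(units, `[[`, integer(1), "transport_delay"),
      reference = vapply(units, `[[`, numeric(1), "reference")
    )
    labels[[l]] <- sprintf("L%dU%d", l, seq_len(nl[l]))
  }
  ref_w <- vector("list", L)
  for (l in seq_len(L - 1)) {
    w <- if (length(reference_weights) >= l) reference_weights[[l]] else NULL
    if (is.null(w)) {
      abort_config(sprintf(
        "reference_weights[[%d]] missing: every non-top unit needs at least one incoming reference weight.", l
      ))
    }
    w <- as.matrix(w)
    if (!all(dim(w) == c(nl[l], nl[l + 1])) || anyNA(w) || !all(is.finite(w))) {
      abort_config(sprintf(
        "reference_weights[[%d]] must be a finite %d x %d matrix.",
        l, nl[l], nl[l + 1]
      ))
    }
    if (any(rowSums(w != 0) == 0)) {
      abort_config(sprintf(
        "every level-%d unit needs at least one nonzero incoming reference weight.", l
      ))
    }
    ref_w[[l]] <- w
  }
  per_w <- vector("list", L)
  for (l in seq_len(L)[-1]) {
    w <- if (length(perception_weights) >= l) perception_weights[[l]] else NULL
    if (is.null(w)) {
      # default: unweighted mean of the level below
      w <- matrix(1 / nl[l - 1], nl[l], nl[l - 1])
    }
    w <- as.matrix(w)
    if (!all(dim(w) == c(nl[l], nl[l - 1])) || anyNA(w) || !all(is.finite(w))) {
      abort_config(sprintf(
        "perception_weights[[%d]] must be a finite %d x %d matrix.",
        l, nl[l], nl[l - 1]
      ))
    }
    if (any(rowSums(w != 0) == 0)) {
      abort_config(sprintf(
        "every level-%d unit needs at least one nonzero incoming perception weight.", l
      ))
    }
    per_w[[l]] <- w
  }
  structure(
    list(
      levels = lev, n_units = nl, ref_w = ref_w, per_w = per_w,
      top_ref = rep_len(as.numeric(top_references), nl[L]),
      labels = labels
    ),
    class = "pct_network"
  )
}

# Wrap a single unit as a degenerate one-level network.
unit_network <- function(unit) {
  network_spec(levels = list(list(unit)), top_references = unit$reference)
}

# ---------------------------------------------------------------------------
# Core synchronous engine. Operates on raw matrices for speed; public
# wrappers convert to tidy tibbles. Optionally interleaves reorganization
# every `reorg$window` iterations (see reorganization.R).
simulate_network <- function(net, env, n_iterations, dt = 0.016,
                             reorg = NULL) {
  n <- as.integer(n_iterations)
  if (is.na(n) || n < 1) abort_config("`n_iterations` must be >= 1.")
  L <- length(net$levels)
  nl <- net$n_units
  kf <- rep_len(env$feedback_gain, nl[1])
  init_qi <- rep_len(env$init_input, nl[1])
  D <- disturbance_series(env$disturbance, n)
  Dm <- if (is.matrix(D)) D else matrix(rep(D, nl[1]), n, nl[1])

  P <- lapply(nl, function(k) matrix(0.0, n, k))
  Rm <- lapply(nl, function(k) matrix(0.0, n, k))
  Em <- lapply(nl, function(k) matrix(0.0, n, k))
  Qom <- lapply(nl, function(k) matrix(0.0, n, k))
  Qi <- matrix(0.0, n, nl[1])

  p_prev <- lapply(nl, function(k) numeric(k))
  qo_prev <- lapply(nl, function(k) numeric(k))
  qi_prev <- init_qi
  all_zero_delay <- all(unlist(lapply(net$levels, `[[`, "delay")) == 0L)

  do_reorg <- !is.null(reorg) && reorg$target_set != "none"
  reorg_state <- NULL
  events <- if (do_reorg) vector("list", n %/% reorg$window) else list()
  n_events <- 0L

  for (t in seq_len(n)) {
    p_new <- vector("list", L)
    qo_new <- vector("list", L)
    for (l in seq_len(L)) {
      lev <- net$levels[[l]]
      r <- if (l == L) net$top_ref else drop(net$ref_w[[l]] %*% qo_prev[[l + 1]])
      if (l == 1) {
        if (all_zero_delay) {
          src <- qi_prev
        } else {
          src <- vapply(seq_len(nl[1]), function(i) {
            idx <- t - 1L - lev$delay[i]
            if (idx >= 1) Qi[idx, i] else if (idx == 0) init_qi[i] else 0
          }, numeric(1))
        }
        p <- lev$ki * src
      } else {
        if (all_zero_delay) {
          low_p <- p_prev[[l - 1]]
          p <- lev$ki * drop(net$per_w[[l]] %*% low_p)
        } else {
          p <- vapply(seq_len(nl[l]), function(i) {
            idx <- t - 1L - lev$delay[i]
            low_p <- if (idx >= 1) P[[l - 1]][idx, ] else numeric(nl[l - 1])
            lev$ki[i] * sum(net$per_w[[l]][i, ] * low_p)
          }, numeric(1))
        }
      }
      e <- r - p
      qo <- qo_prev[[l]] + (lev$ko * e - qo_prev[[l]]) / lev$slowing
      if (anyNA(qo) || max(abs(qo), abs(p)) > .instability_limit) {
        bad <- which(!is.finite(qo) | abs(qo) > .instability_limit |
                       abs(p) > .instability_limit)[1]
        if (is.na(bad)) bad <- 1L
        abort_instability(t, net$labels[[l]][bad])
      }
      P[[l]][t, ] <- p
      Rm[[l]][t, ] <- r
      Em[[l]][t, ] <- e
      Qom[[l]][t, ] <- qo
      p_new[[l]] <- p
      qo_new[[l]] <- qo
    }
    qi <- kf * qo_new[[1]] + Dm[t, ]
    if (anyNA(qi) || max(abs(qi)) > .instability_limit) {
      abort_instability(t, "environment")
    }
    Qi[t, ] <- qi
    qi_prev <- qi
    p_prev <- p_new
    qo_prev <- qo_new

    if (do_reorg && t %% reorg$window == 0L) {
      win <- (t - reorg$window + 1L):t
      win_err <- sum(vapply(Em, function(m) sum(m[win, , drop = FALSE]^2),
                            numeric(1)))
      res <- reorg_step(net, reorg, reorg_state, win_err)
      net <- res$net
      reorg_state <- res$state
      n_events <- n_events + 1L
      events[[n_events]] <- c(step = t, delta_error = res$event$delta_error,
                              tumbled = res$event$tumbled,
                              step_size = res$event$step_size,
                              clipped = res$event$clipped)
    }
  }

  list(
    P = P, R = Rm, E = Em, Qo = Qom, Qi = Qi, D = Dm,
    net = net, dt = dt, n = n,
    events = if (n_events) {
      ev <- do.call(rbind, events[seq_len(n_events)])
      tibble::tibble(
        step = as.integer(ev[, "step"]),
        delta_error = ev[, "delta_error"],
        tumbled = ev[, "tumbled"] > 0,
        step_size = ev[, "step_size"],
        clipped = ev[, "clipped"] > 0
      )
    } else {
      tibble::tibble(step = integer(), delta_error = numeric(),
                     tumbled = logical(), step_size = numeric(),
                     clipped = logical())
    }
  )
}

# Convert raw engine output to the tidy per-unit trace tibble.
engine_trace <- function(sim) {
  L <- length(sim$P)
  n <- sim$n
  pieces <- vector("list", L)
  for (l in seq_len(L)) {
    k <- ncol(sim$P[[l]])
    pieces[[l]] <- tibble::tibble(
      step = rep(seq_len(n), k),
      time_s = rep(seq_len(n), k) * sim$dt,
      level = l,
      unit = rep(sim$net$labels[[l]], each = n),
      p = as.vector(sim$P[[l]]),
      r = as.vector(sim$R[[l]]),
      e = as.vector(sim$E[[l]]),
      qo = as.vector(sim$Qo[[l]]),
      qi = if (l == 1) as.vector(sim$Qi) else NA_real_,
      d = if (l == 1) as.vector(sim$D) else NA_real_
    )
  }
  out <- dplyr::arrange(dplyr::bind_rows(pieces), .data$step, .data$level)
  class(out) <- c("pct_trace", class(out))
  attr(out, "dt") <- sim$dt
  attr(out, "n_iterations") <- n
  out
}

#' Simulate a hierarchy of control units
#'
#' Advances the whole network synchronously for `n_iterations` steps: every
#' unit reads previous-step signals and writes next-step signals, so a
#' non-top unit's reference at step `t` equals the weighted sum of its
#' superiors' outputs at step `t - 1` exactly.
#'
#' @param net A [network_spec()].
#' @param env A [loop_environment()] for the level-1 units (feedback gain,
#'   disturbance and initial input are recycled across level-1 units).
#' @inheritParams run_single_loop
#' @return A tibble of class `pct_trace`, one row per step per unit, with
#'   `qi`/`d` filled for level-1 units and `NA` above.
#' @export
propagate <- function(net, env = loop_environment(), n_iterations = 1000,
                      dt = 0.016) {
  stopifnot(inherits(net, "pct_network"))
  engine_trace(simulate_network(net, env, n_iterations, dt))
}

#' Three-level goal-conflict architecture
#'
#' One top unit sends two reference-setting outputs, one to each of two
#' mid-level units; the two mid-level units share the low-level unit's
#' perception as their input and jointly set the low-level reference. When
#' the two pathways demand incompatible values of the shared low-level
#' perception, both mid-level units carry chronic error: the signature of
#' goal conflict.
#'
#' @param w_top Numeric length-2: connection strengths from the top unit's
#'   output to the references of mid units A and B.
#' @param w_low Numeric length-2: connection strengths from mid units A and
#'   B's outputs to the low-level reference.
#' @param top_reference Fixed reference of the top unit.
#' @param low,mid_a,mid_b,top [control_unit()] parameter sets; defaults are a
#'   fast low-level controller under slower mid and top levels.
#' @return A `pct_network` that is also of class `pct_conflict_architecture`.
#' @seealso [build_three_level_conflict()] for randomized agents.
#' @export
conflict_architecture <- function(w_top, w_low, top_reference = 5,
                                  low = control_unit(output_gain = 20, slowing = 25),
                                  mid_a = control_unit(output_gain = 2, slowing = 50),
                                  mid_b = control_unit(output_gain = 2, slowing = 50),
                                  top = control_unit(output_gain = 2, slowing = 100)) {
  if (length(w_top) != 2 || length(w_low) != 2) {
    abort_config("`w_top` and `w_low` must each have length 2.")
  }
  net <- network_spec(
    levels = list(list(low), list(mid_a, mid_b), list(top)),
    reference_weights = list(
      matrix(as.numeric(w_low), 1, 2),
      matrix(as.numeric(w_top), 2, 1)
    ),
    perception_weights = list(NULL, matrix(1, 2, 1), matrix(0.5, 1, 2)),
    top_references = top_reference
  )
  class(net) <- c("pct_conflict_architecture", class(net))
  net
}

#' Draw a random three-level conflict agent
#'
#' The four connection strengths (two top-to-mid, two mid-to-low) are drawn
#' uniformly from `weight_range`, excluding a dead zone around zero so no
#' agent starts with a vacuous connection; all other parameters come from
#' the documented defaults of [conflict_architecture()]. Deterministic for a
#' fixed seed.
#'
#' @param rng_seed Integer seed.
#' @param weight_range Length-2 interval to draw connection strengths from.
#'   The default `c(0.5, 5)` draws positive strengths of unequal magnitude,
#'   which yields stable loops whose two mid-level reference demands
#'   disagree; ranges spanning zero are allowed (values inside
#'   `(-dead_zone, dead_zone)` are never drawn) but negative strengths put
#'   the corresponding loop in positive feedback.
#' @param dead_zone Half-width of the excluded interval around zero.
#' @param ... Passed to [conflict_architecture()].
#' @return A `pct_conflict_architecture`.
#' @export
build_three_level_conflict <- function(rng_seed, weight_range = c(0.5, 5),
                                       dead_zone = 0.1, ...) {
  if (length(weight_range) != 2 || anyNA(weight_range) ||
      !all(is.finite(weight_range)) || weight_range[1] >= weight_range[2]) {
    abort_config("`weight_range` must be a finite interval c(lo, hi), lo < hi.")
  }
  if (max(abs(weight_range)) <= dead_zone) {
    abort_config("`weight_range` lies entirely inside the dead zone.")
  }
  w <- with_seed(rng_seed, draw_weights(4L, weight_range, dead_zone))
  conflict_architecture(w_top = w[1:2], w_low = w[3:4], ...)
}

# Uniform draw from [lo, hi] excluding (-dz, dz), mass-proportional.
draw_weights <- function(k, range, dz) {
  lo <- range[1]; hi <- range[2]
  segs <- list()
  if (lo < -dz) segs <- c(segs, list(c(lo, min(hi, -dz))))
  if (hi > dz) segs <- c(segs, list(c(max(lo, dz), hi)))
  if (!length(segs)) abort_config("weight range excluded by dead zone.")
  len <- vapply(segs, diff, numeric(1))
  pick <- sample.int(length(segs), k, replace = TRUE, prob = len)
  stats::runif(k, min = vapply(segs, `[`, numeric(1), 1)[pick],
               max = vapply(segs, `[`, numeric(1), 2)[pick])
}

#' Total squared error over a trailing window
#'
#' Sums squared error across all units over the last `window` steps of a
#' trace: the "loss of control" quantity that drives reorganization.
#'
#' @param trace A `pct_trace` tibble.
#' @param window Number of trailing iterations to accumulate over.
#' @return A single non-negative number.
#' @export
total_error <- function(trace, window) {
  n <- max(trace$step)
  window <- check_scalar(window, "window")
  if (window < 1 || window != round(window)) {
    abort_config("`window` must be a positive integer.")
  }
  if (window > n) abort_config("`window` exceeds the trace length.")
  sum(trace$e[trace$step > n - window]^2)
}
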