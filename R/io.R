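#' Generate a disturbance (or target) series
#'
#' Deterministic for a fixed seed. `"pseudorandom"` is seeded uniform noise
#' smoothed by a moving average, a standard low-predictability signal for
#' tracking and disturbance studies.
#'
#' @param kind One of `"constant"`, `"step"`, `"sinusoid"`,
#'   `"pseudorandom"`.
#' @param n Series length in iterations.
#' @param value Constant value (`"constant"`), or post-step value
#'   (`"step"`).
#' @param base Pre-step value for `"step"`.
#' @param step_at Iteration at which the step occurs.
#' @param amplitude Amplitude of `"sinusoid"`; scale of `"pseudorandom"`
#'   (the smoothed noise is rescaled to this maximum absolute value).
#' @param period Sinusoid period in iterations.
#' @param phase Sinusoid phase in radians.
#' @param smooth Moving-average window (iterations) for `"pseudorandom"`.
#' @param seed RNG seed for `"pseudorandom"`; other kinds ignore it.
#' @return A numeric vector of length `n`.
#' @examples
#' generate_disturbance("step", 10, value = 3, step_at = 5)
#' @export
generate_disturbance <- function(kind = c("constant", "step", "sinusoid",
                                          "pseudorandom"),
                                 n, value = 0, base = 0, step_at = 1,
                                 amplitude = 1, period = 100, phase = 0,
                                 smooth = 20, seed = NULL) {
  if (!is.character(kind) || !kind[1] %in% c("constant", "step", "sinusoid",
                                             "pseudorandom")) {
    abort_config(sprintf("unknown disturbance kind '%s'.", kind[1]))
  }
  kind <- kind[1]
  n <- as.integer(n)
  if (is.na(n) || n < 1) abort_config("`n` must be >= 1.")
  switch(kind,
    constant = rep(as.numeric(value), n),
    step = {
      out <- rep(as.numeric(base), n)
      if (step_at <= n) out[seq.int(max(1, step_at), n)] <- as.numeric(value)
      out
    },
    sinusoid = amplitude * sin(2 * pi * seq_len(n) / period + phase),
    pseudorandom = {
      raw <- with_seed(seed, stats::runif(n + smooth, -1, 1))
      sm <- as.numeric(stats::filter(raw, rep(1 / smooth, smooth),
                                     sides = 1))[-seq_len(smooth)]
      m <- max(abs(sm))
      if (m > 0) sm <- sm * (amplitude / m)
      sm
    }
  )
}

# --------------------------------------------------------------------------
# Run configuration: a validated, defaults-filled nested list, readable and
# writable as YAML or JSON (by file extension).

config_defaults <- function() {
  list(
    scenario = NULL,
    seed = 1L,
    out_dir = ".",
    log_level = "info",
    unit = list(input_gain = 1, output_gain = 10, slowing = 20,
                transport_delay = 0, reference = 0),
    env = list(feedback_gain = 1, init_input = 0),
    disturbance = list(kind = "constant", value = 0, base = 0, step_at = 1,
                       amplitude = 1, period = 100, phase = 0, smooth = 20),
    simulation = list(n_iterations = 1000, dt = 0.016),
    reorg = list(window = 200, step_coefficient = 0.005,
                 target_set = "none", error_tolerance = 5, bound = 100,
                 max_step = 0.3),
    experiment = list(n_agents = 20, iterations = 8000,
                      weight_range = c(0.5, 5), dead_zone = 0.1,
                      wmrse_window = 10, trajectory_stride = 50),
    cohort = list(n_cases = 5613, n_sessions = 26, baseline_mean = 20,
                  baseline_sd = 7, score_scale = c(0, 40),
                  change_sd_coef = 0.5, biased_step = FALSE,
                  bias_coef = 0.1),
    approach_avoidance = list(g_safe = 3, r_safe = 10, g_approach = 1,
                              r_approach = 2, d0 = 0, eta = 0.02,
                              iterations = 2000),
    two_agent = list(gain_A = 0.5, gain_B = 0.5, goal_A = 10, start_B = 20,
                     d_safe = 6, r_B = 6, slowing = 1, eta = 0.1,
                     v_max = 20, reaction_delay = 5, iterations = 4000),
    fitting = list(model_kind = "one_level_position",
                   target_kind = "sinusoid", n = 800, noise_sd = 0,
                   n_multistart = 8, max_delay = 4)
  )
}

known_scenarios <- c("run-unit", "run-conflict-experiment",
                     "run-therapy-sim", "run-approach-avoidance",
                     "fit-tracking")

# Merge user values over defaults, rejecting unknown keys at both levels.
merge_config <- function(user) {
  defaults <- config_defaults()
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    abort_config(sprintf("unknown config key: '%s'.", unknown[1]))
  }
  for (key in names(user)) {
    val <- user[[key]]
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(val)) {
        abort_config(sprintf("config block '%s' must be a mapping.", key))
      }
      bad <- setdiff(names(val), names(defaults[[key]]))
      if (length(bad)) {
        abort_config(sprintf("unknown config key: '%s.%s'.", key, bad[1]))
      }
      defaults[[key]][names(val)] <- val
    } else {
      defaults[[key]] <- val
    }
  }
  defaults
}

validate_config <- function(cfg) {
  if (is.null(cfg$scenario) || !cfg$scenario %in% known_scenarios) {
    abort_config(sprintf(
      "`scenario` must be one of: %s.", paste(known_scenarios, collapse = ", ")
    ))
  }
  if (cfg$unit$slowing < 1) {
    abort_config("`unit.slowing` must be >= 1 (out of range).")
  }
  if (cfg$unit$transport_delay < 0) {
    abort_config("`unit.transport_delay` must be >= 0 (out of range).")
  }
  if (cfg$simulation$n_iterations < 1 || cfg$simulation$dt <= 0) {
    abort_config("`simulation` requires n_iterations >= 1 and dt > 0.")
  }
  if (cfg$cohort$n_cases < 1 || cfg$cohort$n_sessions < 2) {
    abort_config("`cohort` requires n_cases >= 1 and n_sessions >= 2.")
  }
  if (cfg$reorg$window < 1 || cfg$reorg$step_coefficient <= 0) {
    abort_config("`reorg` requires window >= 1 and step_coefficient > 0.")
  }
  structure(cfg, class = "pct_config")
}

#' Load, validate and default-fill a run configuration
#'
#' The file format is chosen by extension: `.yaml`/`.yml` or `.json`. Any
#' unknown key is rejected by name; out-of-range values are rejected with
#' their bounds; all missing keys are filled from the documented defaults
#' (see `config_defaults` in the package source, echoed by
#' [write_config()]).
#'
#' @param path Path to a YAML or JSON configuration file.
#' @return A validated list of class `pct_config`.
#' @seealso [write_config()], [pct_cli()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    abort_config(sprintf("config file '%s' does not exist.", path))
  }
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    abort_config(sprintf("unsupported config extension '.%s'.", ext))
  )
  if (is.null(user)) user <- list()
  validate_config(merge_config(user))
}

#' Write a configuration to YAML or JSON
#'
#' @param config A `pct_config` (or plain list accepted by the same
#'   schema).
#' @param path Output path; format chosen by extension.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  cfg <- unclass(config)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    yaml = ,
    yml = yaml::write_yaml(cfg, path),
    json = jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE, null = "null"),
    abort_config(sprintf("unsupported config extension '.%s'.", ext))
  )
  invisible(path)
}

# Stable short hash of a config for output provenance headers.
config_hash <- function(config) {
  json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                           null = "null")
  substr(rlang::hash(as.character(json)), 1, 12)
}

#' Export a trace as tidy long-format CSV
#'
#' One row per step, entity and signal, with a provenance comment line
#' (`# pctsim seed=... config=...`) at the top.
#'
#' @param trace A `pct_trace` tibble.
#' @param path Output CSV path.
#' @param seed,config_id Recorded in the header comment.
#' @return `path`, invisibly.
#' @export
export_trace <- function(trace, path, seed = NA, config_id = "adhoc") {
  long <- trace |>
    tidyr::pivot_longer(cols = c("p", "r", "e", "qo", "qi", "d"),
                        names_to = "signal", values_to = "value") |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::select("step", "time_s", entity_id = "unit", "signal", "value")
  write_csv_with_header(long, path, seed, config_id)
  invisible(path)
}

write_csv_with_header <- function(df, path, seed = NA, config_id = "adhoc") {
  writeLines(sprintf("# pctsim seed=%s config=%s", seed, config_id), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}
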