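test_that("zero reference, zero disturbance, zero state stays at zero", {
  u <- control_unit(output_gain = 10, slowing = 20, reference = 0)
  tr <- run_single_loop(u, loop_environment(), 200)
  expect_true(all(tr$p == 0))
  expect_true(all(tr$e == 0))
  expect_true(all(tr$qo == 0))
  expect_true(all(tr$qi == 0))
})

test_that("analytic steady state matches the fixed-point algebra", {
  u <- control_unit(input_gain = 1, output_gain = 10, slowing = 20,
                    reference = 5)
  env <- loop_environment(feedback_gain = 1)
  ss <- analytic_steady_state(u, env, constant_disturbance = 0)
  expect_equal(ss$e_star, 5 / 11, tolerance = 1e-12)
  expect_equal(ss$p_star, 50 / 11, tolerance = 1e-12)
  ss2 <- analytic_steady_state(u, env, constant_disturbance = 2)
  expect_equal(ss2$e_star, 3 / 11, tolerance = 1e-12)
  # r = Ki * D forces zero error
  u3 <- control_unit(input_gain = 2, output_gain = 10, slowing = 20,
                     reference = 6)
  ss3 <- analytic_steady_state(u3, loop_environment(), 3)
  expect_equal(ss3$e_star, 0)
  expect_error(
    analytic_steady_state(
      control_unit(input_gain = 1, output_gain = -1, slowing = 2),
      loop_environment()
    ),
    class = "pctsim_degenerate_loop_error"
  )
})

test_that("simulation converges to the analytic fixed point", {
  u <- control_unit(input_gain = 1, output_gain = 10, slowing = 20,
                    reference = 5)
  env <- loop_environment()
  tr <- run_single_loop(u, env, 800)
  expect_equal(tr$e[nrow(tr)], 5 / 11, tolerance = 1e-3)
  expect_equal(tr$p[nrow(tr)], 50 / 11, tolerance = 1e-3)
})

test_that("a constant disturbance is resisted, |p| well below |D|", {
  u <- control_unit(output_gain = 20, slowing = 25, reference = 0)
  env <- loop_environment(disturbance = 3)
  tr <- run_single_loop(u, env, 1200)
  p_end <- tr$p[nrow(tr)]
  expect_lt(abs(p_end), 3)
  expect_equal(p_end, 3 / 21, tolerance = 1e-3)
})

test_that("a step disturbance perturbs error transiently, then recovers", {
  u <- control_unit(output_gain = 20, slowing = 25, reference = 2)
  d <- generate_disturbance("step", 1500, value = 3, base = 0,
                            step_at = 700)
  tr <- run_single_loop(u, loop_environment(disturbance = d), 1500)
  pre <- mean(abs(tr$e[600:699]))
  during <- max(abs(tr$e[700:760]))
  post <- mean(abs(tr$e[1400:1500]))
  expect_gt(during, pre + 0.05)
  expect_lt(abs(post - abs(analytic_steady_state(u, loop_environment(),
                                                 3)$e_star)), 1e-3)
})

test_that("error identity e == r - p holds exactly at every step", {
  u <- control_unit(output_gain = 8, slowing = 30, reference = 3,
                    transport_delay = 2)
  d <- generate_disturbance("sinusoid", 400, amplitude = 2, period = 80)
  tr <- run_single_loop(u, loop_environment(disturbance = d), 400)
  expect_identical(tr$e, tr$r - tr$p)
})

test_that("randomized stable loops converge to the analytic oracle", {
  pctsim:::with_seed(404, {
    for (i in 1:30) {
      cfg <- draw_stable_loop()
      ss <- analytic_steady_state(cfg$unit, cfg$env)
      tr <- run_single_loop(cfg$unit, cfg$env, 700)
      expect_equal(tr$p[nrow(tr)], ss$p_star, tolerance = 1e-3)
      expect_equal(tr$qo[nrow(tr)], ss$qo_star, tolerance = 1e-3)
    }
  })
})

test_that("steady-state error shrinks as loop gain grows", {
  env <- loop_environment(disturbance = 1)
  e_for_gain <- function(ko) {
    abs(analytic_steady_state(control_unit(output_gain = ko, slowing = 60,
                                           reference = 4), env)$e_star)
  }
  gains <- c(1, 5, 10, 25, 50)
  errs <- vapply(gains, e_for_gain, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("step_unit iterated by hand reproduces the engine trace exactly", {
  u <- control_unit(output_gain = 6, slowing = 30, reference = 2,
                    transport_delay = 3)
  d <- generate_disturbance("pseudorandom", 300, amplitude = 2, seed = 8)
  env <- loop_environment(feedback_gain = 1.5, disturbance = d,
                          init_input = 0)
  tr <- run_single_loop(u, env, 300)
  st <- unit_state(qi = env$init_input)
  for (t in 1:300) {
    st <- step_unit(u, env, st, d[t], t)
    expect_identical(st$p, tr$p[t])
    expect_identical(st$qo, tr$qo[t])
  }
})

test_that("divergent loops raise an instability error naming the step", {
  u <- control_unit(output_gain = 50, slowing = 2, reference = 1)
  err <- expect_error(run_single_loop(u, loop_environment(), 500),
                      class = "pctsim_instability_error")
  expect_match(conditionMessage(err), "step \\d+")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(control_unit(slowing = 0.5), class = "pctsim_config_error")
  expect_error(control_unit(transport_delay = -1),
               class = "pctsim_config_error")
  expect_error(control_unit(output_gain = NaN),
               class = "pctsim_config_error")
  expect_error(loop_environment(disturbance = c(1, NA)),
               class = "pctsim_config_error")
})

test_that("dt is bookkeeping only: 16 ms default labels the time axis", {
  tr <- run_single_loop(control_unit(), loop_environment(), 10)
  expect_equal(tr$time_s, tr$step * 0.016)
  tr2 <- run_single_loop(control_unit(), loop_environment(), 10, dt = 0.1)
  expect_identical(tr2$p, tr$p)
  expect_equal(tr2$time_s, tr2$step * 0.1)
})
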