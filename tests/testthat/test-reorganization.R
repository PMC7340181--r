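test_that("WMRSE matches the constant-error hand calculation", {
  emat <- cbind(rep(3, 40), rep(4, 40))
  w <- wmrse(trace_from_errors(emat), window = 10)
  expect_equal(nrow(w), 31)
  expect_equal(w$wmrse, rep(sqrt(12.5), 31), tolerance = 1e-12)
  z <- wmrse(trace_from_errors(matrix(0, 30, 3)), window = 10)
  expect_true(all(z$wmrse == 0))
})

test_that("WMRSE equals the naive double-loop oracle on random traces", {
  pctsim:::with_seed(2024, {
    for (i in 1:50) {
      n <- sample(20:60, 1)
      k <- sample(1:4, 1)
      emat <- matrix(rnorm(n * k, sd = 3), n, k)
      w <- sample(2:min(15, n), 1)
      expect_equal(wmrse(trace_from_errors(emat), window = w)$wmrse,
                   naive_wmrse(emat, w), tolerance = 1e-12)
    }
  })
})

test_that("strided WMRSE subsamples the sliding series", {
  emat <- matrix(rnorm(100), 100, 1)
  full <- wmrse(trace_from_errors(emat), window = 10, stride = 1)
  strided <- wmrse(trace_from_errors(emat), window = 10, stride = 10)
  expect_identical(strided$wmrse, full$wmrse[full$window_start %in%
                                               strided$window_start])
  expect_error(wmrse(trace_from_errors(emat), window = 101),
               class = "pctsim_config_error")
})

test_that("reorganization step obeys tumble/run/quiescence semantics", {
  net <- conflict_architecture(w_top = c(1, 2), w_low = c(1, 2))
  rc <- reorg_config(window = 10, step_coefficient = 0.1,
                     target_set = "top_level_weights")
  # quiescence: error at tolerance leaves parameters untouched
  rc_tol <- reorg_config(window = 10, step_coefficient = 0.1,
                         target_set = "top_level_weights",
                         error_tolerance = 1)
  res <- pctsim:::with_seed(1, reorg_step(net, rc_tol, NULL,
                                          current_window_error = 0.5))
  expect_identical(res$net$ref_w, net$ref_w)
  expect_false(res$event$tumbled)
  # and stays frozen while error remains below tolerance
  res2 <- pctsim:::with_seed(1, reorg_step(res$net, rc_tol, res$state, 0.8))
  expect_identical(res2$net$ref_w, net$ref_w)

  # tumble: error increase of 2 with coefficient 0.1 gives step norm 0.2
  st <- list(previous_window_error = 1, direction = c(0, 0), step_size = 0)
  res3 <- pctsim:::with_seed(5, reorg_step(net, rc, st, 3))
  expect_true(res3$event$tumbled)
  delta <- as.numeric(res3$net$ref_w[[2]] - net$ref_w[[2]])
  expect_equal(sqrt(sum(delta^2)), 0.2, tolerance = 1e-12)
  # run: error decrease keeps direction and step size
  res4 <- pctsim:::with_seed(99, reorg_step(res3$net, rc, res3$state, 2.5))
  expect_false(res4$event$tumbled)
  delta2 <- as.numeric(res4$net$ref_w[[2]] - res3$net$ref_w[[2]])
  expect_equal(delta2 / sqrt(sum(delta2^2)), res3$state$direction,
               tolerance = 1e-12)
  expect_equal(res4$event$step_size, res3$event$step_size)
})

test_that("only the targeted parameter set changes", {
  net <- conflict_architecture(w_top = c(1, 2), w_low = c(1.5, 2.5))
  st <- list(previous_window_error = 0, direction = c(0, 0), step_size = 0)
  top <- pctsim:::with_seed(3, reorg_step(
    net, reorg_config(target_set = "top_level_weights",
                      step_coefficient = 0.01), st, 5
  ))
  expect_false(identical(top$net$ref_w[[2]], net$ref_w[[2]]))
  expect_identical(top$net$ref_w[[1]], net$ref_w[[1]])
  expect_identical(top$net$levels, net$levels)
  mid <- pctsim:::with_seed(3, reorg_step(
    net, reorg_config(target_set = "mid_level_weights",
                      step_coefficient = 0.01), st, 5
  ))
  expect_false(identical(mid$net$ref_w[[1]], net$ref_w[[1]]))
  expect_identical(mid$net$ref_w[[2]], net$ref_w[[2]])
  gains <- pctsim:::with_seed(3, reorg_step(
    net, reorg_config(target_set = "mid_level_gains",
                      step_coefficient = 0.01), st, 5
  ))
  expect_false(identical(gains$net$levels[[2]]$ko, net$levels[[2]]$ko))
  expect_identical(gains$net$ref_w, net$ref_w)
  none <- reorg_step(net, reorg_config(target_set = "none"), NULL, 5)
  expect_identical(none$net, net)
})

test_that("step size is proportional to the error increase, capped", {
  net <- conflict_architecture(w_top = c(1, 2), w_low = c(1, 2))
  rc <- reorg_config(step_coefficient = 0.05, max_step = 10,
                     target_set = "top_level_weights")
  for (dE in c(0.5, 2, 7)) {
    st <- list(previous_window_error = 1, direction = c(0, 0),
               step_size = 0)
    res <- pctsim:::with_seed(8, reorg_step(net, rc, st, 1 + dE))
    delta <- as.numeric(res$net$ref_w[[2]] - net$ref_w[[2]])
    expect_equal(sqrt(sum(delta^2)) / dE, 0.05, tolerance = 1e-10)
  }
  capped <- reorg_config(step_coefficient = 0.05, max_step = 0.01,
                         target_set = "top_level_weights")
  st <- list(previous_window_error = 0, direction = c(0, 0), step_size = 0)
  res <- pctsim:::with_seed(8, reorg_step(net, capped, st, 100))
  delta <- as.numeric(res$net$ref_w[[2]] - net$ref_w[[2]])
  expect_equal(sqrt(sum(delta^2)), 0.01, tolerance = 1e-10)
})

test_that("perturbed parameters are clipped to the configured bound", {
  net <- conflict_architecture(w_top = c(99.99, 99.99), w_low = c(1, 2))
  rc <- reorg_config(step_coefficient = 10, bound = 100,
                     target_set = "top_level_weights")
  st <- list(previous_window_error = 0, direction = c(0, 0), step_size = 0)
  res <- pctsim:::with_seed(42, reorg_step(net, rc, st, 100))
  expect_true(all(abs(res$net$ref_w[[2]]) <= 100))
})

test_that("run_with_reorg is deterministic and logs its decisions", {
  net <- build_three_level_conflict(21)
  env <- loop_environment(disturbance = generate_disturbance(
    "pseudorandom", 2000, amplitude = 1, seed = 21
  ))
  rc <- reorg_config(window = 100, step_coefficient = 0.005,
                     target_set = "top_level_weights", max_step = 0.3)
  r1 <- run_with_reorg(net, env, 2000, rc, seed = 5)
  r2 <- run_with_reorg(net, env, 2000, rc, seed = 5)
  expect_identical(r1$trace, r2$trace)
  expect_identical(r1$events, r2$events)
  expect_equal(nrow(r1$events), 20)
  expect_true(any(r1$events$tumbled))
  # the final network differs from the initial one in the targeted weights
  expect_false(identical(r1$net$ref_w[[2]], net$ref_w[[2]]))
  expect_identical(r1$net$ref_w[[1]], net$ref_w[[1]])
})

test_that("fast conflict simulator matches the generic engine", {
  net <- build_three_level_conflict(42)
  d <- generate_disturbance("pseudorandom", 1500, amplitude = 1, seed = 42)
  env <- loop_environment(disturbance = d)
  em_generic <- pctsim:::trace_error_matrix(propagate(net, env, 1500))
  fast <- pctsim:::simulate_conflict_fast(net, env, 1500)
  expect_equal(unname(em_generic), unname(fast$E), tolerance = 1e-12)
  rc <- reorg_config(window = 100, step_coefficient = 0.005,
                     target_set = "mid_level_weights", max_step = 0.3)
  g <- pctsim:::with_seed(7, pctsim:::simulate_network(net, env, 1500,
                                                       reorg = rc))
  f <- pctsim:::with_seed(7, pctsim:::simulate_conflict_fast(net, env, 1500,
                                                             rc))
  expect_equal(unname(do.call(cbind, g$E)), unname(f$E), tolerance = 1e-12)
  expect_equal(g$events, f$events)
})
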