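test_that("conflict experiment is paired, structured and reproducible", {
  ex <- run_conflict_reorg_experiment(n_agents = 6, iterations = 2000,
                                      window = 200, seed = 2)
  expect_s3_class(ex$final, "tbl_df")
  expect_equal(nrow(ex$final), 18) # 6 agents x 3 conditions
  expect_equal(sum(ex$final$condition == "none"), 6)
  expect_true(all(ex$final$final_wmrse[!ex$final$divergent] >= 0))
  expect_true(all(ex$final$n_tumbles[ex$final$condition == "none"] == 0,
                  na.rm = TRUE))
  ex2 <- run_conflict_reorg_experiment(n_agents = 6, iterations = 2000,
                                       window = 200, seed = 2)
  expect_identical(ex$final, ex2$final)
  expect_identical(ex$trajectories, ex2$trajectories)
  ord <- condition_ordering_test(ex)
  expect_equal(ord$comparison, c("top < mid", "mid < none"))
  expect_true(all(ord$p_value >= 0 & ord$p_value <= 1))
})

test_that("without reorganization a conflicted agent does not improve", {
  ex <- run_conflict_reorg_experiment(n_agents = 4, conditions = "none",
                                      iterations = 3000, seed = 6,
                                      trajectory_stride = 10)
  for (a in unique(ex$trajectories$agent)) {
    tr <- ex$trajectories[ex$trajectories$agent == a, ]
    early <- mean(tr$wmrse[tr$window_start <= 1000 &
                             tr$window_start > 500])
    late <- mean(tr$wmrse[tr$window_start > 2000])
    expect_equal(late, early, tolerance = 0.15)
  }
})

test_that("two-agent demo classifies the three gain regimes", {
  low_low <- run_two_agent_conflict(0.5, 0.5)
  expect_equal(low_low$outcome, "goals_met")
  expect_lt(low_low$err_a, 0.05 * 10)
  low_high <- run_two_agent_conflict(0.5, 15)
  expect_equal(low_high$outcome, "blocked")
  high_high <- run_two_agent_conflict(15, 15)
  expect_equal(high_high$outcome, "oscillation")
  expect_gt(high_high$late_variance, 0.10 * 10^2)
  expect_error(run_two_agent_conflict(-1, 1), class = "pctsim_config_error")
})

test_that("approach-avoidance settles at the gain-weighted compromise", {
  aa <- run_approach_avoidance(g_safe = 3, r_safe = 10, g_approach = 1,
                               r_approach = 2)
  expect_equal(aa$equilibrium, 8, tolerance = 1e-3)
  expect_equal(aa$virtual_reference, 8)
  # stronger defensive gain pulls the compromise toward the safe distance
  strong <- run_approach_avoidance(g_safe = 10, r_safe = 10,
                                   g_approach = 0.5, r_approach = 2)
  expect_gt(strong$equilibrium, 9)
  expect_gt(strong$relative_position, 0.9)
  expect_error(run_approach_avoidance(r_safe = 2, r_approach = 5),
               class = "pctsim_config_error")
})

test_that("equal references remove the conflict entirely", {
  aa <- run_approach_avoidance(g_safe = 2, r_safe = 5 + 1e-9,
                               g_approach = 7, r_approach = 5)
  expect_equal(aa$equilibrium, 5, tolerance = 1e-6)
})

test_that("compromise equilibrium matches the closed form over random draws", {
  pctsim:::with_seed(31, {
    for (i in 1:25) {
      g1 <- runif(1, 0.5, 5)
      g2 <- runif(1, 0.5, 5)
      ra <- runif(1, 0, 5)
      rs <- ra + runif(1, 0.5, 10)
      eta <- min(0.05, 1 / (g1 + g2))
      aa <- run_approach_avoidance(g_safe = g1, r_safe = rs,
                                   g_approach = g2, r_approach = ra,
                                   eta = eta, iterations = 4000)
      expect_equal(aa$equilibrium, (g1 * rs + g2 * ra) / (g1 + g2),
                   tolerance = 1e-3)
    }
  })
})

test_that("therapy cohort: zero baseline stays at zero, scores stay in scale", {
  cc <- cohort_config(n_cases = 50, n_sessions = 10, baseline_mean = 0,
                      baseline_sd = 0, rng_seed = 1)
  res <- simulate_therapy_cohort(cc)
  expect_true(all(res$scores == 0))
  res2 <- simulate_therapy_cohort(cohort_config(n_cases = 400,
                                                rng_seed = 2))
  expect_true(all(res2$scores >= 0 & res2$scores <= 40))
  expect_equal(dim(res2$scores), c(400, 26))
  # reruns with the same seed are identical
  res3 <- simulate_therapy_cohort(cohort_config(n_cases = 400,
                                                rng_seed = 2))
  expect_identical(res2$scores, res3$scores)
})

test_that("cohort change decelerates: early changes exceed late ones", {
  res <- simulate_therapy_cohort(cohort_config(n_cases = 1000,
                                               rng_seed = 1))
  s <- summarize_trajectories(res)
  expect_gt(s$early_mean_abs_change, s$late_mean_abs_change)
  expect_lt(s$fits$rmse[s$fits$model == "exponential_decay"],
            s$fits$rmse[s$fits$model == "linear"])
  expect_false(s$degenerate)
})

test_that("trajectory summary recovers an exact exponential and flags
           constant cohorts", {
  t <- 1:20
  exact <- matrix(rep(12 * exp(-0.3 * (t - 1)) + 4, each = 5), 5,
                  byrow = FALSE)
  s <- summarize_trajectories(exact)
  expect_lt(s$fits$rmse[1], s$fits$rmse[2])
  expect_lt(s$fits$rmse[1], 0.01)
  flat <- matrix(15, 10, 8)
  sf <- summarize_trajectories(flat)
  expect_true(sf$degenerate)
  expect_equal(sf$fits$rmse, c(0, 0))
})

test_that("sudden-gain detector follows its documented rule exactly", {
  series <- c(30, 29, 28, 27, 17, 16, 16, 15)
  expect_equal(detect_sudden_gains(series, drop_threshold = 8,
                                   stability_window = 2), 4L)
  # rebound cancels the gain
  expect_length(detect_sudden_gains(c(30, 20, 30, 30, 30),
                                    drop_threshold = 8,
                                    stability_window = 2), 0)
  expect_length(detect_sudden_gains(rep(20, 10)), 0)
  expect_warning(out <- detect_sudden_gains(c(30, 20), drop_threshold = 8),
                 "too short")
  expect_length(out, 0)
})

test_that("early-response detector follows its documented rule exactly", {
  expect_true(detect_early_response(c(30, 23, 22, 25, 25)))
  expect_false(detect_early_response(c(30, 28, 27, 10, 10)))
  expect_false(detect_early_response(rep(10, 5)))
})

test_that("default cohort exhibits both clinical change patterns", {
  res <- simulate_therapy_cohort(cohort_config(n_cases = 500, rng_seed = 1))
  g <- glance(res)
  expect_gt(g$early_response_rate, 0)
  expect_gt(g$sudden_gain_rate, 0)
  expect_lt(g$final_mean, g$baseline_mean)
})
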