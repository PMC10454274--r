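test_that("enumerated probabilities conserve mass and degenerate configs match the trace", {
  small <- staircase_rule(total_transitions = 3, transitions_used = 2,
                          max_trials = 200)
  # step profile: a single deterministic trajectory carries all the mass
  p_step <- as.numeric(default_ladder()$widths >= 2)
  d <- exact_staircase_distribution(p_step, small, trial_horizon = 40)
  expect_equal(nrow(d$outcomes), 1)
  expect_equal(d$outcomes$prob, 1)
  expect_equal(d$outcomes$trials, 12)
  expect_equal(d$outcomes$threshold_mm, 1.75)
  expect_equal(d$outcomes$transitions, "1.5,2,1.5")

  # flat profile at the equilibrium probability: mass conserved and the
  # expected fraction of correct responses equals the equilibrium value
  d2 <- exact_staircase_distribution(rep(2^(-1 / 2), 11), small,
                                     trial_horizon = 90)
  expect_gte(d2$mass_accounted, 1 - 1e-6)
  expect_lte(sum(d2$outcomes$prob), 1 + 1e-12)
  expect_equal(d2$expected_fraction_correct, 2^(-1 / 2), tolerance = 1e-9)

  # an undersized horizon is reported, not silently truncated
  expect_error(exact_staircase_distribution(rep(2^(-1 / 2), 11), small,
                                            trial_horizon = 12),
               "trial_horizon")
  expect_error(exact_staircase_distribution(rep(0.7, 11),
                                            staircase_rule(total_transitions = 5)),
               "total_transitions")
})

test_that("Monte-Carlo staircase runs match exact enumeration within 3 SE", {
  ladder <- default_ladder()
  configs <- list(
    list(p = rep(0.75, 11),
         rule = staircase_rule(total_transitions = 2, transitions_used = 2,
                               max_trials = 200),
         horizon = 80),
    list(p = p_correct(psychometric_observer(1.5, 4, lapse = 0.02),
                       ladder$widths),
         rule = staircase_rule(total_transitions = 3, transitions_used = 2,
                               max_trials = 200),
         horizon = 80),
    list(p = rep(0.6, 11),
         rule = staircase_rule(total_transitions = 4, transitions_used = 3,
                               max_trials = 300),
         horizon = 120))
  set.seed(41)
  for (cfg in configs) {
    exact <- exact_staircase_distribution(cfg$p, cfg$rule, ladder,
                                          trial_horizon = cfg$horizon)
    mc <- mc_staircase_stats(cfg$p, cfg$rule, ladder, n_sessions = 2000)
    se_tri <- sd(mc$tri) / sqrt(length(mc$tri))
    se_est <- sd(mc$est) / sqrt(length(mc$est))
    expect_lt(abs(mean(mc$tri) - exact$expected_trials), 3 * se_tri)
    expect_lt(abs(mean(mc$est) - exact$estimator_mean), 3 * se_est)
  }
})

test_that("cohort runs are deterministic under a fixed seed and never drop observers", {
  spec <- cohort_spec(n_observers = 8, seed = 61)
  a <- run_cohort(spec)
  b <- run_cohort(spec)
  expect_identical(a$observers, b$observers)
  expect_equal(nrow(a$observers), 8)
  expect_equal(sum(a$path_counts), 8)
  # aggregates are recomputable from the per-observer records
  measured <- a$observers$threshold_mm[!is.na(a$observers$threshold_mm)]
  expect_equal(a$mean_threshold_mm, mean(measured))
})

test_that("a degenerate steep cohort concentrates at the rung-gap midpoint", {
  # Identical near-step observers with the 70.71% point midway between the
  # 1.5 and 2 mm rungs.  The 2AFC guessing floor still allows occasional
  # lucky descents below 1.5 mm, so estimates concentrate at 1.75 mm with a
  # small downward spread rather than being exactly deterministic.
  spec <- cohort_spec(n_observers = 12, threshold_mean = 1.75,
                      threshold_sd = 0, slope_mean = 200, slope_sd = 0,
                      lapse = 0, seed = 3)
  summ <- run_cohort(spec)
  expect_true(all(summ$observers$threshold_mm >= 1.25))
  expect_true(all(summ$observers$threshold_mm <= 2))
  expect_lt(abs(summ$mean_threshold_mm - 1.75), 0.15)
  expect_lt(summ$sd_threshold_mm, 0.15)
})

test_that("a uniformly competent cohort never fails training", {
  spec <- cohort_spec(n_observers = 23, threshold_mean = 1.5,
                      threshold_sd = 0.3, threshold_bounds = c(1, 2),
                      slope_mean = 4, slope_sd = 0.5, lapse = 0.02, seed = 19)
  summ <- run_cohort(spec)
  expect_equal(as.integer(summ$path_counts[["fail"]]), 0)
  expect_equal(as.integer(summ$path_counts[["pass_4mm"]]), 23)
})

test_that("bias study is reproducible and tight where the ladder is kind", {
  one <- bias_study(1.75, slope = 40, lapse = 0, reps = 400, seed = 5)
  # truth midway between the 1.5 and 2 mm rungs, near-step observer: the
  # staircase oscillates across the gap.  Upward excursions above 2 mm are
  # impossible (p = 1 there) while the 0.5 guessing floor permits occasional
  # descents below 1.5 mm, so a small downward bias within the lower rung
  # spacing remains.
  expect_lt(abs(one$bias_mm), 0.15)
  expect_lt(one$rmse_mm, 0.25)
  expect_equal(one$n_incomplete, 0)
  again <- bias_study(1.75, slope = 40, lapse = 0, reps = 1, seed = 5)
  again2 <- bias_study(1.75, slope = 40, lapse = 0, reps = 1, seed = 5)
  expect_identical(again, again2)
})
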