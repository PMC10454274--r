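test_that("balanced orientation sequences are pairwise balanced and reproducible", {
  s10 <- balanced_orientation_sequence(10, seed = 3)
  expect_equal(sum(s10 == 1), 5)
  expect_equal(sum(s10 == 2), 5)
  # every consecutive pair holds one of each
  pairs <- matrix(s10, nrow = 2)
  expect_true(all(colSums(pairs) == 3))
  expect_length(balanced_orientation_sequence(1), 1)
  expect_identical(balanced_orientation_sequence(25, seed = 8),
                   balanced_orientation_sequence(25, seed = 8))
  s110 <- balanced_orientation_sequence(110, seed = 4)
  expect_equal(as.integer(table(s110)), c(55L, 55L))
  expect_equal(orientation_label(c(1, 2)), c("vertical", "horizontal"))
})

test_that("practice concludes each phase at three consecutive correct answers", {
  rec <- practice_session(step_observer(0), seed = 1)
  expect_equal(nrow(rec), 6)
  expect_equal(as.integer(table(rec$session)[c("practice_open", "practice_blind")]),
               c(3L, 3L))
  expect_true(all(rec$correct))

  # an early error resets the consecutive counter: wrong,right,right,right
  sc <- scripted_observer(c(rep(TRUE, 3), c(FALSE, TRUE, TRUE, TRUE)))
  rec2 <- practice_session(sc, seed = 1)
  expect_equal(sum(rec2$session == "practice_blind"), 4)

  # a responder that never strings three together hits the cap and signals
  expect_error(practice_session(scripted_observer(rep(c(TRUE, TRUE, FALSE), 40)),
                                seed = 1),
               class = "jvp_practice_failure")
})

test_that("training schedule is the 110-trial double sweep", {
  sched <- training_schedule(default_ladder())
  expect_length(sched, 110)
  expect_equal(sched[1:10], rep(4, 10))
  expect_equal(sched[51:60], rep(1.25, 10))
  counts <- table(sched)
  expect_equal(counts[["1.25"]], 10)
  for (w in c("4", "3", "2.5", "2", "1.5")) expect_equal(counts[[w]], 20)
  expect_equal(sched[seq(5, 110, by = 10)],
               c(4, 3, 2.5, 2, 1.5, 1.25, 1.5, 2, 2.5, 3, 4))
  # a ladder missing a scheduled width is rejected
  expect_error(training_schedule(dome_ladder(c(5, 3, 2, 1))), "not on the ladder")
})

test_that("training gates on the 20-trial checks with a strict 75% rule", {
  set.seed(12)
  # 16/20 at 4 mm passes directly
  tr <- training_session(scripted_observer(c(rep(TRUE, 110),
                                             n_correct_vec(16, 20))))
  expect_equal(tr$outcome$path, "pass_4mm")
  expect_equal(tr$outcome$accuracy_4mm, 0.8)
  expect_equal(nrow(tr$records), 130)

  # 13/20 at 4 mm then 20/20 at 5 mm passes on the coarser dome
  tr2 <- training_session(scripted_observer(c(rep(TRUE, 110),
                                              n_correct_vec(13, 20),
                                              rep(TRUE, 20))))
  expect_equal(tr2$outcome$path, "pass_5mm")
  expect_equal(tr2$outcome$accuracy_5mm, 1)

  # 13/20 then 14/20 fails both checks
  tr3 <- training_session(scripted_observer(c(rep(TRUE, 110),
                                              n_correct_vec(13, 20),
                                              n_correct_vec(14, 20))))
  expect_equal(tr3$outcome$path, "fail")
  expect_equal(nrow(tr3$records), 150)

  # exactly 75% is not "higher than 75%": the 5-mm check must run
  tr4 <- training_session(scripted_observer(c(rep(TRUE, 110),
                                              n_correct_vec(15, 20),
                                              rep(TRUE, 20))))
  expect_equal(tr4$outcome$accuracy_4mm, 0.75)
  expect_equal(tr4$outcome$path, "pass_5mm")
})

test_that("training sweep responses are logged but never gated", {
  # all 110 sweep responses wrong, yet a clean 4-mm check still passes
  tr <- training_session(scripted_observer(c(rep(FALSE, 110), rep(TRUE, 20))))
  expect_equal(tr$outcome$path, "pass_4mm")
  sweep <- tr$records[tr$records$session == "training", ]
  expect_equal(nrow(sweep), 110)
  expect_false(any(sweep$correct))
})

test_that("a completed testing session has exactly eight transitions", {
  set.seed(21)
  for (i in 1:5) {
    res <- testing_session(psychometric_observer(runif(1, 1, 2.5), 4))
    expect_equal(sum(res$records$transition), 8)
    expect_length(res$transitions, 8)
    expect_equal(res$estimate$threshold_mm,
                 mean(tail(res$transitions, 6)))
  }
})

test_that("a perfect responder pins the floor and exceeds the trial cap", {
  err <- tryCatch(testing_session(step_observer(0)),
                  jvp_incomplete_session = function(e) e)
  expect_s3_class(err, "jvp_incomplete_session")
  expect_equal(nrow(err$records), 200)
  expect_equal(tail(err$records$width_mm, 1), 0.35)
  expect_lte(length(err$state$transitions), 1)
})

test_that("every protocol run ends in exactly one total outcome", {
  # measured
  res <- run_protocol(psychometric_observer(1.5, 4), seed = 2)
  expect_equal(res$estimate$outcome, "measured")
  # ceiling: fails both checks, never enters testing
  sc <- scripted_observer(protocol_script(n_correct_vec(13, 20),
                                          n_correct_vec(14, 20)))
  res2 <- run_protocol(sc, seed = 2)
  expect_equal(res2$estimate$outcome, "ceiling_recorded")
  expect_equal(res2$estimate$threshold_mm, 5)
  expect_length(res2$estimate$transition_values, 0)
  expect_equal(sum(res2$records$session == "testing"), 0)
  # explicit signal: perfect responder cannot terminate the staircase
  expect_error(run_protocol(step_observer(0), seed = 2),
               class = "jvp_incomplete_session")
})

test_that("trial accounting: a 4-mm pass run is 6 + 110 + 20 + testing trials", {
  res <- run_protocol(step_observer(2), seed = 9)
  expect_equal(res$training_outcome$path, "pass_4mm")
  counts <- table(res$records$session)
  expect_equal(as.integer(counts[c("practice_open", "practice_blind",
                                   "training", "training_check", "testing")]),
               c(3L, 3L, 110L, 20L, 20L))
  expect_equal(nrow(res$records), 6 + 110 + 20 + 20)
  # trial indices appear exactly once per session
  by_session <- split(res$records$trial_index, res$records$session)
  for (ix in by_session) expect_equal(sort(ix), seq_along(ix))
})

test_that("a competent observer passes training at 4 mm with high probability", {
  # p(correct at 4 mm) for the cohort default is ~0.97; P(>15/20) > 0.999.
  # 200 seeded protocol runs must all take the pass_4mm path.
  set.seed(17)
  obs <- psychometric_observer(1.5, 4, lapse = 0.02)
  expect_gt(p_correct(obs, 4), 0.9)
  paths <- replicate(200, {
    run_protocol(obs)$training_outcome$path
  })
  expect_true(all(paths == "pass_4mm"))
})
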