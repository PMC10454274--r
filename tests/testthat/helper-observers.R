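# Shared fixtures for the test suite.  All fixtures are built in code.

# Drive a staircase with an explicit correctness sequence and return the
# full state history; independent of testing_session()'s bookkeeping.
trace_staircase <- function(correct_seq, rule = staircase_rule(),
                            ladder = default_ladder()) {
  state <- staircase_state(rule, ladder)
  states <- list()
  for (ok in correct_seq) {
    state <- staircase_update(state, ok, rule, ladder)
    states[[length(states) + 1L]] <- state
    if (staircase_complete(state, rule)) break
  }
  states
}

# Correctness script for a full protocol run: practice (2 x 3 correct),
# the 110-trial sweep, then the given 20-trial check outcomes.
protocol_script <- function(check1_correct, check2_correct = NULL) {
  s <- c(rep(TRUE, 6), rep(TRUE, 110), check1_correct)
  if (!is.null(check2_correct)) s <- c(s, check2_correct)
  s
}

n_correct_vec <- function(n_correct, n_total) {
  sample(c(rep(TRUE, n_correct), rep(FALSE, n_total - n_correct)))
}

# Monte-Carlo estimate of trial-count and estimator moments for a staircase
# configuration, driven by per-level correct probabilities.
mc_staircase_stats <- function(p_by_level, rule, ladder = default_ladder(),
                               n_sessions = 2000) {
  est <- numeric(n_sessions); tri <- integer(n_sessions)
  correct_fn <- function(w, lev) runif(1) < p_by_level[lev]
  for (i in seq_len(n_sessions)) {
    run <- jvpdome:::run_staircase(correct_fn, rule, ladder)
    stopifnot(run$completed)
    est[i] <- mean(tail(run$transitions, rule$transitions_used))
    tri[i] <- run$trials
  }
  list(est = est, tri = tri)
}
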