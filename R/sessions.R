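#' Balanced random orientation sequence
#'
#' Stimulus orientations are drawn as independently shuffled
#' (vertical, horizontal) pairs, truncated to `n`.  Every consecutive pair
#' contains one vertical and one horizontal stimulus, so counts over any even
#' prefix are exactly balanced while the order stays unpredictable.
#'
#' @param n Number of orientations to generate (>= 1).
#' @param seed Optional integer seed for reproducibility.
#' @return Integer vector of codes, 1 = vertical, 2 = horizontal.
#' @examples
#' table(balanced_orientation_sequence(110, seed = 1))  # 55 / 55
#' @export
balanced_orientation_sequence <- function(n, seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  pairs <- vapply(seq_len(ceiling(n / 2)),
                  function(i) sample(c(1L, 2L)), integer(2))
  as.integer(pairs)[seq_len(n)]
}

#' Orientation label for a record code
#'
#' @param code Orientation code(s), 1 or 2.
#' @return `"vertical"` for 1, `"horizontal"` for 2.
#' @export
orientation_label <- function(code) {
  stopifnot(all(code %in% c(1L, 2L)))
  c("vertical", "horizontal")[as.integer(code)]
}

trial_row <- function(session, trial_index, width_mm, stimulus_code,
                      response_code, transition = FALSE) {
  data.frame(session = session, trial_index = as.integer(trial_index),
             width_mm = width_mm, stimulus_code = as.integer(stimulus_code),
             response_code = as.integer(response_code),
             correct = stimulus_code == response_code,
             transition = transition, stringsAsFactors = FALSE)
}

# Run one practice phase: 4-mm stimuli until `needed` consecutive correct
# answers, bounded by `cap` attempts.
practice_phase <- function(responder, phase, width_mm, needed, cap,
                           open_view) {
  stimuli <- balanced_orientation_sequence(cap)
  rows <- vector("list", cap)
  streak <- 0L
  i <- 0L
  while (streak < needed) {
    if (i >= cap) {
      stop(errorCondition(
        sprintf("practice phase '%s' not completed within %d attempts",
                phase, cap),
        class = c("jvp_practice_failure", "error")))
    }
    i <- i + 1L
    stim <- stimuli[i]
    resp <- respond(responder, width_mm, stim, open_view = open_view)
    streak <- if (resp == stim) streak + 1L else 0L
    rows[[i]] <- trial_row(phase, i, width_mm, stim, resp)
  }
  do.call(rbind, rows[seq_len(i)])
}

#' Practice session
#'
#' Two phases at the 4-mm dome: first with the stimulus in open view, then
#' blind behind the screening box.  Each phase concludes after three
#' consecutive correct answers; a phase that has not concluded within
#' `attempt_cap` trials aborts the protocol with a practice-failure
#' condition.
#'
#' @param responder An observer object (see [psychometric_observer()]) or any
#'   object with a [respond()] method.
#' @param width_mm Practice dome width, mm.
#' @param needed_consecutive Consecutive correct answers that conclude each
#'   phase.
#' @param attempt_cap Maximum trials per phase before the practice-failure
#'   signal (class `jvp_practice_failure`).
#' @param seed Optional integer seed.
#' @return A data frame of trial records with sessions `practice_open` and
#'   `practice_blind`.
#' @export
practice_session <- function(responder, width_mm = 4,
                             needed_consecutive = 3L, attempt_cap = 30L,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rbind(
    practice_phase(responder, "practice_open", width_mm, needed_consecutive,
                   attempt_cap, open_view = TRUE),
    practice_phase(responder, "practice_blind", width_mm, needed_consecutive,
                   attempt_cap, open_view = FALSE))
}

#' Training sweep schedule
#'
#' The familiarisation sweep presents every dome from `from_mm` down to
#' `to_mm` and then back up to `from_mm` (the turn-around dome is not
#' repeated), `reps` consecutive trials per dome.  With the default ladder
#' this is 4, 3, 2.5, 2, 1.5, 1.25 mm and back: 11 dome blocks, 110 trials.
#'
#' @param ladder A [dome_ladder()] containing `from_mm` and `to_mm`.
#' @param from_mm Coarsest dome of the sweep, mm.
#' @param to_mm Finest dome of the sweep, mm.
#' @param reps Trials per dome block.
#' @return Numeric vector of groove widths, one per scheduled trial.
#' @examples
#' length(training_schedule(default_ladder()))  # 110
#' @export
training_schedule <- function(ladder = default_ladder(), from_mm = 4,
                              to_mm = 1.25, reps = 10L) {
  i_from <- ladder_index(ladder, from_mm)
  i_to <- ladder_index(ladder, to_mm)
  if (i_from >= i_to) {
    stop("`from_mm` must be coarser than `to_mm`", call. = FALSE)
  }
  down <- ladder$widths[i_from:i_to]
  sweep <- c(down, rev(down)[-1])
  rep(sweep, each = as.integer(reps))
}

#' Training session with accuracy gating
#'
#' Runs the 110-trial familiarisation sweep (responses are logged but never
#' gated), then a 20-trial accuracy check at the 4-mm dome.  Accuracy
#' strictly above 75% passes (`pass_4mm`).  Otherwise a second 20-trial
#' check at the 5-mm dome follows: strictly above 75% passes (`pass_5mm`),
#' and failing both ends the task — the caller records the threshold at the
#' 5-mm ceiling.
#'
#' @inheritParams practice_session
#' @param ladder A [dome_ladder()].
#' @param check_trials Trials per accuracy check.
#' @param pass_accuracy Accuracy that must be strictly exceeded to pass a
#'   check.
#' @param check_widths_mm Widths of the first and second accuracy check, mm.
#' @return A list of class `training_result`: `outcome` (list with `path`
#'   in `pass_4mm` / `pass_5mm` / `fail` and the check accuracies) and
#'   `records` (trial data frame, sessions `training` and `training_check`).
#' @export
training_session <- function(responder, ladder = default_ladder(),
                             check_trials = 20L, pass_accuracy = 0.75,
                             check_widths_mm = c(4, 5), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  widths <- training_schedule(ladder)
  stimuli <- balanced_orientation_sequence(length(widths))
  sweep <- do.call(rbind, lapply(seq_along(widths), function(i) {
    resp <- respond(responder, widths[i], stimuli[i])
    trial_row("training", i, widths[i], stimuli[i], resp)
  }))

  run_check <- function(width_mm, offset) {
    stim <- balanced_orientation_sequence(check_trials)
    do.call(rbind, lapply(seq_len(check_trials), function(i) {
      resp <- respond(responder, width_mm, stim[i])
      trial_row("training_check", offset + i, width_mm, stim[i], resp)
    }))
  }

  check1 <- run_check(check_widths_mm[1], 0L)
  acc1 <- mean(check1$correct)
  if (acc1 > pass_accuracy) {
    outcome <- list(path = "pass_4mm", accuracy_4mm = acc1,
                    accuracy_5mm = NA_real_)
    records <- rbind(sweep, check1)
  } else {
    check2 <- run_check(check_widths_mm[2], check_trials)
    acc2 <- mean(check2$correct)
    outcome <- list(path = if (acc2 > pass_accuracy) "pass_5mm" else "fail",
                    accuracy_4mm = acc1, accuracy_5mm = acc2)
    records <- rbind(sweep, check1, check2)
  }
  structure(list(outcome = outcome, records = records),
            class = "training_result")
}

#' @export
print.training_result <- function(x, ...) {
  o <- x$outcome
  cat("Training session:", o$path,
      sprintf("(4 mm check %.0f%%", 100 * o$accuracy_4mm))
  if (!is.na(o$accuracy_5mm)) cat(sprintf(", 5 mm check %.0f%%", 100 * o$accuracy_5mm))
  cat(")\n")
  invisible(x)
}

#' Testing session: the two-down-one-up staircase
#'
#' Drives the staircase from `rule$start_width_mm` until
#' `rule$total_transitions` transition points are identified, then estimates
#' the threshold from the last `rule$transitions_used` of them.  Exceeding
#' `rule$max_trials` aborts with an incomplete-session condition (class
#' `jvp_incomplete_session`) carrying the partial record.
#'
#' @inheritParams practice_session
#' @param rule A [staircase_rule()].
#' @param ladder A [dome_ladder()].
#' @param stimuli Optional integer vector of orientation codes to present in
#'   order (used when replaying a recorded session); generated as a balanced
#'   random sequence when `NULL`.
#' @return A list of class `testing_result`: `records` (trial data frame
#'   with transition flags), `estimate` (a `threshold_estimate`), and
#'   `transitions` (the eight transition widths in order).
#' @examples
#' res <- testing_session(step_observer(2))
#' res$estimate$threshold_mm  # 1.75
#' @export
testing_session <- function(responder, rule = staircase_rule(),
                            ladder = default_ladder(), stimuli = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stimuli)) {
    stimuli <- balanced_orientation_sequence(rule$max_trials)
  }
  state <- staircase_state(rule, ladder)
  rows <- vector("list", rule$max_trials)
  while (!staircase_complete(state, rule)) {
    if (state$trial_count >= rule$max_trials ||
        state$trial_count >= length(stimuli)) {
      stop(errorCondition(
        sprintf("testing session incomplete: %d transitions after %d trials",
                length(state$transitions), state$trial_count),
        class = c("jvp_incomplete_session", "error"),
        records = do.call(rbind, rows[seq_len(state$trial_count)]),
        state = state))
    }
    i <- state$trial_count + 1L
    w <- ladder$widths[state$level_index]
    stim <- stimuli[i]
    resp <- respond(responder, w, stim)
    state <- staircase_update(state, resp == stim, rule, ladder)
    rows[[i]] <- trial_row("testing", i, w, stim, resp,
                           transition = state$last_transition)
  }
  records <- do.call(rbind, rows[seq_len(state$trial_count)])
  structure(list(records = records,
                 estimate = estimate_threshold(state$transitions, rule,
                                               n_trials = state$trial_count),
                 transitions = state$transitions),
            class = "testing_result")
}

#' Run the full assessment protocol
#'
#' Practice, training and testing in sequence.  A responder that fails both
#' training accuracy checks never enters the testing session; its threshold
#' is recorded at the 5-mm ceiling.  The run therefore always ends in
#' exactly one of: a measured threshold, the ceiling record, or an explicit
#' signalled failure (practice cap or incomplete testing session).
#'
#' @inheritParams testing_session
#' @return A list of class `protocol_result`: `records` (all sessions, in
#'   order), `training_outcome`, and `estimate` (a `threshold_estimate` with
#'   outcome `measured` or `ceiling_recorded`).
#' @examples
#' res <- run_protocol(psychometric_observer(1.5, 4), seed = 7)
#' res$estimate
#' @export
run_protocol <- function(responder, rule = staircase_rule(),
                         ladder = default_ladder(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  practice <- practice_session(responder)
  training <- training_session(responder, ladder)
  if (training$outcome$path == "fail") {
    records <- rbind(practice, training$records)
    est <- ceiling_estimate(ladder, n_trials = 0L)
  } else {
    testing <- testing_session(responder, rule, ladder)
    records <- rbind(practice, training$records, testing$records)
    est <- testing$estimate
  }
  structure(list(records = records, training_outcome = training$outcome,
                 estimate = est),
            class = "protocol_result")
}

#' @export
print.protocol_result <- function(x, ...) {
  cat("Grating orientation task protocol run\n")
  cat("  training path:", x$training_outcome$path, "\n")
  cat("  trials logged:", nrow(x$records), "\n")
  print(x$estimate)
  invisible(x)
}
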