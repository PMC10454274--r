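#' Staircase rule for the transformed up-down procedure
#'
#' The testing session uses a k-down-1-up staircase: after `n_down`
#' consecutive correct responses the next finer dome is presented, after
#' `n_up` consecutive errors the next coarser one.  The protocol default is
#' the two-down-one-up rule starting at the 4-mm dome, terminating at 8
#' transition (reversal) points and averaging the widths at the last 6.
#'
#' @param n_down Consecutive correct responses required to step to a finer
#'   dome.  Protocol value 2.
#' @param n_up Consecutive incorrect responses required to step to a coarser
#'   dome.  Protocol value 1.
#' @param start_width_mm Groove width of the first trial, in mm.  Must be on
#'   the ladder used.  Protocol value 4.
#' @param total_transitions Number of transition points at which the session
#'   terminates.  Protocol value 8.
#' @param transitions_used Number of terminal transitions averaged by the
#'   threshold estimator.  Protocol value 6.
#' @param max_trials Safety cap on testing-session trials; exceeding it
#'   aborts the session with an incomplete-session error rather than
#'   producing a threshold.
#'
#' @return An object of class `staircase_rule`.
#' @export
staircase_rule <- function(n_down = 2L, n_up = 1L, start_width_mm = 4,
                           total_transitions = 8L, transitions_used = 6L,
                           max_trials = 200L) {
  n_down <- as.integer(n_down); n_up <- as.integer(n_up)
  total_transitions <- as.integer(total_transitions)
  transitions_used <- as.integer(transitions_used)
  max_trials <- as.integer(max_trials)
  if (n_down < 1L || n_up < 1L) {
    stop("`n_down` and `n_up` must both be at least 1", call. = FALSE)
  }
  if (transitions_used < 1L || transitions_used > total_transitions) {
    stop("`transitions_used` must be between 1 and `total_transitions`",
         call. = FALSE)
  }
  if (max_trials < 1L) stop("`max_trials` must be positive", call. = FALSE)
  structure(list(n_down = n_down, n_up = n_up,
                 start_width_mm = as.numeric(start_width_mm),
                 total_transitions = total_transitions,
                 transitions_used = transitions_used,
                 max_trials = max_trials),
            class = "staircase_rule")
}

#' @export
print.staircase_rule <- function(x, ...) {
  cat(sprintf("%d-down-%d-up staircase: start %g mm, stop at %d transitions (last %d averaged), cap %d trials\n",
              x$n_down, x$n_up, x$start_width_mm, x$total_transitions,
              x$transitions_used, x$max_trials))
  invisible(x)
}

#' Initial staircase state
#'
#' The movement direction starts as `"down"`: the staircase begins at a
#' coarse dome expecting descent, so an error before any descent already
#' counts as a direction change and records the first transition point.
#'
#' @param rule A [staircase_rule()].
#' @param ladder A [dome_ladder()] containing `rule$start_width_mm`.
#' @return An object of class `staircase_state` with fields `level_index`,
#'   `consecutive_correct`, `consecutive_incorrect`, `direction`,
#'   `transitions`, `trial_count`, and per-trial bookkeeping `last_width_mm`
#'   and `last_transition`.
#' @export
staircase_state <- function(rule = staircase_rule(), ladder = default_ladder()) {
  stopifnot(inherits(rule, "staircase_rule"))
  structure(list(level_index = ladder_index(ladder, rule$start_width_mm),
                 consecutive_correct = 0L,
                 consecutive_incorrect = 0L,
                 direction = "down",
                 transitions = numeric(0),
                 trial_count = 0L,
                 last_width_mm = NA_real_,
                 last_transition = FALSE),
            class = "staircase_state")
}

#' Has the staircase identified all its transition points?
#'
#' @param state A `staircase_state`.
#' @param rule The governing [staircase_rule()].
#' @return `TRUE` once `total_transitions` transition points are recorded.
#' @export
staircase_complete <- function(state, rule) {
  length(state$transitions) >= rule$total_transitions
}

#' Advance the staircase by one scored trial
#'
#' Applies the k-down-1-up bookkeeping to a single trial outcome.  When the
#' consecutive-correct counter reaches `n_down` the staircase intends a move
#' to the next finer dome; when the consecutive-error counter reaches `n_up`
#' it intends a move to the next coarser dome.  An intended move whose
#' direction differs from the previous intended direction is a transition
#' point, and the width presented on the triggering trial (the extremum
#' level) is recorded.  Both counters reset on every intended move.  At the
#' ends of the ladder the level is clamped but the intended direction is
#' still updated, so direction changes at a boundary count as transitions.
#'
#' @param state Current `staircase_state` (see [staircase_state()]).
#' @param correct Logical: was the response on this trial correct?
#' @param rule The governing [staircase_rule()].
#' @param ladder The [dome_ladder()] in use.
#' @return The updated `staircase_state`.  `last_width_mm` holds the width
#'   presented on the trial just consumed and `last_transition` whether that
#'   trial produced a transition point.
#' @examples
#' st <- staircase_state()
#' st <- staircase_update(st, correct = FALSE)  # 4 mm error: first transition
#' st$transitions
#' @export
staircase_update <- function(state, correct, rule = staircase_rule(),
                             ladder = default_ladder()) {
  stopifnot(inherits(state, "staircase_state"), is.logical(correct),
            length(correct) == 1L, !is.na(correct))
  if (staircase_complete(state, rule)) {
    stop("staircase already terminated: all transition points identified",
         call. = FALSE)
  }
  w <- ladder$widths[state$level_index]
  state$trial_count <- state$trial_count + 1L
  state$last_width_mm <- w
  state$last_transition <- FALSE

  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    state$consecutive_incorrect <- 0L
  } else {
    state$consecutive_incorrect <- state$consecutive_incorrect + 1L
    state$consecutive_correct <- 0L
  }

  move <- NULL
  if (state$consecutive_correct >= rule$n_down) move <- "down"
  if (state$consecutive_incorrect >= rule$n_up) move <- "up"
  if (!is.null(move)) {
    if (!identical(move, state$direction)) {
      state$transitions <- c(state$transitions, w)
      state$last_transition <- TRUE
    }
    state$direction <- move
    state$consecutive_correct <- 0L
    state$consecutive_incorrect <- 0L
    step <- if (move == "down") 1L else -1L  # finer domes sit later in the ladder
    state$level_index <- min(max(state$level_index + step, 1L),
                             length(ladder$widths))
  }
  state
}

#' Reversal-averaged threshold estimate
#'
#' The tactile discrimination threshold is the arithmetic mean of the groove
#' widths at the last `transitions_used` transition points; the earlier ones
#' are discarded as the staircase's approach phase.
#'
#' @param transitions Numeric vector of transition-point widths in mm, in the
#'   order they occurred; its length must equal `rule$total_transitions`.
#' @param rule The governing [staircase_rule()].
#' @param n_trials Optional trial count to store as provenance.
#' @return An object of class `threshold_estimate` with fields
#'   `threshold_mm`, `transition_values`, `n_trials` and
#'   `outcome = "measured"`.
#' @examples
#' estimate_threshold(c(2.5, 1.5, 2, 1, 1.5, 1, 2, 1.25))
#' @export
estimate_threshold <- function(transitions, rule = staircase_rule(),
                               n_trials = NA_integer_) {
  stopifnot(is.numeric(transitions))
  if (length(transitions) != rule$total_transitions) {
    stop(sprintf("expected %d transition points, got %d",
                 rule$total_transitions, length(transitions)), call. = FALSE)
  }
  used <- utils::tail(transitions, rule$transitions_used)
  structure(list(threshold_mm = mean(used),
                 transition_values = used,
                 n_trials = as.integer(n_trials),
                 outcome = "measured"),
            class = "threshold_estimate")
}

# Ceiling outcome: training failed both accuracy checks, threshold recorded at
# the coarsest dome with no transition points.
ceiling_estimate <- function(ladder = default_ladder(),
                             n_trials = NA_integer_) {
  structure(list(threshold_mm = max(ladder$widths),
                 transition_values = numeric(0),
                 n_trials = as.integer(n_trials),
                 outcome = "ceiling_recorded"),
            class = "threshold_estimate")
}

#' @export
print.threshold_estimate <- function(x, ...) {
  if (x$outcome == "measured") {
    cat(sprintf("Tactile discrimination threshold: %.4g mm\n", x$threshold_mm))
    cat("  mean of transition widths:",
        paste(format(x$transition_values, trim = TRUE), collapse = ", "), "\n")
    if (!is.na(x$n_trials)) cat("  testing trials:", x$n_trials, "\n")
  } else {
    cat(sprintf("Threshold recorded at ceiling: %.4g mm (failed training checks)\n",
                x$threshold_mm))
  }
  invisible(x)
}

#' Equilibrium performance level of a k-down-1-up staircase
#'
#' For a k-down-1-up rule, a downward step needs `n_down` consecutive correct
#' responses while an upward step needs a single error, so the staircase is
#' in equilibrium at the per-trial probability of a correct response `p`
#' solving `p^n_down = 1/2`.  The two-down-one-up protocol therefore
#' converges on the stimulus level supporting 2^(-1/2) ~ 70.71% correct.
#'
#' @param n_down Down-rule count (>= 1).
#' @param n_up Up-rule count; the closed form holds for `n_up = 1` only.
#' @return The equilibrium probability of a correct response.
#' @examples
#' equilibrium_probability(2, 1)  # 0.7071068
#' @export
equilibrium_probability <- function(n_down, n_up = 1L) {
  stopifnot(is.numeric(n_down), length(n_down) == 1L, n_down >= 1)
  if (n_up != 1L) {
    stop("closed-form equilibrium is defined for n_up = 1 only", call. = FALSE)
  }
  2^(-1 / n_down)
}

# Fast staircase runner used by Monte-Carlo evaluation; no per-trial records.
# correct_fn(width_mm, level_index) must return a single logical.
run_staircase <- function(correct_fn, rule = staircase_rule(),
                          ladder = default_ladder()) {
  widths <- ladder$widths
  n_levels <- length(widths)
  lev <- ladder_index(ladder, rule$start_width_mm)
  cc <- 0L; ci <- 0L
  dir_down <- TRUE
  trans <- numeric(rule$total_transitions)
  nt <- 0L; trials <- 0L; n_correct <- 0L
  while (nt < rule$total_transitions) {
    if (trials >= rule$max_trials) {
      return(list(completed = FALSE, transitions = trans[seq_len(nt)],
                  trials = trials, n_correct = n_correct))
    }
    trials <- trials + 1L
    w <- widths[lev]
    if (isTRUE(correct_fn(w, lev))) {
      n_correct <- n_correct + 1L
      cc <- cc + 1L; ci <- 0L
    } else {
      ci <- ci + 1L; cc <- 0L
    }
    move_down <- NA
    if (cc >= rule$n_down) move_down <- TRUE
    if (ci >= rule$n_up) move_down <- FALSE
    if (!is.na(move_down)) {
      if (move_down != dir_down) {
        nt <- nt + 1L
        trans[nt] <- w
      }
      dir_down <- move_down
      cc <- 0L; ci <- 0L
      lev <- min(max(lev + if (move_down) 1L else -1L, 1L), n_levels)
    }
  }
  list(completed = TRUE, transitions = trans, trials = trials,
       n_correct = n_correct)
}
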