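#' Simulated 2AFC observers
#'
#' Observers stand in for human participants: given a groove width and the
#' true orientation of the grating, they return a reported orientation.
#' `psychometric_observer()` is the parametric model — a logistic psychometric
#' function on log groove width rising from the 0.5 guessing floor of the
#' two-alternative forced choice to a `1 - lapse` ceiling.
#' `step_observer()` is the idealised deterministic observer (always correct
#' at or above its step width, never below), `flat_observer()` answers
#' correctly with a width-independent probability, `scripted_observer()`
#' follows a prescribed correct/incorrect sequence, and `replay_observer()`
#' replays recorded orientation codes verbatim.
#'
#' @param threshold_mm Width (mm) at which the discrimination component of
#'   the psychometric function reaches half its range (p = 0.75 when
#'   `lapse = 0`).
#' @param slope Positive shape parameter of the logistic on the log-width
#'   scale; larger is steeper.
#' @param guess Lower asymptote; 0.5 for 2AFC and not normally changed.
#' @param lapse Probability of a stimulus-independent error, in \[0, 0.1\];
#'   caps the ceiling at `1 - lapse`.
#' @return An observer object; all observers share the [respond()] generic.
#' @examples
#' obs <- psychometric_observer(threshold_mm = 1.5, slope = 4)
#' p_correct(obs, c(0.5, 1.5, 5))
#' @export
psychometric_observer <- function(threshold_mm, slope, guess = 0.5,
                                  lapse = 0.02) {
  stopifnot(is.numeric(threshold_mm), threshold_mm > 0,
            is.numeric(slope), slope > 0,
            is.numeric(guess), guess >= 0, guess < 1,
            is.numeric(lapse), lapse >= 0, lapse <= 0.1)
  if (guess + lapse >= 1) stop("guess + lapse must be below 1", call. = FALSE)
  structure(list(threshold_mm = threshold_mm, slope = slope,
                 guess = guess, lapse = lapse),
            class = c("psychometric_observer", "jvp_observer"))
}

#' @param step_mm Step width in mm: correct iff `width_mm >= step_mm`.
#' @rdname psychometric_observer
#' @export
step_observer <- function(step_mm) {
  stopifnot(is.numeric(step_mm), length(step_mm) == 1L, step_mm >= 0)
  structure(list(step_mm = step_mm),
            class = c("step_observer", "jvp_observer"))
}

#' @param p Width-independent probability of a correct response.
#' @rdname psychometric_observer
#' @export
flat_observer <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 0, p <= 1)
  structure(list(p = p), class = c("flat_observer", "jvp_observer"))
}

#' @param correct Logical vector consumed one element per trial: should the
#'   scripted response be correct?
#' @rdname psychometric_observer
#' @export
scripted_observer <- function(correct) {
  stopifnot(is.logical(correct), length(correct) >= 1L, !anyNA(correct))
  env <- new.env(parent = emptyenv())
  env$correct <- correct
  env$cursor <- 0L
  structure(list(env = env), class = c("scripted_observer", "jvp_observer"))
}

#' @param responses Integer vector of recorded orientation codes (1 =
#'   vertical, 2 = horizontal) consumed one per trial, ignoring the stimulus.
#' @rdname psychometric_observer
#' @export
replay_observer <- function(responses) {
  responses <- as.integer(responses)
  stopifnot(length(responses) >= 1L, all(responses %in% c(1L, 2L)))
  env <- new.env(parent = emptyenv())
  env$responses <- responses
  env$cursor <- 0L
  structure(list(env = env), class = c("replay_observer", "jvp_observer"))
}

#' Probability of a correct orientation judgment
#'
#' @param observer An observer object.
#' @param width_mm Groove width(s) in mm, strictly positive.
#' @return Probability (vectorised over `width_mm`) of a correct response.
#' @export
p_correct <- function(observer, width_mm) UseMethod("p_correct")

#' @export
p_correct.default <- function(observer, width_mm) {
  stop("this observer has no psychometric function", call. = FALSE)
}

#' @export
p_correct.psychometric_observer <- function(observer, width_mm) {
  if (any(!is.finite(width_mm)) || any(width_mm <= 0)) {
    stop("`width_mm` must be strictly positive", call. = FALSE)
  }
  f <- stats::plogis(observer$slope *
                       (log(width_mm) - log(observer$threshold_mm)))
  observer$guess + (1 - observer$guess - observer$lapse) * f
}

#' @export
p_correct.step_observer <- function(observer, width_mm) {
  if (any(!is.finite(width_mm)) || any(width_mm <= 0)) {
    stop("`width_mm` must be strictly positive", call. = FALSE)
  }
  as.numeric(width_mm >= observer$step_mm)
}

#' @export
p_correct.flat_observer <- function(observer, width_mm) {
  if (any(!is.finite(width_mm)) || any(width_mm <= 0)) {
    stop("`width_mm` must be strictly positive", call. = FALSE)
  }
  rep(observer$p, length(width_mm))
}

# Probability of a correct answer when the observer knows the stimulus
# (open-view practice): only attention lapses remain.
p_open_view <- function(observer) UseMethod("p_open_view")
#' @export
p_open_view.psychometric_observer <- function(observer) 1 - observer$lapse
#' @export
p_open_view.default <- function(observer) 1

#' One 2AFC response
#'
#' Draws a response to a single stimulus: the true orientation with
#' probability `p_correct(observer, width_mm)`, the other orientation
#' otherwise.  The construction is orientation-symmetric — vertical and
#' horizontal gratings are equally hard.  Scripted and replay observers
#' consume their pre-recorded sequences instead and signal when exhausted.
#'
#' @param observer An observer object.
#' @param width_mm Groove width of the presented dome, mm.
#' @param stimulus_code True orientation code: 1 = vertical, 2 = horizontal.
#' @param open_view Logical: does the observer see the dome orientation
#'   (open-view practice)?  If so, the psychometric observer responds
#'   correctly except for lapses.
#' @return Reported orientation code, 1 or 2.
#' @export
respond <- function(observer, width_mm, stimulus_code, open_view = FALSE) {
  UseMethod("respond")
}

#' @export
respond.default <- function(observer, width_mm, stimulus_code,
                            open_view = FALSE) {
  stopifnot(stimulus_code %in% c(1L, 2L))
  p <- if (open_view) p_open_view(observer) else p_correct(observer, width_mm)
  if (stats::runif(1) < p) as.integer(stimulus_code) else
    other_orientation(stimulus_code)
}

#' @export
respond.scripted_observer <- function(observer, width_mm, stimulus_code,
                                      open_view = FALSE) {
  stopifnot(stimulus_code %in% c(1L, 2L))
  env <- observer$env
  env$cursor <- env$cursor + 1L
  if (env$cursor > length(env$correct)) {
    stop("scripted observer exhausted: no response left for this trial",
         call. = FALSE)
  }
  if (env$correct[env$cursor]) as.integer(stimulus_code) else
    other_orientation(stimulus_code)
}

#' @export
respond.replay_observer <- function(observer, width_mm, stimulus_code,
                                    open_view = FALSE) {
  env <- observer$env
  env$cursor <- env$cursor + 1L
  if (env$cursor > length(env$responses)) {
    stop("replay observer exhausted: no recorded response left for this trial",
         call. = FALSE)
  }
  env$responses[env$cursor]
}

#' Width at which the staircase's target performance is reached
#'
#' The two-down-one-up staircase converges on the stimulus supporting
#' 2^(-1/2) ~ 70.71% correct.  For a smooth psychometric observer this width
#' exists and is unique whenever the ceiling `1 - lapse` exceeds 2^(-1/2);
#' it is obtained by analytic inversion of the logistic.
#'
#' @param observer A [psychometric_observer()].
#' @param p_target Target probability of a correct response; defaults to the
#'   two-down-one-up equilibrium 2^(-1/2).
#' @return Groove width in mm where `p_correct` equals `p_target`.
#' @examples
#' true_convergence_width(psychometric_observer(1.5, 4, lapse = 0))
#' @export
true_convergence_width <- function(observer,
                                   p_target = equilibrium_probability(2)) {
  if (!inherits(observer, "psychometric_observer")) {
    stop("convergence width is defined for smooth psychometric observers only",
         call. = FALSE)
  }
  fr <- (p_target - observer$guess) / (1 - observer$guess - observer$lapse)
  if (fr <= 0 || fr >= 1) {
    stop(sprintf(
      "psychometric range [%.3f, %.3f] does not contain the target %.5f",
      observer$guess, 1 - observer$lapse, p_target), call. = FALSE)
  }
  observer$threshold_mm * exp(stats::qlogis(fr) / observer$slope)
}

# Inverse of true_convergence_width(): the threshold_mm parameter that puts a
# logistic observer's p_target-correct width exactly at `width_mm`.
threshold_param_for_convergence <- function(width_mm, slope, lapse = 0.02,
                                            guess = 0.5,
                                            p_target = equilibrium_probability(2)) {
  fr <- (p_target - guess) / (1 - guess - lapse)
  stopifnot(fr > 0, fr < 1)
  width_mm / exp(stats::qlogis(fr) / slope)
}

other_orientation <- function(code) 3L - as.integer(code)
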