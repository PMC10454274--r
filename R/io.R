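RECORD_COLUMNS <- c("session", "trial_index", "width_mm", "stimulus_code",
                    "response_code", "correct", "transition")
RECORD_SESSIONS <- c("practice_open", "practice_blind", "training",
                     "training_check", "testing")

#' Write and read answer record tables
#'
#' Record tables use the digital answer-record layout of the protocol: one
#' row per stimulus with the session label, trial index, groove width in mm,
#' and the stimulus/response orientation codes (1 = vertical,
#' 2 = horizontal), plus the scored correctness and the transition-point
#' flag.  The CSV round-trip is lossless; malformed files are rejected with
#' row-numbered diagnostics.
#'
#' @param records Trial record data frame as produced by the session
#'   functions (see [testing_session()]).
#' @param path File path for the CSV.
#' @return `write_record()` returns `path` invisibly; `read_record()`
#'   returns the validated record data frame.
#' @export
write_record <- function(records, path) {
  validate_record(records)
  utils::write.csv(records[, RECORD_COLUMNS], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_record
#' @export
read_record <- function(path) {
  records <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(RECORD_COLUMNS, names(records))
  if (length(missing)) {
    stop("record table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$correct <- as.logical(records$correct)
  records$transition <- as.logical(records$transition)
  validate_record(records)
  records
}

validate_record <- function(records) {
  stopifnot(is.data.frame(records))
  check_row <- function(cond, column) {
    bad <- which(!cond)
    if (length(bad)) {
      stop(sprintf("record table row %d: invalid value in column '%s'",
                   bad[1], column), call. = FALSE)
    }
  }
  check_row(records$session %in% RECORD_SESSIONS, "session")
  check_row(is.finite(records$width_mm) & records$width_mm > 0, "width_mm")
  check_row(records$stimulus_code %in% c(1L, 2L), "stimulus_code")
  check_row(records$response_code %in% c(1L, 2L), "response_code")
  check_row(!is.na(records$correct) &
              records$correct == (records$stimulus_code == records$response_code),
            "correct")
  check_row(!is.na(records$transition) &
              (!records$transition | records$session == "testing"),
            "transition")
  invisible(records)
}

#' Replay a recorded testing session through the staircase engine
#'
#' Feeds the recorded stimulus and response codes of a testing-session table
#' back through [testing_session()] via a [replay_observer()], recomputing
#' widths, correctness and transition flags from scratch.  A faithful record
#' reproduces itself trial for trial.
#'
#' @param records Record data frame containing a completed testing session.
#' @param rule,ladder Protocol configuration the record was produced under.
#' @return A `testing_result` recomputed from the recorded responses.
#' @export
replay_testing_record <- function(records, rule = staircase_rule(),
                                  ladder = default_ladder()) {
  testing <- records[records$session == "testing", , drop = FALSE]
  if (nrow(testing) == 0L) {
    stop("record table contains no testing-session rows", call. = FALSE)
  }
  testing <- testing[order(testing$trial_index), , drop = FALSE]
  testing_session(replay_observer(testing$response_code), rule, ladder,
                  stimuli = testing$stimulus_code)
}

#' Protocol configuration files
#'
#' A configuration bundles the ladder widths, the staircase rule, an
#' optional observer specification (`family` one of `"logistic"`, `"step"`,
#' `"flat"` with the matching parameters) and a seed.  The defaults
#' reproduce the standard protocol exactly.  Files are YAML or JSON by
#' extension.
#'
#' @param rule A [staircase_rule()].
#' @param ladder A [dome_ladder()].
#' @param observer Optional named list observer specification.
#' @param seed Optional integer seed.
#' @return `protocol_config()` returns a named list of class
#'   `protocol_config`; `read_protocol_config()` parses and validates a file
#'   back into one.
#' @export
protocol_config <- function(rule = staircase_rule(),
                            ladder = default_ladder(), observer = NULL,
                            seed = NULL) {
  cfg <- structure(list(ladder = ladder$widths,
                        rule = unclass(rule),
                        observer = observer,
                        seed = seed),
                   class = "protocol_config")
  validate_protocol_config(cfg)
}

validate_protocol_config <- function(cfg) {
  ladder <- dome_ladder(cfg$ladder)
  rule <- do.call(staircase_rule, cfg$rule)
  ladder_index(ladder, rule$start_width_mm)  # start width must be on ladder
  if (!is.null(cfg$observer)) {
    fam <- cfg$observer$family
    if (is.null(fam) || !fam %in% c("logistic", "step", "flat")) {
      stop("observer family must be one of 'logistic', 'step', 'flat'",
           call. = FALSE)
    }
  }
  cfg
}

#' @rdname protocol_config
#' @param path Configuration file path (`.yaml`/`.yml` or `.json`).
#' @export
read_protocol_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  defaults <- protocol_config()
  cfg <- structure(utils::modifyList(unclass(defaults), raw),
                   class = "protocol_config")
  validate_protocol_config(cfg)
}

#' @rdname protocol_config
#' @param cfg A `protocol_config`.
#' @export
write_protocol_config <- function(cfg, path) {
  cfg <- validate_protocol_config(cfg)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                         null = "null")
  } else {
    yaml::write_yaml(unclass(cfg), path)
  }
  invisible(path)
}

#' Build the observer described by a configuration
#'
#' @param spec Named list with `family` and the family's parameters:
#'   `threshold_mm`, `slope`, `lapse` (logistic); `step_mm` (step);
#'   `p` (flat).
#' @return An observer object.
#' @export
observer_from_spec <- function(spec) {
  switch(spec$family,
         logistic = psychometric_observer(spec$threshold_mm, spec$slope,
                                          lapse = spec$lapse %||% 0.02),
         step = step_observer(spec$step_mm),
         flat = flat_observer(spec$p),
         stop("unknown observer family: ", spec$family, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Polynomial rolling hash over the deparsed configuration: a short
# reproducibility fingerprint for logs and summaries, not cryptographic.
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(unclass(cfg)), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' JSON-ready summary of a protocol run
#'
#' @param result A `protocol_result` from [run_protocol()].
#' @param cfg Optional `protocol_config` to fingerprint.
#' @param seed Seed used for the run, echoed for reproducibility.
#' @return Named list with the outcome path, threshold, per-session trial
#'   counts, seed and configuration hash; write it with
#'   `jsonlite::write_json(..., auto_unbox = TRUE)`.
#' @export
session_summary <- function(result, cfg = protocol_config(), seed = NULL) {
  stopifnot(inherits(result, "protocol_result"))
  counts <- as.list(table(factor(result$records$session,
                                 levels = RECORD_SESSIONS)))
  list(outcome = result$estimate$outcome,
       training_path = result$training_outcome$path,
       threshold_mm = result$estimate$threshold_mm,
       transition_values = result$estimate$transition_values,
       trials = counts,
       total_trials = nrow(result$records),
       seed = seed,
       config_hash = config_hash(cfg))
}
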