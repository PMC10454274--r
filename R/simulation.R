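#' Specification of a simulated cohort
#'
#' Describes a population of logistic 2AFC observers from which a cohort is
#' sampled: thresholds and slopes are drawn from truncated normal
#' distributions, the lapse rate is fixed.  The defaults emulate a healthy
#' middle-aged cohort — mean threshold parameter 1.8 mm with SD 0.75 mm,
#' truncated to the ladder range — with slope mean 4 (SD 1, floored at 1)
#' and lapse 0.02 as modelling choices for quantities no human data pins
#' down.
#'
#' @param n_observers Number of simulated participants.
#' @param threshold_mean,threshold_sd Mean and SD (mm) of the observers'
#'   psychometric threshold parameter.
#' @param threshold_bounds Truncation bounds (mm) for sampled thresholds;
#'   defaults to the default ladder range.
#' @param slope_mean,slope_sd Mean and SD of the logistic slope.
#' @param slope_min Lower truncation for sampled slopes.
#' @param lapse Fixed lapse rate for all observers.
#' @param seed Optional integer seed governing the whole cohort run.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_observers = 23L, threshold_mean = 1.8,
                        threshold_sd = 0.75, threshold_bounds = c(0.35, 5),
                        slope_mean = 4, slope_sd = 1, slope_min = 1,
                        lapse = 0.02, seed = NULL) {
  stopifnot(n_observers >= 1, threshold_sd >= 0, slope_sd >= 0,
            length(threshold_bounds) == 2L,
            threshold_bounds[1] < threshold_bounds[2])
  structure(list(n_observers = as.integer(n_observers),
                 threshold_mean = threshold_mean, threshold_sd = threshold_sd,
                 threshold_bounds = threshold_bounds,
                 slope_mean = slope_mean, slope_sd = slope_sd,
                 slope_min = slope_min, lapse = lapse, seed = seed),
            class = "cohort_spec")
}

# Truncated-normal draw by rejection; degenerates to the mean when sd = 0.
rtruncnorm1 <- function(mean, sd, lower, upper) {
  if (sd == 0) return(min(max(mean, lower), upper))
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

#' Monte-Carlo evaluation of the full protocol over a simulated cohort
#'
#' Samples observers from a [cohort_spec()], runs the complete protocol —
#' practice, training with its accuracy gates, and the staircase testing
#' session — for each, and aggregates.  Practice failures and incomplete
#' testing sessions are kept as flagged per-observer outcomes, never
#' silently dropped.
#'
#' @param spec A [cohort_spec()].
#' @param rule A [staircase_rule()].
#' @param ladder A [dome_ladder()].
#' @return An object of class `protocol_summary`: per-observer data frame
#'   `observers` (sampled parameters, training path, threshold, trial
#'   counts) and aggregate fields `mean_threshold_mm`, `sd_threshold_mm`,
#'   `mean_trials`, `sd_trials` (testing-session trials of measured runs)
#'   and the `path_counts` table.
#' @export
run_cohort <- function(spec = cohort_spec(), rule = staircase_rule(),
                       ladder = default_ladder()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  rows <- vector("list", spec$n_observers)
  for (i in seq_len(spec$n_observers)) {
    th <- rtruncnorm1(spec$threshold_mean, spec$threshold_sd,
                      spec$threshold_bounds[1], spec$threshold_bounds[2])
    sl <- rtruncnorm1(spec$slope_mean, spec$slope_sd, spec$slope_min, Inf)
    obs <- psychometric_observer(th, sl, lapse = spec$lapse)
    res <- tryCatch(run_protocol(obs, rule, ladder),
                    jvp_practice_failure = function(e) e,
                    jvp_incomplete_session = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- data.frame(
        observer = i, threshold_param = th, slope = sl,
        path = if (inherits(res, "jvp_practice_failure"))
          "practice_failure" else "incomplete",
        threshold_mm = NA_real_, testing_trials = NA_integer_,
        total_trials = NA_integer_, stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(
        observer = i, threshold_param = th, slope = sl,
        path = res$training_outcome$path,
        threshold_mm = res$estimate$threshold_mm,
        testing_trials = res$estimate$n_trials,
        total_trials = nrow(res$records), stringsAsFactors = FALSE)
    }
  }
  observers <- do.call(rbind, rows)
  measured <- observers[!is.na(observers$threshold_mm), , drop = FALSE]
  tested <- measured[measured$path != "fail", , drop = FALSE]
  structure(list(
    observers = observers,
    mean_threshold_mm = mean(measured$threshold_mm),
    sd_threshold_mm = stats::sd(measured$threshold_mm),
    mean_trials = mean(tested$testing_trials),
    sd_trials = stats::sd(tested$testing_trials),
    path_counts = table(factor(observers$path,
                               levels = c("pass_4mm", "pass_5mm", "fail",
                                          "practice_failure", "incomplete"))),
    spec = spec), class = "protocol_summary")
}

#' @export
print.protocol_summary <- function(x, ...) {
  cat(sprintf("Simulated cohort of %d observers\n", nrow(x$observers)))
  cat(sprintf("  threshold: %.2f +/- %.2f mm\n",
              x$mean_threshold_mm, x$sd_threshold_mm))
  cat(sprintf("  testing trials: %.2f +/- %.2f\n", x$mean_trials, x$sd_trials))
  cat("  training paths:",
      paste(names(x$path_counts), as.integer(x$path_counts), sep = "=",
            collapse = ", "), "\n")
  invisible(x)
}

#' Exact outcome distribution of a small staircase configuration
#'
#' Exhaustively enumerates every response sequence of a k-down-1-up
#' staircase against per-level correct-response probabilities, propagating
#' exact path probabilities trial by trial and retiring sessions as they
#' complete.  Tractable for small configurations (at most 4 transition
#' points); it serves as the independent oracle against which Monte-Carlo
#' runs of the same configuration are checked.
#'
#' @param p_by_level Numeric vector of per-level probabilities of a correct
#'   response, aligned with `ladder$widths`.
#' @param rule A [staircase_rule()] with `total_transitions <= 4`.
#' @param ladder A [dome_ladder()].
#' @param trial_horizon Number of trials to enumerate; probability mass not
#'   absorbed by then must be below `mass_tol` or an error is signalled.
#' @param mass_tol Maximum unaccounted probability mass.
#' @return An object of class `staircase_distribution`: data frame
#'   `outcomes` (`trials`, `threshold_mm`, `prob`, `transitions` string),
#'   `expected_trials`, `estimator_mean`, `expected_fraction_correct`
#'   (expected correct responses over expected trials), and
#'   `mass_accounted`.
#' @export
exact_staircase_distribution <- function(p_by_level, rule,
                                         ladder = default_ladder(),
                                         trial_horizon = 40L,
                                         mass_tol = 1e-6) {
  stopifnot(inherits(rule, "staircase_rule"),
            length(p_by_level) == length(ladder$widths),
            all(p_by_level >= 0), all(p_by_level <= 1))
  if (rule$total_transitions > 4L) {
    stop("exact enumeration is supported for total_transitions <= 4",
         call. = FALSE)
  }
  widths <- ladder$widths
  L <- length(widths)
  ntot <- rule$total_transitions
  nd <- rule$n_down; nu <- rule$n_up
  nseq <- ntot - 1L          # transition level-indices carried in the state
  B <- L + 1L                # digit base for the sequence code (0 = empty)

  # States of equal trial count merge.  A state is packed into one integer:
  # level, the two run counters, the intended direction, and the sequence of
  # transition level-indices so far (base-B digits, filled left to right).
  # Each state carries its probability mass and the mass-weighted expected
  # number of correct responses.
  encode <- function(lev, cc, ci, dir, seqc) {
    (lev - 1) + L * (cc + nd * (ci + nu * (dir + 2 * seqc)))
  }
  seq_digits <- function(seqc) {
    d <- matrix(0L, nrow = length(seqc), ncol = max(nseq, 1L))
    tmp <- seqc
    for (j in seq_len(nseq)) {
      d[, j] <- tmp %% B
      tmp <- tmp %/% B
    }
    d
  }

  code <- encode(ladder_index(ladder, rule$start_width_mm), 0, 0, 1, 0)
  prob <- 1
  wc <- 0
  out <- vector("list", trial_horizon)

  for (t in seq_len(trial_horizon)) {
    if (length(code) == 0L) break
    lev <- code %% L + 1L;  r <- code %/% L
    cc  <- r %% nd;         r <- r %/% nd
    ci  <- r %% nu;         r <- r %/% nu
    dir <- r %% 2           # 1 = down (finer), 0 = up (coarser)
    seqc <- r %/% 2
    digs <- seq_digits(seqc)
    k <- rowSums(digs > 0)  # transitions recorded so far
    p <- p_by_level[lev]

    branch <- function(correct) {
      q <- if (correct) p else 1 - p
      pr <- prob * q
      cc2 <- if (correct) cc + 1 else 0 * cc
      ci2 <- if (correct) 0 * ci else ci + 1
      move_down <- cc2 >= nd
      move_up <- ci2 >= nu
      move <- move_down | move_up
      dir2 <- ifelse(move_down, 1, ifelse(move_up, 0, dir))
      transition <- move & dir2 != dir
      done <- transition & k == ntot - 1L
      # completed sessions: the width presented this trial is the final
      # transition; the estimator averages the last transitions_used widths
      est <- rep(NA_real_, length(code))
      trs <- rep(NA_character_, length(code))
      if (any(done)) {
        dd <- digs[done, , drop = FALSE]
        full <- cbind(dd[, seq_len(nseq), drop = FALSE], lev[done])
        est[done] <- rowMeans(matrix(
          widths[full[, (ntot - rule$transitions_used + 1L):ntot]],
          nrow = sum(done)))
        labels <- vapply(widths, function(x) format(x, trim = TRUE), "")
        trs[done] <- apply(matrix(labels[full], nrow = sum(done)), 1, paste,
                           collapse = ",")
      }
      seqc2 <- ifelse(transition & !done, seqc + lev * B^k, seqc)
      cc3 <- ifelse(move, 0, cc2)
      ci3 <- ifelse(move, 0, ci2)
      lev2 <- ifelse(move, pmin(pmax(lev + ifelse(move_down, 1, -1), 1), L),
                     lev)
      list(code = encode(lev2, cc3, ci3, dir2, seqc2), prob = pr,
           wc = wc * q + if (correct) pr else 0,
           done = done, est = est, trs = trs)
    }

    bc <- branch(TRUE); bw <- branch(FALSE)
    done <- c(bc$done, bw$done)
    all_code <- c(bc$code, bw$code)
    all_prob <- c(bc$prob, bw$prob)
    all_wc <- c(bc$wc, bw$wc)
    fin <- done & all_prob > 0
    if (any(fin)) {
      out[[t]] <- data.frame(trials = t,
                             prob = all_prob[fin], wc = all_wc[fin],
                             threshold_mm = c(bc$est, bw$est)[fin],
                             transitions = c(bc$trs, bw$trs)[fin],
                             stringsAsFactors = FALSE)
    }
    keep <- !done & all_prob > 0
    if (any(keep)) {
      grp <- factor(all_code[keep])
      prob <- as.numeric(rowsum(all_prob[keep], grp))
      wc <- as.numeric(rowsum(all_wc[keep], grp))
      code <- as.numeric(levels(grp))
    } else {
      code <- numeric(0); prob <- numeric(0); wc <- numeric(0)
    }
  }

  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    stop(sprintf(
      "no session completed within %d trials; increase `trial_horizon`",
      trial_horizon), call. = FALSE)
  }
  # merge completed paths sharing trial count and transition sequence
  key <- interaction(out$trials, out$transitions, drop = TRUE)
  out_trials <- as.integer(tapply(out$trials, key, `[`, 1))
  out_thr <- as.numeric(tapply(out$threshold_mm, key, `[`, 1))
  out_tr <- as.character(tapply(out$transitions, key, `[`, 1))
  out_prob <- as.numeric(tapply(out$prob, key, sum))
  out_wc <- as.numeric(tapply(out$wc, key, sum))
  ord <- order(out_trials, -out_prob)
  out_trials <- out_trials[ord]; out_thr <- out_thr[ord]
  out_tr <- out_tr[ord]; out_prob <- out_prob[ord]; out_wc <- out_wc[ord]

  mass <- sum(out_prob)
  if (1 - mass > mass_tol) {
    stop(sprintf(
      "only %.8f of the probability mass completed within %d trials; increase `trial_horizon`",
      mass, trial_horizon), call. = FALSE)
  }
  outcomes <- data.frame(trials = out_trials, threshold_mm = out_thr,
                         prob = out_prob, transitions = out_tr,
                         stringsAsFactors = FALSE)
  structure(list(outcomes = outcomes,
                 expected_trials = sum(out_prob * out_trials) / mass,
                 estimator_mean = sum(out_prob * out_thr) / mass,
                 expected_fraction_correct =
                   sum(out_wc) / sum(out_prob * out_trials),
                 mass_accounted = mass),
            class = "staircase_distribution")
}

#' @export
print.staircase_distribution <- function(x, ...) {
  cat(sprintf("Exact staircase distribution over %d outcomes (mass %.8f)\n",
              nrow(x$outcomes), x$mass_accounted))
  cat(sprintf("  expected trials %.4f, estimator mean %.4f mm\n",
              x$expected_trials, x$estimator_mean))
  invisible(x)
}

#' Bias and RMSE of the reversal-averaged estimator
#'
#' For each target width, constructs a logistic observer whose true
#' 70.71%-correct width equals the target, runs `reps` independent testing
#' sessions against it, and reports the estimator's bias (mean estimate
#' minus truth) and root-mean-square error.  On a discrete non-uniform
#' ladder the achievable resolution is bounded by the local rung spacing,
#' which is the natural scale for these errors.
#'
#' @param true_widths_mm Grid of true convergence widths, mm, within the
#'   ladder interior.
#' @param slope,lapse Observer parameters shared across the grid.
#' @param reps Testing sessions per grid point.
#' @param rule A [staircase_rule()].
#' @param ladder A [dome_ladder()].
#' @param seed Optional integer seed.
#' @return Data frame with one row per grid point: `true_width_mm`,
#'   `mean_estimate_mm`, `bias_mm`, `rmse_mm`, `mean_trials`,
#'   `n_incomplete`.
#' @export
bias_study <- function(true_widths_mm, slope = 4, lapse = 0.02, reps = 1000L,
                       rule = staircase_rule(), ladder = default_ladder(),
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(true_widths_mm, function(w) {
    th <- threshold_param_for_convergence(w, slope, lapse)
    pl <- p_correct(psychometric_observer(th, slope, lapse = lapse),
                    ladder$widths)
    correct_fn <- function(width, lev) stats::runif(1) < pl[lev]
    est <- numeric(reps); tri <- integer(reps); bad <- 0L
    for (r in seq_len(reps)) {
      run <- run_staircase(correct_fn, rule, ladder)
      if (!run$completed) { bad <- bad + 1L; est[r] <- NA; tri[r] <- NA }
      else {
        est[r] <- mean(utils::tail(run$transitions, rule$transitions_used))
        tri[r] <- run$trials
      }
    }
    ok <- !is.na(est)
    data.frame(true_width_mm = w, mean_estimate_mm = mean(est[ok]),
               bias_mm = mean(est[ok]) - w,
               rmse_mm = sqrt(mean((est[ok] - w)^2)),
               mean_trials = mean(tri[ok]), n_incomplete = bad)
  })
  do.call(rbind, rows)
}
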