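---
title: "The grating orientation protocol: model, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The grating orientation protocol: model, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jvpdome)
```

## The task and the measurement problem

The grating orientation task (GOT) measures tactile spatial acuity.  A JVP
dome — a hemisphere whose surface carries parallel grooves and bars of equal
width — is pressed onto the index fingerpad with its grating either along
(vertical) or across (horizontal) the finger's long axis, and the
participant must report which, a two-alternative forced choice (2AFC).
Narrower grooves make the judgment harder, so the groove width at which a
participant can still discriminate orientation at a criterion performance
level is a threshold of spatial acuity, in mm.

`jvpdome` implements the full assessment protocol as a reusable engine: the
discrete ladder of dome widths, a two-down-one-up staircase with
transition-point bookkeeping and a reversal-averaged threshold estimator,
the practice/training/testing session flow with its accuracy gates,
simulated observers that stand in for human participants, and exact and
Monte-Carlo machinery for validating the staircase's stochastic behaviour.

## The stimulus ladder

The default ladder has 11 domes, coarsest first:
5, 4, 3, 2.5, 2, 1.5, 1.25, 1, 0.75, 0.5, 0.35 mm.  The 5- and 4-mm domes
extend the classic JVP range upward so that middle-aged and clinical
participants remain measurable; the 2.5-mm dome smooths the otherwise
abrupt difficulty jump between 3 and 2 mm.  The ladder is deliberately
non-uniform: spacing tracks the roughly ratio-scaled difficulty of the
task, and it bounds the resolution any estimator can achieve locally.

## The staircase and its convergence point

The testing session runs a two-down-one-up transformed up-down staircase
starting at the 4-mm dome: two consecutive correct answers step to the next
finer dome, a single error steps to the next coarser one.  A *transition
point* (reversal) is a trial at which the intended movement direction
changes; the session stops at the eighth transition, and the threshold is
the arithmetic mean of the groove widths at the last six, the first two
being discarded as the approach phase.

The rule targets the performance level at which upward and downward
movements are equiprobable.  A down move requires two consecutive correct
responses (probability $p^2$), an up move one error, so equilibrium solves

$$p^2 = \tfrac{1}{2} \quad\Rightarrow\quad p = 2^{-1/2} \approx 0.70711,$$

i.e. the staircase concentrates trials at, and the estimator reports, the
groove width supporting 70.71% correct.  `equilibrium_probability(2, 1)`
computes this, and generalises to $p = 2^{-1/k}$ for a $k$-down-1-up rule.

```{r equilibrium}
equilibrium_probability(2, 1)
```

### Bookkeeping conventions

Three details of reversal bookkeeping are genuinely open in common
descriptions of the procedure; the package fixes them as follows and keeps
them configurable only where that is methodologically meaningful.

* **Which width does a transition record?**  The width presented on the
  trial whose response triggers the direction change — the extremum level —
  consistent with standard reversal bookkeeping.
* **Initial direction.**  The staircase starts "descending": it begins at a
  coarse dome expecting descent, so an error before any descent is already
  a direction change and records the first transition at the width where it
  happened.
* **Ladder boundaries.**  At 5 mm and 0.35 mm the level clamps, but the
  intended direction still updates and intended-direction changes still
  count as transitions.  This preserves the convergence logic for
  observers whose thresholds sit near the ends of the ladder.
* **Counters.**  The consecutive-correct counter resets on every intended
  move (standard transformed up-down semantics), so partial runs never
  carry across levels.

A safety cap (`max_trials`, default 200) aborts a session that cannot
terminate — for example a flawless responder, which never makes the errors
the staircase needs — with an explicit incomplete-session condition rather
than a threshold.  The deterministic reference trace is the step observer
with its step at 2 mm: it descends 4 → 1.5 mm, then oscillates, yielding
transitions (1.5, 2, 1.5, 2, 1.5, 2, 1.5, 2), threshold 1.75 mm, in exactly
20 trials.

```{r trace}
res <- testing_session(step_observer(2))
res$transitions
res$estimate
```

## Session flow and gates

A full assessment is practice, training and testing in sequence
(`run_protocol()`).

**Practice** uses the 4-mm dome in two phases — stimulus in open view, then
blind behind the screening box — each ending after three consecutive
correct answers.  The open-view phase is modelled for simulated observers
as known-stimulus responding, correct except for lapses ($p = 1 -
\lambda$); the blind phase uses the ordinary psychometric response.  The
protocol itself has no failure path for practice, but an uncapped loop is
unacceptable engineering, so a configurable cap (default 30 attempts per
phase) raises a distinct practice-failure condition.

**Training** is a fixed 110-trial familiarisation sweep — 4, 3, 2.5, 2,
1.5, 1.25 mm and back up to 4 mm, ten consecutive trials per dome — whose
responses are logged but never gated, followed by a 20-trial accuracy check
at 4 mm.  Accuracy strictly above 75% passes; the wording "higher than
75%" is enforced strictly, so exactly 15/20 does *not* pass and sends the
participant to a second 20-trial check at 5 mm.  Passing neither ends the
task with the threshold recorded at the 5-mm ceiling — the coarsest dome —
with no testing session.  Every protocol run therefore ends in exactly one
of: a measured threshold, the 5-mm ceiling record, or an explicit signalled
failure.

**Orientations** are assigned as independently shuffled
(vertical, horizontal) pairs (`balanced_orientation_sequence()`), so counts
over every even prefix are exactly balanced — 55/55 over the training
sweep — while remaining unpredictable trial to trial.  Record tables code
vertical as 1 and horizontal as 2 throughout.

## Simulated observers

The parametric observer is a logistic psychometric function on log groove
width,

$$p(w) = \gamma + (1 - \gamma - \lambda)\,
  \mathrm{logistic}\!\big(\beta(\log w - \log \alpha)\big),$$

with guess rate $\gamma = 0.5$ fixed by the 2AFC design, lapse rate
$\lambda \in [0, 0.1]$ capping the ceiling at $1 - \lambda$, threshold
parameter $\alpha$ (mm, the width of half-range performance) and slope
$\beta$ on the log scale.  The log scale is chosen because spatial-acuity
thresholds are ratio-scaled quantities.  The default lapse of 0.02 keeps
simulations realistic and exercises the boundary code; 0 remains available.
Observers are orientation-symmetric: real participants can show
vertical/horizontal asymmetries, but the protocol treats the two
orientations as one difficulty, and the simulation follows it.

`true_convergence_width()` inverts the logistic analytically to the width
where $p = 2^{-1/2}$, which exists whenever $1 - \lambda > 2^{-1/2}$; it is
the ground truth that validation studies compare estimates against.
Deterministic (`step_observer`), flat-probability (`flat_observer`),
scripted and replayed responders cover the degenerate and bookkeeping
cases.

### The guessing floor is not a step

A steep logistic is often treated as "step-function-like", but under the
2AFC floor it is not: below threshold the observer still guesses correctly
half the time, so a staircase sitting on the 1.5/2 mm gap can occasionally
descend below 1.5 mm on lucky guesses while the matching upward excursion
(above a width where $p \approx 1$) is impossible.  The result is a small
downward bias of roughly 0.09 mm for arbitrarily steep smooth observers —
a property of the procedure, not an implementation artefact.  Exact
determinism holds only for the true step responder, whose sub-step
probability is 0.

## The synthetic cohort

`cohort_spec()` describes the population the Monte-Carlo protocol
evaluation samples from.  Its defaults emulate a healthy middle-aged
cohort: threshold parameters from a normal distribution with mean 1.8 mm
and SD 0.75 mm truncated to the ladder range, matching the moments such
cohorts exhibit on this task.  No human data constrain the slope or lapse,
so their defaults — slope $\mathcal{N}(4, 1)$ truncated at 1, lapse 0.02 —
are modelling choices, made once and flagged as such.  What the simulated
cohort does *not* emulate: learning and fatigue across the ~160-trial
session, examiner variability in dome placement, orientation asymmetries,
and finger- or age-specific psychometric shapes.  Passing cohort-level
checks therefore validates the protocol engine, not any claim about human
thresholds; reproducing observed human numbers is explicitly out of scope.

## Validation strategy

* **Exact enumeration oracle.**  `exact_staircase_distribution()`
  enumerates every response sequence of a small configuration (at most 4
  transition points) against per-level correct probabilities, propagating
  exact path probabilities trial by trial until at least $1 - 10^{-6}$ of
  the mass has completed.  States are merged under a packed integer coding,
  so the enumeration is exact, not sampled.  For a flat profile at
  $p = 2^{-1/2}$ the oracle's expected fraction of correct responses
  reproduces 0.7071 to nine decimals — the equilibrium argument made
  mechanical.
* **Oracle–Monte-Carlo equivalence.**  For three small configurations the
  Monte-Carlo mean trial count and mean estimate (2,000 sessions each) must
  sit within 3 standard errors of the exact values.  The full 8-transition
  engine is the same code path exercised at scale, where invariant checks
  (exactly 8 transitions, estimator = mean of last 6, thresholds inside the
  ladder) take over.
* **Parameter recovery.**  Across true convergence widths 1–3 mm (slope 4,
  lapse 0.02, 1,000 sessions per point) the estimator's absolute bias stays
  within 0.3 mm.  RMSE tracks the local rung spacing — about 0.3 mm where
  rungs are 0.25 mm apart, rising to about 0.64 mm at 3 mm where spacing is
  0.5–1 mm — which is the resolution a discrete non-uniform ladder affords;
  tolerances are therefore set relative to local spacing rather than as one
  flat number.
* **Trial-count corridor.**  For cohorts spanning the mid-ladder, the mean
  testing-session length falls in a 15–45 trial corridor: a sanity bracket
  around what human runs of this protocol take, deliberately loose because
  no principled slope/lapse calibration to humans exists.

Problem sizes (2,000 Monte-Carlo sessions per oracle configuration, 1,000
per recovery grid point, 10,000 reversals for the fine-ladder convergence
check, 50,000 trials for the flat-responder equilibrium check) were chosen
so that the 3-SE comparisons are sharp enough to detect rule-fidelity bugs
while keeping the whole validation suite quick on a single CPU.

## Known limitations

* The reversal-averaged estimator inherits the ladder's discreteness: on a
  coarse region of the ladder, thresholds quantise toward rung midpoints
  and a mild positive bias (~0.1–0.2 mm here) appears because coarse rungs
  are asymmetric around the true width.
* The recorded-table schema is a faithful re-encoding of the examiner's
  digital answer table, not a byte-level clone of any particular
  spreadsheet layout.
* Timing and force of dome application, examiner skill, multi-site testing
  and test–retest reliability are outside the engine's scope.
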