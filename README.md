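# jvpdome

Tactile spatial acuity is commonly measured with the grating orientation
task (GOT): a JVP dome — a hemisphere with parallel grooves and bars of
equal width — is pressed onto the index fingerpad with its grating either
along ("vertical", coded 1) or across ("horizontal", coded 2) the finger,
and the participant must say which, a two-alternative forced choice.  The
narrowest groove width a person can still discriminate is their tactile
discrimination threshold, in mm.

`jvpdome` implements the complete staircase-based assessment protocol as a
reusable engine, for psychophysicists and clinical researchers who run the
task, and for methodologists who want to study the procedure itself:

* the discrete 11-dome ladder (5, 4, 3, 2.5, 2, 1.5, 1.25, 1, 0.75, 0.5,
  0.35 mm);
* a **two-down-one-up staircase** starting at 4 mm: two consecutive correct
  answers step to a finer dome, one error steps to a coarser one.  The
  session ends at the 8th transition (reversal) point, and the threshold is
  the mean groove width at the last six transitions.  The rule's
  equilibrium solves `p^2 = 1/2`, so the estimate sits at the width
  supporting `p = 2^(-1/2) ≈ 70.71%` correct;
* the surrounding session flow: practice (two phases, each until three
  consecutive correct answers at 4 mm), a 110-trial training sweep, and
  20-trial accuracy checks at 4 mm and, if needed, 5 mm — accuracy strictly
  above 75% passes, failing both records the threshold at the 5-mm ceiling
  with no testing session;
* simulated observers (logistic psychometric function on log width with
  2AFC guess floor 0.5 and a lapse-limited ceiling; step, flat, scripted
  and replayed responders), Monte-Carlo cohort evaluation, an **exact
  enumeration oracle** for small staircase configurations, estimator
  bias/RMSE studies, and lossless CSV record tables in the 1/2 orientation
  coding plus a command-line front end (`inst/cli/jvpdome.R`).

## Worked example

```r
library(jvpdome)

obs <- psychometric_observer(threshold_mm = 1.5, slope = 4, lapse = 0.02)
true_convergence_width(obs)   # width where p = 0.7071: 1.4 mm
res <- run_protocol(obs, seed = 42)
res
#> Grating orientation task protocol run
#>   training path: pass_4mm
#>   trials logged: 172
#> Tactile discrimination threshold: 1.375 mm
#>   mean of transition widths: 1.00, 1.50, 1.25, 1.50, 1.00, 2.00
#>   testing trials: 36
```

The simulated participant passed the 4-mm accuracy check (`pass_4mm`),
logged 172 trials in total (6 practice + 110 sweep + 20 check + 36
testing), and the staircase's last six reversal widths average to
1.375 mm — close to this observer's true 70.71%-correct width of 1.4 mm.

A whole cohort, with thresholds drawn from a truncated normal emulating a
healthy middle-aged population:

```r
run_cohort(cohort_spec(n_observers = 23, seed = 42))
#> Simulated cohort of 23 observers
#>   threshold: 1.95 +/- 0.77 mm
#>   testing trials: 28.87 +/- 6.93
#>   training paths: pass_4mm=21, pass_5mm=2, fail=0, practice_failure=0, incomplete=0
```

Deterministic reference trace (the idealised step responder, always right
at 2 mm and above, never below):

```r
testing_session(step_observer(2))$estimate
#> Tactile discrimination threshold: 1.75 mm
#>   mean of transition widths: 1.5, 2.0, 1.5, 2.0, 1.5, 2.0
#>   testing trials: 20
```

Validation against the exact oracle:

```r
small <- staircase_rule(total_transitions = 3, transitions_used = 2, max_trials = 200)
exact_staircase_distribution(rep(2^-0.5, 11), small, trial_horizon = 90)
#> Exact staircase distribution over 12465 outcomes (mass 1.00000000)
#>   expected trials 10.2426, estimator mean 3.6529 mm
```

At the flat equilibrium probability the enumerated expected fraction of
correct responses is `0.7071068` — the convergence level, derived
mechanically rather than asymptotically.

See `vignette("grating-orientation-protocol")` for the model, the
bookkeeping conventions (reversal value, initial direction, boundary
clamping), the observer assumptions, and the validation strategy.

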