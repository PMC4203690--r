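# tpma — the Three Process Model of alertness for roster fatigue-risk assessment

Irregular working hours, night duties and time-zone crossings degrade
alertness, and bio-mathematical sleepiness models are the standard tool for
screening shift schedules and aircrew rosters inside Fatigue Risk Management
Systems. `tpma` implements the extended Three Process Model (TPM): given a
history of sleep, wake and duty episodes it computes an internal alertness
trajectory, optionally generates model-based sleep when no sleep log exists,
and converts alertness into predicted ratings on the 9-point Karolinska
Sleepiness Scale (KSS) — as group means, as individual reference limits
covering 50/75/90% of subjects, and as full probability distributions over
all nine KSS categories for absolute risk assessment.

## The model in brief

The internal alertness score is a sum of closed-form processes on a scale
with asymptotes `la = 2.4` and `ha = 14.3`:

| Process | Form | Defaults |
|---|---|---|
| S (wake) | `la + (sw − la)·e^{d·taw}` | `d = −0.0353`/h |
| S′ (sleep) | `ha + (ss − ha)·e^{g·tas}` | `g = log((ha−14)/(ha−7.96))/8 ≈ −0.3813`/h |
| S_B (brake) | linear at `(−g)(ha − bl)`/h below `bl`, exponential above | `bl = 12.2` |
| C (circadian) | `Cm + Ca·cos(2π(tod − p)/24)` | `p = 16.8` h, `Ca = 2.5` |
| U (ultradian) | `Um + Ua·cos(2π(tod − p)/12)` | `Ua = 0.5`, `Um = −0.5` |
| W (inertia) | `Wc·e^{Wd·taw}` | `Wc = −5.72`, `Wd = −1.51` (off by default) |
| A (jetlag) | gap to local zone shrinks by `(1 − daily)` per day | `daily = 0.5` |

Predicted mean KSS is `a + b·score` (`a = 10.6, b = −0.6` legacy, or the
field-fitted `9.68/−0.46`); reference limits add `qnorm(coverage)·sd(η)`
using the between-subject SD; a proportional-odds transfer with eight cut
points yields `P(KSS = k)` and severe-sleepiness risk `P(KSS ≥ 7)`.
Circadian phase can be adjusted by rated circadian type (14.61–16.62 h in
0.669 h steps) and acclimatizes gradually across time zones via process A.
A deterministic threshold generator inserts sleep (`S+C+U < 8.38` to fall
asleep, `> 11.38` to wake, with duty-buffer and minimum-duration
constraints) when sleep logs are unavailable.

See the methods vignette (`vignettes/tpma-methods.Rmd`) for the full
description, design choices and validation design.

## Worked example

Two nights of sleep (23:00–07:00, then 23:00–06:30) followed by two day
duties and a long wake period:

```r
library(tpma)

duties <- data.frame(start = c(32, 56), end = c(42, 66),
                     dep_tz = 0, arr_tz = 0, label = "duty")
sleep  <- data.frame(start = c(23, 47), end = c(31, 54.5))

traj <- alertness_trajectory(sleep, duties, tpm_params())
pred <- predict_kss(traj)
pred[which.max(pred$p_ge7_50), ]
```

```
    time_h score kss_mean kss_p1 kss_p2 kss_p3 kss_p4 kss_p5 kss_p6 kss_p7
679   79.5 4.768    7.487      0  0.002  0.006  0.013  0.035  0.128  0.256
    kss_p8 kss_p9 p_ge7_50 p_ge7_75 p_ge7_90
679  0.463  0.097    0.816    0.903    0.948
```

The riskiest moment comes at hour 79.5 — a full day after the last sleep,
near the circadian trough (~03:30 on the clock): the internal alertness
score has fallen to 4.8, the predicted mean KSS is 7.5 ("sleepy, effort to
stay awake"), and severe sleepiness (KSS ≥ 7) is predicted for 82% of
average subjects — rising to 95% at the 90% reference limit. At the end of
the second duty (hour 66), by contrast, the score is 12.2, mean KSS 4.1,
and severe-sleepiness risk only 5%.

When no sleep log exists, `generate_sleep(duties, generator_rule("default"))`
inserts model-based sleep, and `evaluate_generator()` cross-tabulates it
against an observed log (conditional probabilities and odds ratio).
`fit_cosinor()`, `fit_linear_transfer()`, `compare_models()` and
`rate_sweep()` form the validation harness; `simulate_roster()` and
`simulate_ratings()` generate synthetic multi-day rosters with ordinal KSS
ratings and subject random effects for end-to-end parameter recovery.

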