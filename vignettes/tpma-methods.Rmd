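---
title: "The Three Process Model in tpma: model, transfer functions and validation harness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Three Process Model in tpma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tpma)
```

## The model

The Three Process Model (TPM) predicts subjective sleepiness from a sleep/wake
history by summing additive processes on an internal alertness scale bounded
by a lower asymptote `la = 2.4` and an upper asymptote `ha = 14.3`:

* **S — homeostatic process.** During wake, alertness decays exponentially
  from its level at awakening `sw` toward `la` at rate `d = -0.0353` per hour:
  `S(taw) = la + (sw - la) exp(d * taw)`. During sleep it recovers
  exponentially from the level at sleep onset `ss` toward `ha` at rate `g`:
  `S'(tas) = ha + (ss - ha) exp(g * tas)`. The rate `g` is not a free number:
  it is defined by the calibration that eight hours of sleep starting from
  `ss = 7.96` end at exactly 14.0, i.e. `g = log((ha-14)/(ha-7.96))/8 ≈
  -0.3813`. This identity is asserted in the test suite to machine precision.
* **The recovery brake (S_B).** The plain exponential recovers most of the
  deficit in the first hours of sleep. The braked variant splits recovery at
  the brake level `bl = 12.2`: below `bl` the process rises *linearly* at the
  slope the exponential would have at `bl`, namely `(-g)(ha - bl)` per hour
  (about 0.80/h), and switches to the exponential branch at the brake point
  `bt = (bl - ss) / ((-g)(ha - bl))`. The two branches join continuously at
  `bt`; sleep beginning at or above `bl` has `bt = 0` and is purely
  exponential. The linear form below `bl` is the defining property of the
  brake — it slows recovery and makes S nearly linear over most of a full
  sleep episode — and continuity plus that slope determine the branch
  completely.
* **C — circadian process.** A 24 h cosine with acrophase `p = 16.8` h,
  amplitude `Ca = 2.5` and mesor 0: `C = Cm + Ca cos(2π(tod - p)/24)`.
* **U — ultradian process.** A 12 h cosine sharing the phase of C with
  amplitude 0.5 and mesor -0.5, so it only subtracts (range `[-1, 0]`).
* **W — sleep inertia.** `W(taw) = Wc exp(Wd * taw)` with `Wc = -5.72`,
  `Wd = -1.51`: a -5.72 hit at the moment of waking that decays within a few
  hours. W is disabled by default (`use_w = FALSE`): adding it with these
  default parameters consistently *worsens* fits to field ratings, so it is
  kept available for exploration only.
* **A — acclimatization.** After a time-zone transition the circadian phase
  does not jump; A tracks the acclimatized offset between internal phase and
  the home-base clock. Within a location the gap to the local offset `TZ`
  contracts by the factor `(1 - daily_rate)` per day, continuously in time:
  `A(T + dt) = TZ + (A(T) - TZ)(1 - daily_rate)^dt`. `daily_rate = 0.5` is
  the conventional default; about 0.3 fits field data best. A is added to
  the phase of both C and U. Time-zone differences are wrapped to the signed
  shortest path in `(-12, 12]` (eastward positive), and location changes
  take effect at duty arrival times.

The combined score is the sum of the enabled components. All processes are
closed-form within an episode; state is carried exactly at episode
boundaries (`sw` from S at each sleep-to-wake transition, `ss` at each
wake-to-sleep transition), so no numerical integration is involved and S is
continuous everywhere, including at the brake point.

**Initial condition.** A trajectory starts at the first logged sleep onset,
assuming the subject fell asleep at the combined score the sleep generator
uses (8.38): S at onset is solved as `8.38 - C - U` over the *enabled*
components (with U disabled, `S + C = 8.38`). Trajectories that must start
mid-wake require an explicit initial S. Because one assumed sleep is a weak
anchor, ratings are only analyzed after two completed sleeps (the `warmup_end`
attribute and `apply_selection_rules()`), and no later than 16 h after the
last logged sleep.

## Time conventions

All internal times are decimal hours on the home-base clock, measured from
the log's first midnight; ISO-8601 timestamps are converted on ingest.
Episodes are half-open `[start, end)`; an instant on a boundary belongs to
the following episode. Evaluation uses a 5-minute grid by default
(`grid_step = 1/12`), matching the segmentation used in field analyses;
arbitrary time points are supported because the model is closed-form.

## From alertness to KSS

* **Linear transfer.** `KSS = a + b * score + η + ε` with a subject random
  intercept η. The legacy transfer is `a = 10.6`, `b = -0.6`; the transfer
  fitted for the braked S+C+U score is `a = 9.68`, `b = -0.46` with
  `sd(η) = 0.839` and residual SD 1.42 (`linear_transfer("5c")`). Predictions
  are clipped to `[1, 9]` for reporting only.
* **Reference limits.** The line below which a stated share of subjects
  falls is the mean prediction plus `qnorm(coverage) * sd(η)`:
  offsets 1.07 (90%) and 0.57 (75%) at `sd(η) = 0.839`. The offset enters
  the ordinal model's linear predictor with positive sign so that higher
  coverage means higher predicted sleepiness risk.
* **Ordinal transfer.** A proportional-odds model over the nine KSS
  categories: `P(KSS > k) = plogis(slope * score + offset - K_k)` with eight
  ordered cut points. Category probabilities are obtained by differencing;
  they are nonnegative and sum to one by construction. Two presets ship:
  `"s_b_c_u_5c"` (cut points -10.99 … -0.58, subject SD 1.10) for the braked
  S+C+U score, and `"s_b_ct_6d"` (cut points -11.29 … -0.53, subject SD 1.14)
  for the type-adjusted two-process score. **Slope calibration:** the
  preset slopes are derived from the matching linear transfers by logistic
  rescaling, `b_ord = b_lin (π/√3) / ε` — the standard conversion between a
  linear residual scale and the standard logistic — giving -0.589 and
  -0.573. This is the package's own calibration choice for a coefficient
  that the source analyses embed in the cumulative-logit equation; any
  user-fitted slope can be supplied instead.
* **Severe-sleepiness risk.** `risk_curve()` reports `P(KSS ≥ 7)` per time
  point at the 50/75/90% reference limits; curves are ordered in coverage by
  construction.

## Circadian type and the cosinor harness

Subject phases are estimated by cosinor analysis: regress ratings on 24 h
sine and cosine terms (adjusting for the homeostatic score to remove the
time-awake trend), then convert coefficients with
`phase = arctan(β_sin/β_cos)·24/(2π) + K + 12`, where K = 0, 12, 12, 24 for
sign patterns (+/+), (+/-), (-/-), (-/+), wrapped to `[0, 24)`; the +12
maps the sleepiness peak onto the alertness acrophase. Amplitude is
`sqrt(β_sin² + β_cos²)`. A brute-force test inverts cosines of every phase
on a 0.1 h grid through this quadrant table. With per-subject random
sine/cosine terms (uncorrelated by default — the random-effect covariance
is not identified well in sparse field data and the uncorrelated form is
the conservative choice), empirical-Bayes (BLUP) subject phases are
produced; they are shrunken toward the group mean, so their spread
understates true between-subject variance.

Rated circadian type maps to a predicted phase by an affine ladder:
16.62 h for extreme evening types minus 0.669 h per earlier level — 14.61,
15.28, 15.95, 16.62 h for morning through extreme evening. The extreme
morning value (13.94 h) extrapolates one step beyond the observed groups
and warns when used.

Model variants are compared by deviance (twice the absolute log-likelihood
difference), charging ≈2 df per added or modified process, so deviance > 6
marks a significant improvement at α ≈ 0.05. Mixed models are fitted by
maximum likelihood with lme4; the bespoke content of this package is the
model processes, the phase/quadrant extraction, the EB-phase pipeline and
the acclimatization sweep, not the generic mixed-model machinery.

## The sleep generator

When sleep logs are unavailable, sleep is inserted deterministically by
threshold rules on the alertness score:

* `"default"` rule: fall asleep when `S + C + U < 8.38`, wake when
  `S + C + U > 11.38` (unbraked S, default phase).
* `"new"` rule: fall asleep when `S_B + C_T < 8`, wake when `S_B + C_T > 13`
  (braked S, circadian-type adjusted phase, no ultradian term).

Three structural constraints prevent flip/flop behavior: no sleep within
±1 h of a duty period, no sleep within 2 h of the last waking, and no waking
during the first hour of sleep. A duty (minus its buffer) forces waking at
the exact buffer boundary; sleep never begins if a duty buffer opens within
the minimum sleep time, so all three constraints hold exactly on every
output (property-tested on randomized duty sets). Threshold comparisons are
strict, so a score exactly at threshold does not trigger; transitions occur
at grid points. If the score never crosses the sleep threshold the generator
returns an all-wake timeline with a warning rather than oscillating.

When seeded with an observed first sleep, the scan starts asleep at that
episode's start with S solved from the generator score, is forced awake at
its logged end, and marks the episode `bootstrap` so evaluation can exclude
it. Without a seed the scan starts fully rested (`S = ha`) and immediately
eligible to sleep — a deterministic, conservative choice for the unobserved
history. Proximity to duty beyond the hard ±1 h buffer is deliberately not
modelled.

`evaluate_generator()` cross-tabulates observed against generated sleep on
5-minute segments and reports the conditional probabilities of observed
sleep given generated status and their odds ratio; identical timelines give
an infinite (degenerate) odds ratio, which is flagged rather than hidden.

## The synthetic data generator

`simulate_roster()` produces duty schedules: `shorthaul` (daily ~07-17
duties, home time zone), `longhaul` (five-day rotations with an outbound
flight to a shifted zone, a layover, a return flight, two rest days),
`mixed`, and `rotating` (one 8 h duty per 27 h, so duty start drifts 3 h per
day through the full clock — a rotating shift system). `simulate_ratings()`
draws per-subject circadian phases (SD 1 h around the group mean or the
circadian-type means, matching the spread of field EB estimates), subject
intercepts, and KSS ratings by either the linear transfer (Gaussian,
rounded and clipped to 1-9) or the ordinal transfer (categorical draws
including a subject logit offset). Rating times are duty-weighted by
default — 70% inside duty windows, most of the rest in 08-22 h, under 2%
nocturnal — to emulate field sampling; `sampling = "uniform"` gives the
balanced around-the-clock design of a controlled validation study. Ratings
during sleep are discarded, as is anything before the first completed
sleep.

What the generator does *not* emulate: self-selection of subjects, app
usage artifacts, missing-not-at-random gaps, correlation between workload
and rating propensity, or in-flight naps. Passing recovery tests therefore
demonstrates that the estimation machinery inverts the model's own data
generating process at realistic sizes — not that the model is correct for
any particular airline's operations.

## Validation experiments and their sizes

The test suite and `scripts/acceptance.R` run three seeded recovery
experiments chosen to be sharp enough to detect implementation errors while
completing in well under a minute each:

* **Phase recovery** — 100 subjects × ~75 ratings on a 9-day rotating
  roster with a shared generated sleep log, balanced sampling, continuous
  ratings from the two-process braked-S + C model (the best-supported model
  for field data; omitting U also avoids 12 h leakage into the 24 h fit
  under restricted sampling windows). The cosinor, adjusted for the
  homeostatic score, recovers the generating 16.8 h phase within 0.25 h in
  ≈90% of seeds. The rotating roster matters: with day duties only, nobody
  is awake at the circadian trough, and the cosine becomes partially
  confounded with the homeostatic decay.
* **Transfer recovery** — the same data fitted by
  `fit_linear_transfer()` recovers `a = 9.68`, `b = -0.46` within 2 SE and
  `sd(η) = 0.839` within 20%. Continuous ratings are used here because
  rounding/clipping to the integer scale attenuates the fitted slope by a
  few percent — an intentional property of the discretized simulator, not
  of the estimator under test.
* **Acclimatization-rate recovery** — 40 subjects × 12 ratings/day over a
  25-day long-haul roster (+8 h rotations) simulated at a true daily rate of
  30%; sweeping 0-100% in 5% steps and refitting the transfer at each rate
  recovers the generating rate within one grid step. Single-time-zone data
  leave the sweep criterion flat, which is also asserted.

## Numerical choices and degenerate inputs

* Strict inequalities at generator thresholds; grid-aligned transitions;
  duty-buffer boundaries applied exactly (not rounded to the grid).
* The initial-condition solve clamps S to `[la, ha]` in pathological
  phase/threshold combinations.
* `extract_phase` treats a zero coefficient as positive in the quadrant
  table and rejects the all-zero case; phases compare on the circle
  (`phase_distance`).
* Zero-variance score columns abort transfer fitting with a clear error;
  cosinor fits warn when time-of-day coverage spans less than 6 h.
* `rnorm`-based simulators accept zero SDs (degenerating to deterministic
  draws) so noise-free oracles are exact.

## Known limitations

* The ordinal slope presets are calibrated, not estimated, as described
  above; absolute probability levels from the presets inherit that
  approximation even though ordering and normalization are exact.
* Sleep inertia uses the published fixed parameters; an adaptive inertia
  magnitude depending on sleep pressure at waking is out of scope.
* The generator does not model the social rhythm of sleep timing after
  time-zone transitions; generated sleep is anchored to the (possibly
  type-adjusted) circadian phase only.
* Time-on-task fatigue, in-flight sleep quality and performance outcomes
  (e.g. psychomotor vigilance) are outside the model.
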