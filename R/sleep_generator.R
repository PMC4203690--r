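#' Sleep-generator threshold rule
#'
#' Defines which model components form the generator's score and the
#' thresholds and structural constraints that govern model-based sleep.
#' Two named presets are shipped:
#'
#' * `"default"`: score `S + C + U` (unbraked S, default phase), fall asleep
#'   below 8.38, wake above 11.38.
#' * `"new"`: score `S_B + C_T` (braked S, circadian-type adjusted phase, no
#'   ultradian term), fall asleep below 8, wake above 13.
#'
#' Both share the structural constraints: no sleep within +/-1 h of a duty
#' period, no sleep earlier than 2 h after waking up, and no waking during
#' the first hour of sleep (these prevent flip/flop switching around the
#' thresholds).
#'
#' @param preset `"default"` or `"new"`, or `NULL` to set fields directly.
#' @param sleep_on Falling-asleep threshold (score strictly below triggers).
#' @param wake Waking threshold (score strictly above triggers).
#' @param use_brake Use braked sleep recovery in the generator score?
#' @param use_u Include process U in the generator score?
#' @param use_type_phase Use the circadian-type adjusted phase for C (and U)?
#' @param duty_buffer Hours around duty periods where sleep is forbidden.
#' @param min_wake_before_sleep Minimum hours awake before sleep may start.
#' @param min_sleep Minimum hours of sleep before waking is allowed.
#' @return A `tpm_generator_rule` object.
#' @examples
#' generator_rule("new")
#' @export
generator_rule <- function(preset = c("default", "new"),
                           sleep_on = NULL, wake = NULL,
                           use_brake = NULL, use_u = NULL,
                           use_type_phase = NULL,
                           duty_buffer = 1,
                           min_wake_before_sleep = 2,
                           min_sleep = 1) {
  preset <- match.arg(preset)
  def <- switch(preset,
    default = list(sleep_on = 8.38, wake = 11.38, use_brake = FALSE,
                   use_u = TRUE, use_type_phase = FALSE),
    new = list(sleep_on = 8, wake = 13, use_brake = TRUE,
               use_u = FALSE, use_type_phase = TRUE)
  )
  rule <- list(
    preset = preset,
    sleep_on = if (is.null(sleep_on)) def$sleep_on else sleep_on,
    wake = if (is.null(wake)) def$wake else wake,
    use_brake = if (is.null(use_brake)) def$use_brake else isTRUE(use_brake),
    use_u = if (is.null(use_u)) def$use_u else isTRUE(use_u),
    use_type_phase = if (is.null(use_type_phase)) def$use_type_phase
                     else isTRUE(use_type_phase),
    duty_buffer = duty_buffer,
    min_wake_before_sleep = min_wake_before_sleep,
    min_sleep = min_sleep
  )
  stopifnot(
    "sleep_on must be below wake" = rule$sleep_on < rule$wake,
    "durations must be >= 0" = duty_buffer >= 0 &&
      min_wake_before_sleep >= 0 && min_sleep >= 0
  )
  class(rule) <- "tpm_generator_rule"
  rule
}

#' @export
print.tpm_generator_rule <- function(x, ...) {
  cat(sprintf(
    "Sleep generator rule ('%s'): %s%s%s < %.3g to sleep, > %.3g to wake\n",
    x$preset, if (x$use_brake) "S_B" else "S",
    if (x$use_type_phase) "+C_T" else "+C", if (x$use_u) "+U" else "",
    x$sleep_on, x$wake))
  cat(sprintf("  duty buffer %.3g h; >= %.3g h awake before sleep; >= %.3g h asleep before wake\n",
              x$duty_buffer, x$min_wake_before_sleep, x$min_sleep))
  invisible(x)
}

#' Generate model-based sleep for a duty schedule
#'
#' Forward scan over the evaluation grid: sleep starts at the first grid
#' point where the rule's alertness score falls strictly below `sleep_on`
#' while the point is at least `duty_buffer` hours away from every duty and
#' at least `min_wake_before_sleep` hours have passed since the last waking.
#' Sleep ends at the first grid point where the score strictly exceeds
#' `wake` after at least `min_sleep` hours of sleep, or exactly when a duty
#' (minus the buffer) begins; sleep never starts when a duty zone opens
#' within `min_sleep` hours, so the minimum-sleep guarantee always holds.
#' The scan is deterministic given its inputs.
#'
#' A seeding first sleep may be supplied (e.g. the first observed sleep of a
#' log): the scan then starts asleep at its start -- with S solved from the
#' generator's falling-asleep score -- and is forced awake at its logged
#' end; the seed is marked `provenance = "bootstrap"`. Without a seed the
#' scan starts fully rested (S = `ha`) and eligible to sleep at the horizon
#' start.
#'
#' @param duties Duty data frame (`start`, `end`, optionally `arr_tz`), may
#'   have zero rows.
#' @param rule A [generator_rule()].
#' @param prm A [tpm_params()] object (asymptotes, rates, phases).
#' @param horizon Length-2 numeric: time window to scan, decimal hours.
#' @param grid_step Scan step in hours (default 5 minutes).
#' @param circadian_type Circadian type used when the rule has
#'   `use_type_phase = TRUE`.
#' @param first_sleep Optional one-row data frame (`start`, `end`) seeding
#'   the scan as described above.
#' @return Sleep episode data frame (`start`, `end`, `provenance`); zero
#'   rows (with a warning) when the score never drops below threshold.
#' @examples
#' duties <- data.frame(start = 8, end = 16, dep_tz = 0, arr_tz = 0)
#' generate_sleep(duties, generator_rule("default"), horizon = c(0, 48))
#' @export
generate_sleep <- function(duties, rule = generator_rule("default"),
                           prm = tpm_params(), horizon = NULL,
                           grid_step = 1 / 12, circadian_type = NULL,
                           first_sleep = NULL) {
  if (is.null(horizon)) {
    if (is.null(duties) || nrow(duties) == 0) {
      stop("supply an explicit horizon when there are no duties")
    }
    horizon <- c(min(duties$start) - 24, max(duties$end) + 24)
  }
  stopifnot(length(horizon) == 2, horizon[2] > horizon[1])
  phase <- if (rule$use_type_phase && !is.null(circadian_type)) {
    phase_for_type(circadian_type)
  } else {
    prm$p
  }
  times <- horizon[1] + seq(0, horizon[2] - horizon[1], by = grid_step)
  n <- length(times)
  tod <- times %% 24
  Cv <- process_c(tod, phase, prm$Ca, prm$Cm)
  Uv <- if (rule$use_u) process_u(tod, phase, prm$Ua, prm$Um) else rep(0, n)

  # grid points within duty_buffer of any duty
  forbidden <- rep(FALSE, n)
  buffer_starts <- numeric(0) # exact times where a no-sleep zone begins
  if (!is.null(duties) && nrow(duties)) {
    for (k in seq_len(nrow(duties))) {
      forbidden <- forbidden |
        (times >= duties$start[k] - rule$duty_buffer &
           times < duties$end[k] + rule$duty_buffer)
    }
    buffer_starts <- sort(duties$start - rule$duty_buffer)
  }
  # earliest upcoming no-sleep zone strictly after t (Inf if none)
  next_zone <- function(t) {
    nz <- buffer_starts[buffer_starts > t]
    if (length(nz)) nz[1] else Inf
  }

  recover_fn <- if (rule$use_brake) homeostatic_sleep_braked else homeostatic_sleep

  # scan state
  starts <- ends <- numeric(0)
  prov <- character(0)
  if (!is.null(first_sleep)) {
    stopifnot(nrow(first_sleep) == 1, first_sleep$start < first_sleep$end)
    asleep <- TRUE
    anchor <- first_sleep$start # episode start time
    cb <- process_c(anchor %% 24, phase, prm$Ca, prm$Cm)
    ub <- if (rule$use_u) process_u(anchor %% 24, phase, prm$Ua, prm$Um) else 0
    s_anchor <- min(max(rule$sleep_on - cb - ub, prm$la), prm$ha)
    forced_end <- first_sleep$end
    cur_start <- anchor
    cur_prov <- "bootstrap"
  } else {
    asleep <- FALSE
    anchor <- times[1]
    s_anchor <- prm$ha # fully rested at horizon start
    forced_end <- NA_real_
    cur_start <- NA_real_
    cur_prov <- "generated"
  }
  last_wake <- -Inf # time of last waking; -Inf = gate open at start

  for (i in seq_len(n)) {
    t <- times[i]
    if (!is.na(forced_end) && asleep) {
      # bootstrap sleep: forced to end at its logged end
      if (t >= forced_end) {
        s_anchor <- recover_fn(s_anchor, forced_end - cur_start, prm)
        starts <- c(starts, cur_start); ends <- c(ends, forced_end)
        prov <- c(prov, cur_prov)
        asleep <- FALSE; anchor <- forced_end; last_wake <- forced_end
        forced_end <- NA_real_; cur_prov <- "generated"
      } else next
    }
    if (asleep) {
      if (forbidden[i]) {
        # duty (minus buffer) begins: wake exactly at the zone boundary
        zb <- buffer_starts[buffer_starts >= cur_start & buffer_starts <= t]
        t_end <- if (length(zb)) zb[length(zb)] else t
        s_anchor <- recover_fn(s_anchor, t_end - cur_start, prm)
        starts <- c(starts, cur_start); ends <- c(ends, t_end)
        prov <- c(prov, cur_prov)
        asleep <- FALSE; anchor <- t_end; last_wake <- t_end
        cur_prov <- "generated"
      } else {
        S <- recover_fn(s_anchor, t - cur_start, prm)
        score <- S + Cv[i] + Uv[i]
        if (score > rule$wake && t - cur_start >= rule$min_sleep) {
          s_anchor <- S
          starts <- c(starts, cur_start); ends <- c(ends, t)
          prov <- c(prov, cur_prov)
          asleep <- FALSE; anchor <- t; last_wake <- t
          cur_prov <- "generated"
        }
      }
    } else {
      S <- homeostatic_wake(s_anchor, t - anchor, prm)
      score <- S + Cv[i] + Uv[i]
      if (score < rule$sleep_on && !forbidden[i] &&
          t - last_wake >= rule$min_wake_before_sleep &&
          next_zone(t) - t >= rule$min_sleep) {
        s_anchor <- S
        asleep <- TRUE; cur_start <- t
      }
    }
  }
  if (asleep && cur_start < times[n]) {
    starts <- c(starts, cur_start); ends <- c(ends, times[n])
    prov <- c(prov, cur_prov)
  }
  out <- data.frame(start = starts, end = ends, provenance = prov)
  if (!any(out$provenance == "generated")) {
    warning("alertness score never crossed the sleep threshold; ",
            "no sleep generated over the horizon")
  }
  out
}

#' Cross-tabulate observed against generated sleep
#'
#' Expands both timelines to grid segments over a common window and
#' cross-tabulates sleep status, returning the conditional probabilities of
#' observed sleep given generated sleep status and their odds ratio.
#'
#' @param observed,generated Sleep episode data frames (`start`, `end`);
#'   rows of `generated` with `provenance == "bootstrap"` are excluded from
#'   the evaluation.
#' @param from,to Common evaluation window (defaults to the union span).
#' @param grid_step Segment length in hours (default 5 minutes).
#' @return A list of class `tpm_generator_eval`: `table` (2x2 counts),
#'   `p1` = P(observed sleep | generated), `p0` = P(observed sleep | not
#'   generated), `odds_ratio`, and `degenerate` (TRUE when the odds ratio is
#'   infinite because agreement is perfect on one margin).
#' @export
evaluate_generator <- function(observed, generated, from = NULL, to = NULL,
                               grid_step = 1 / 12) {
  if (!is.null(generated$provenance)) {
    generated <- generated[generated$provenance != "bootstrap", , drop = FALSE]
  }
  if (is.null(from)) from <- min(observed$start, generated$start)
  if (is.null(to)) to <- max(observed$end, generated$end)
  times <- from + seq(0, to - from - grid_step / 2, by = grid_step)
  in_ep <- function(t, ep) {
    out <- rep(FALSE, length(t))
    for (k in seq_len(nrow(ep))) out <- out | (t >= ep$start[k] & t < ep$end[k])
    out
  }
  obs <- in_ep(times, observed)
  gen <- in_ep(times, generated)
  tab <- table(generated = factor(gen, c(FALSE, TRUE)),
               observed = factor(obs, c(FALSE, TRUE)))
  p1 <- if (sum(gen) > 0) mean(obs[gen]) else NA_real_
  p0 <- if (sum(!gen) > 0) mean(obs[!gen]) else NA_real_
  or <- odds_ratio(p1, p0)
  structure(list(table = tab, p1 = p1, p0 = p0, odds_ratio = or,
                 degenerate = !is.finite(or)),
            class = "tpm_generator_eval")
}

#' Odds ratio from two conditional probabilities
#'
#' `(p1/(1-p1)) / (p0/(1-p0))`; `Inf` for a degenerate (perfect) margin.
#'
#' @param p1 P(event | condition present).
#' @param p0 P(event | condition absent).
#' @return The odds ratio.
#' @examples
#' odds_ratio(0.790, 0.118) # about 28
#' @export
odds_ratio <- function(p1, p0) {
  (p1 / (1 - p1)) / (p0 / (1 - p0))
}

#' @export
print.tpm_generator_eval <- function(x, ...) {
  cat("Sleep generator evaluation (5-min segments)\n")
  print(x$table)
  cat(sprintf("  P(observed sleep | generated) = %.3f\n", x$p1))
  cat(sprintf("  P(observed sleep | not generated) = %.3f\n", x$p0))
  cat(sprintf("  odds ratio = %s\n",
              if (x$degenerate) "Inf (perfect agreement on a margin)"
              else sprintf("%.1f", x$odds_ratio)))
  invisible(x)
}
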