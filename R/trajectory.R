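#' Combined internal alertness score
#'
#' Adds the enabled model components. Components whose switch is off in
#' `prm` contribute zero.
#'
#' @param S,C,U,W Component values (vectorized).
#' @param prm A [tpm_params()] object (component switches).
#' @return The combined alertness score.
#' @export
combined_score <- function(S, C, U = 0, W = 0, prm = tpm_params()) {
  (if (prm$use_s) S else 0) +
    (if (prm$use_c) C else 0) +
    (if (prm$use_u) U else 0) +
    (if (prm$use_w) W else 0)
}

# closed-form S during one sleep episode, branch per the brake switch
.recover <- function(ss, tas, prm) {
  if (prm$use_brake) homeostatic_sleep_braked(ss, tas, prm)
  else homeostatic_sleep(ss, tas, prm)
}

#' Alertness trajectory over a sleep/wake timeline
#'
#' Evaluates every enabled model process on a time grid across a history of
#' sleep episodes, carrying the homeostatic state across transitions: `sw`
#' is S at each sleep-to-wake transition and `ss` is S at each wake-to-sleep
#' transition. Within episodes all processes are closed-form; transitions
#' occur exactly at episode boundaries (half-open intervals), so S is
#' continuous everywhere.
#'
#' The initial condition assumes the first logged sleep began at the
#' combined score used by the model-based sleep generator (8.38 with the
#' default components): S at the first onset is solved as
#' `sleep_on_threshold` minus the enabled time-of-day components. When the
#' requested window starts before the first sleep, an explicit `initial_sw`
#' (S at the start of that leading wake period) must be supplied instead.
#'
#' Trajectories based on fewer than two prior sleeps are unreliable; the
#' returned object carries a `warmup_end` attribute (end of the second
#' sleep) used by [apply_selection_rules()].
#'
#' @param sleep Sleep episode data frame with columns `start`, `end`
#'   (decimal hours from the log origin), non-overlapping, at least one row.
#' @param duties Optional duty data frame (columns `start`, `end`,
#'   `dep_tz`, `arr_tz`); used for the acclimatization process A (location
#'   changes take effect at duty arrival times).
#' @param prm A [tpm_params()] object.
#' @param grid_step Evaluation step in hours (default 1/12, i.e. 5 minutes).
#' @param from,to Window of evaluation; defaults: first sleep onset to 16 h
#'   after the later of the last sleep or last duty.
#' @param times Optional explicit evaluation times (overrides the grid).
#' @param circadian_type Optional circadian type (see [phase_for_type()]);
#'   used only when `prm$use_type_phase` is `TRUE`.
#' @param initial_sw Optional S at `from` when `from` precedes the first
#'   sleep episode.
#' @return A data frame of class `tpm_trajectory` with columns `time_h`,
#'   `state`, `S`, `C`, `U`, `W`, `phase_used`, `score`, and attributes
#'   `params` and `warmup_end`.
#' @examples
#' sleep <- data.frame(start = c(23, 47), end = c(31, 55))
#' tr <- alertness_trajectory(sleep, prm = tpm_params(use_u = FALSE))
#' range(tr$S)
#' @export
alertness_trajectory <- function(sleep, duties = NULL, prm = tpm_params(),
                                 grid_step = 1 / 12, from = NULL, to = NULL,
                                 times = NULL, circadian_type = NULL,
                                 initial_sw = NULL) {
  if (is.null(sleep) || nrow(sleep) == 0) stop("empty timeline: no sleep episodes")
  sleep <- sleep[order(sleep$start), , drop = FALSE]
  if (any(sleep$end <= sleep$start)) stop("sleep episodes must have start < end")
  if (nrow(sleep) > 1 && any(sleep$start[-1] < sleep$end[-nrow(sleep)])) {
    stop("sleep episodes overlap")
  }
  if (is.null(from)) from <- sleep$start[1]
  if (is.null(to)) {
    to <- max(sleep$end[nrow(sleep)],
              if (!is.null(duties) && nrow(duties)) max(duties$end) else -Inf) + 16
  }
  if (is.null(times)) {
    if (grid_step <= 0) stop("grid_step must be > 0")
    times <- from + seq(0, max(to - from, 0), by = grid_step)
  } else {
    times <- sort(as.numeric(times))
    from <- min(from, times[1])
  }

  if (from < sleep$start[1] && is.null(initial_sw)) {
    stop("window starts with wake of unknown prior sleep; supply initial_sw ",
         "or start the window at the first sleep onset")
  }

  base_phase <- if (prm$use_type_phase && !is.null(circadian_type)) {
    phase_for_type(circadian_type)
  } else {
    prm$p
  }

  A <- acclimatization_offset(times, duties, prm$daily_rate)
  phase_used <- base_phase + A

  # --- episode table: alternating wake/sleep covering [from, to] ------------
  n_sleep <- nrow(sleep)
  ep_start <- ep_end <- numeric(0)
  ep_state <- character(0)
  if (from < sleep$start[1]) {
    ep_start <- from; ep_end <- sleep$start[1]; ep_state <- "wake"
  }
  for (k in seq_len(n_sleep)) {
    ep_start <- c(ep_start, sleep$start[k])
    ep_end <- c(ep_end, sleep$end[k])
    ep_state <- c(ep_state, "sleep")
    nxt <- if (k < n_sleep) sleep$start[k + 1] else max(to, sleep$end[k])
    if (nxt > sleep$end[k]) {
      ep_start <- c(ep_start, sleep$end[k])
      ep_end <- c(ep_end, nxt)
      ep_state <- c(ep_state, "wake")
    }
  }

  # --- carry S across episode boundaries ------------------------------------
  n_ep <- length(ep_start)
  S0 <- numeric(n_ep) # S at each episode start
  if (ep_state[1] == "wake") {
    S0[1] <- initial_sw
  } else {
    # solve the generator score at first onset from the enabled components
    A1 <- acclimatization_offset(ep_start[1], duties, prm$daily_rate)
    tod1 <- ep_start[1] %% 24
    c1 <- if (prm$use_c) process_c(tod1, base_phase + A1, prm$Ca, prm$Cm) else 0
    u1 <- if (prm$use_u) process_u(tod1, base_phase + A1, prm$Ua, prm$Um) else 0
    S0[1] <- min(max(prm$sleep_on_threshold - c1 - u1, prm$la), prm$ha)
  }
  for (k in seq_len(n_ep)) {
    len <- ep_end[k] - ep_start[k]
    s_end <- if (ep_state[k] == "sleep") .recover(S0[k], len, prm)
             else homeostatic_wake(S0[k], len, prm)
    if (k < n_ep) S0[k + 1] <- s_end
  }

  # --- evaluate on the grid --------------------------------------------------
  idx <- findInterval(times, ep_start)
  idx[idx == 0] <- 1
  el <- times - ep_start[idx] # time within episode
  is_sleep <- ep_state[idx] == "sleep"
  S <- numeric(length(times))
  for (k in unique(idx)) {
    sel <- idx == k
    S[sel] <- if (ep_state[k] == "sleep") .recover(S0[k], el[sel], prm)
              else homeostatic_wake(S0[k], el[sel], prm)
  }
  tod <- times %% 24
  C <- process_c(tod, phase_used, prm$Ca, prm$Cm)
  U <- process_u(tod, phase_used, prm$Ua, prm$Um)
  W <- ifelse(is_sleep, 0, prm$Wc * exp(prm$Wd * el))

  out <- data.frame(
    time_h = times,
    state = ifelse(is_sleep, "sleep", "wake"),
    S = S, C = C, U = U, W = W,
    phase_used = phase_used,
    score = combined_score(S, C, U, W, prm)
  )
  attr(out, "params") <- prm
  attr(out, "warmup_end") <- if (n_sleep >= 2) sleep$end[2] else NA_real_
  class(out) <- c("tpm_trajectory", "data.frame")
  out
}

#' @export
print.tpm_trajectory <- function(x, ...) {
  cat(sprintf("TPM alertness trajectory: %d points over %.1f-%.1f h\n",
              nrow(x), min(x$time_h), max(x$time_h)))
  cat(sprintf("  score range %.2f-%.2f; %d sleep points\n",
              min(x$score), max(x$score), sum(x$state == "sleep")))
  NextMethod()
}

#' Write a trajectory as CSV
#'
#' Columns: `time_h, state, S, C, U, W, phase_used, score`.
#'
#' @param traj A `tpm_trajectory`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(as.data.frame(traj)[, c("time_h", "state", "S", "C", "U",
                                           "W", "phase_used", "score")],
                   path, row.names = FALSE)
  invisible(path)
}
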