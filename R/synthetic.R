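#' Simulate a duty roster
#'
#' Reproducible duty schedules for testing and simulation. Patterns:
#'
#' * `"shorthaul"`: one duty per day, about 07-17 h local, no time-zone
#'   changes.
#' * `"rotating"`: one 8 h duty per day whose start advances 3 h each day,
#'   cycling through the full clock (a rotating shift system; no time-zone
#'   changes). Useful when estimating circadian parameters, since sleep and
#'   ratings then cover all times of day.
#' * `"longhaul"`: five-day rotations -- outbound flight arriving in
#'   `tz_sequence[1]`, a layover day, a return flight arriving in
#'   `tz_sequence[2]`, then two rest days -- giving the eastward/westward
#'   shifts needed to exercise acclimatization.
#' * `"mixed"`: shorthaul days with one longhaul rotation in the middle.
#'
#' @param n_days Number of days covered (`>= 1`).
#' @param pattern One of `"shorthaul"`, `"longhaul"`, `"mixed"`.
#' @param tz_sequence Arrival time-zone offsets (hours, eastward positive)
#'   for longhaul rotations, recycled; default `c(8, 0)` (out +8 h, home).
#' @param seed RNG seed; the output is identical for identical seeds.
#' @return Duty data frame: `start`, `end`, `dep_tz`, `arr_tz`, `label`
#'   (times in decimal hours from day-0 midnight).
#' @examples
#' simulate_roster(3, "shorthaul", seed = 1)
#' @export
simulate_roster <- function(n_days, pattern = c("shorthaul", "longhaul",
                                                "mixed", "rotating"),
                            tz_sequence = c(8, 0), seed = 1) {
  pattern <- match.arg(pattern)
  stopifnot(n_days >= 1)
  set.seed(seed)
  mk_short <- function(days) {
    if (!length(days)) {
      return(data.frame(start = numeric(0), end = numeric(0),
                        dep_tz = numeric(0), arr_tz = numeric(0),
                        label = character(0)))
    }
    st <- 24 * (days - 1) + 7 + stats::runif(length(days), 0, 2)
    data.frame(start = st, end = st + 8 + stats::runif(length(days), 0, 2),
               dep_tz = 0, arr_tz = 0, label = "shorthaul")
  }
  mk_long <- function(day0, tz_out, tz_back, dep0 = 0) {
    st1 <- 24 * day0 + 9 + stats::runif(1)
    st2 <- 24 * (day0 + 2) + 9 + stats::runif(1)
    data.frame(start = c(st1, st2), end = c(st1 + 10, st2 + 10),
               dep_tz = c(dep0, tz_out), arr_tz = c(tz_out, tz_back),
               label = "longhaul")
  }
  duties <- switch(pattern,
    shorthaul = mk_short(seq_len(n_days)),
    rotating = {
      k <- seq_len(n_days)
      st <- 6 + 27 * (k - 1) # one duty per 27 h: start drifts 3 h daily
      data.frame(start = st, end = st + 8, dep_tz = 0, arr_tz = 0,
                 label = "rotating")
    },
    longhaul = {
      out <- list(); i <- 0; tzi <- 1
      while (5 * i + 3 <= n_days) {
        tz_out <- wrap_tz(tz_sequence[(tzi - 1) %% length(tz_sequence) + 1])
        tz_back <- wrap_tz(tz_sequence[tzi %% length(tz_sequence) + 1])
        dep0 <- if (i == 0) 0 else tz_back
        out[[i + 1]] <- mk_long(5 * i, tz_out, tz_back, dep0 = 0)
        i <- i + 1; tzi <- tzi + 2
      }
      if (!length(out)) mk_long(0, wrap_tz(tz_sequence[1]),
                                wrap_tz(tz_sequence[min(2, length(tz_sequence))]))
      else do.call(rbind, out)
    },
    mixed = {
      mid <- floor(n_days / 2)
      rot_days <- intersect(seq(mid, mid + 4), seq_len(n_days))
      short_days <- setdiff(seq_len(n_days), rot_days)
      rbind(mk_short(short_days),
            mk_long(mid - 1, wrap_tz(tz_sequence[1]),
                    wrap_tz(tz_sequence[min(2, length(tz_sequence))])))
    }
  )
  duties <- duties[order(duties$start), , drop = FALSE]
  rownames(duties) <- NULL
  validate_duties(duties)
}

# one subject's rating times: duty-weighted daytime sampling ("field") or
# balanced around-the-clock sampling ("uniform")
.rating_times <- function(n_days, per_day, duties, t0 = 0,
                          sampling = "field") {
  n <- n_days * per_day
  if (sampling == "uniform") {
    return(sort(t0 + stats::runif(n, 0, 24 * n_days)))
  }
  cat_p <- c(duty = 0.70, day = 0.28, night = 0.02)
  cats <- sample(names(cat_p), n, replace = TRUE, prob = cat_p)
  day <- sample(seq_len(n_days), n, replace = TRUE)
  base <- 24 * floor(t0 / 24) # align rating days to midnight
  t <- numeric(n)
  for (i in seq_len(n)) {
    d0 <- base + 24 * (day[i] - 1)
    if (cats[i] == "duty" && !is.null(duties) && nrow(duties)) {
      ov <- duties[duties$end > d0 & duties$start < d0 + 24, , drop = FALSE]
      if (nrow(ov)) {
        k <- sample(nrow(ov), 1)
        t[i] <- stats::runif(1, max(ov$start[k], d0), min(ov$end[k], d0 + 24))
        next
      }
      cats[i] <- "day"
    }
    t[i] <- if (cats[i] == "night") {
      d0 + sample(c(stats::runif(1, 0, 6), stats::runif(1, 23, 24)), 1)
    } else {
      d0 + stats::runif(1, 8, 22)
    }
  }
  sort(t)
}

#' Simulate subject KSS ratings over a roster
#'
#' Generates ordinal sleepiness ratings with the statistical structure the
#' validation harness assumes: per-subject circadian phases drawn around a
#' group mean (or circadian-type means), subject-level random intercepts,
#' and model-based sleep when no sleep log is supplied. Rating times are
#' daytime-weighted (70% within duty windows, most of the rest in
#' 08-22 h, under 2% nocturnal) to emulate field sampling.
#'
#' @param duties Duty data frame (see [simulate_roster()]).
#' @param sleep Optional shared sleep log; `NULL` generates each subject's
#'   sleep with the default [generator_rule()] at the subject's own phase.
#' @param n_subjects Number of subjects.
#' @param ratings_per_day Mean ratings per subject-day.
#' @param transfer `"linear"` (rounded/clipped Gaussian KSS) or `"ordinal"`
#'   (categorical draw from the proportional-odds transfer).
#' @param prm Base [tpm_params()]; its `daily_rate` is the true
#'   acclimatization rate of the simulation.
#' @param a,b,eta_sd,residual_sd True linear-transfer parameters.
#' @param ordinal True [ordinal_transfer()] for `transfer = "ordinal"`.
#' @param phase_mean,phase_sd Between-subject circadian phase distribution
#'   (hours); `phase_mean = NULL` uses circadian-type means via
#'   [phase_for_type()] with types drawn from a field-realistic mix.
#' @param sampling `"field"` (duty-weighted daytime rating times, the
#'   default) or `"uniform"` (around-the-clock, as in a balanced validation
#'   study; awake-only filtering still applies).
#' @param discretize For the linear transfer, round and clip ratings to the
#'   integer 1-9 scale (the default)? `FALSE` keeps continuous ratings,
#'   which estimator-validation experiments use since rounding/clipping
#'   attenuates fitted slopes by a few percent.
#' @param seed RNG seed.
#' @return Ratings data frame (`time`, `kss`, `subject_id`,
#'   `circadian_type`) with attributes `truth` (per-subject phases and
#'   intercepts plus the generating parameters) and `sleep` (per-subject
#'   sleep logs).
#' @export
simulate_ratings <- function(duties, sleep = NULL, n_subjects = 20,
                             ratings_per_day = 8,
                             transfer = c("linear", "ordinal"),
                             prm = tpm_params(),
                             a = 9.68, b = -0.46, eta_sd = 0.839,
                             residual_sd = 1.42,
                             ordinal = ordinal_transfer("s_b_c_u_5c"),
                             phase_mean = 16.8, phase_sd = 1.0,
                             sampling = c("field", "uniform"),
                             discretize = TRUE,
                             seed = 1) {
  transfer <- match.arg(transfer)
  sampling <- match.arg(sampling)
  set.seed(seed)
  horizon <- c(min(duties$start) - 24, max(duties$end) + 24)
  n_days <- ceiling(diff(horizon) / 24)

  # paper-like mix of circadian types (none extreme morning)
  type_p <- c(0, 0.28, 0.44, 0.26, 0.02)
  types <- sample(circadian_types, n_subjects, replace = TRUE, prob = type_p)
  phases <- if (is.null(phase_mean)) {
    stats::rnorm(n_subjects, phase_for_type(types), phase_sd)
  } else {
    stats::rnorm(n_subjects, phase_mean, phase_sd)
  }
  etas <- stats::rnorm(n_subjects, 0, eta_sd)
  etas_logit <- stats::rnorm(n_subjects, 0, ordinal$eta_sd)

  res <- vector("list", n_subjects)
  sleeps <- vector("list", n_subjects)
  for (j in seq_len(n_subjects)) {
    prm_j <- prm
    prm_j$p <- phases[j] %% 24
    sl <- if (is.null(sleep)) {
      generate_sleep(duties, generator_rule("default"), prm_j,
                     horizon = horizon)
    } else sleep
    sleeps[[j]] <- sl
    tt <- .rating_times(n_days, ratings_per_day, duties, t0 = horizon[1],
                        sampling = sampling)
    # only awake ratings after the first completed sleep
    keep <- tt >= sl$end[1]
    for (k in seq_len(nrow(sl))) keep <- keep & !(tt >= sl$start[k] & tt < sl$end[k])
    tt <- tt[keep]
    if (!length(tt)) next
    tr <- alertness_trajectory(sl, duties, prm_j, times = tt)
    kss <- if (transfer == "linear") {
      raw <- a + b * tr$score + etas[j] + stats::rnorm(length(tt), 0, residual_sd)
      if (discretize) pmin(pmax(round(raw), 1), 9) else raw
    } else {
      pr <- kss_probabilities(tr$score, ordinal, offset = etas_logit[j])
      apply(pr, 1, function(p) sample(1:9, 1, prob = p))
    }
    if (discretize || transfer == "ordinal") kss <- as.integer(kss)
    res[[j]] <- data.frame(time = tt, kss = kss,
                           subject_id = sprintf("S%03d", j),
                           circadian_type = types[j])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "truth") <- list(
    phases = phases, etas = etas, etas_logit = etas_logit, types = types,
    a = a, b = b, eta_sd = eta_sd, residual_sd = residual_sd,
    daily_rate = prm$daily_rate, prm = prm
  )
  attr(out, "sleep") <- sleeps
  out
}

#' Write the canonical fixture suite
#'
#' Produces the small plain-text fixtures used by the tests: a 3-day
#' shorthaul roster with sleep and ratings, a 10-day longhaul roster with a
#' +8 h rotation, deliberately malformed logs for the validators, and a
#' JSON manifest of expected row counts. Regeneration with the same seed is
#' byte-identical.
#'
#' @param out_dir Output directory (created if missing).
#' @param seed RNG seed.
#' @return Invisibly, the manifest as a list.
#' @export
make_fixture_suite <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)

  duties3 <- simulate_roster(3, "shorthaul", seed = seed)
  write_roster_csv(duties3, fp("duties_shorthaul.csv"))
  sleep3 <- generate_sleep(duties3, generator_rule("default"),
                           horizon = c(min(duties3$start) - 24,
                                       max(duties3$end) + 24))
  write_roster_csv(sleep3, fp("sleep_shorthaul.csv"))
  ratings3 <- simulate_ratings(duties3, n_subjects = 3, ratings_per_day = 4,
                               seed = seed)
  write_roster_csv(ratings3, fp("ratings_shorthaul.csv"))

  duties10 <- simulate_roster(10, "longhaul", tz_sequence = c(8, 0),
                              seed = seed)
  write_roster_csv(duties10, fp("duties_longhaul.csv"))

  # malformed on purpose: inverted interval, overlap, impossible tz jump
  bad_sleep <- data.frame(start = c(23, 30, 29), end = c(31, 28, 36),
                          provenance = "observed")
  write_roster_csv(bad_sleep, fp("bad_sleep.csv"))
  bad_duties <- data.frame(start = c(8, 30), end = c(16, 40),
                           dep_tz = c(0, 0), arr_tz = c(26, 0),
                           label = "duty")
  write_roster_csv(bad_duties, fp("bad_duties.csv"))

  manifest <- list(
    seed = seed,
    duties_shorthaul = nrow(duties3),
    sleep_shorthaul = nrow(sleep3),
    ratings_shorthaul = nrow(ratings3),
    duties_longhaul = nrow(duties10),
    bad_sleep = nrow(bad_sleep),
    bad_duties = nrow(bad_duties)
  )
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE)
  invisible(manifest)
}
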