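test_that("a single sleep-wake cycle composes the scalar processes", {
  # 8 h sleep then 16 h wake, C and U off, unbraked, starting at ss = 7.96
  prm <- tpm_params(use_c = FALSE, use_u = FALSE, use_brake = FALSE,
                    sleep_on_threshold = 7.96)
  sleep <- data.frame(start = 23, end = 31)
  tr <- alertness_trajectory(sleep, prm = prm, to = 47)
  # initial solve with only S enabled: ss = threshold = 7.96
  expect_equal(tr$S[1], 7.96)
  i_wake <- which(tr$time_h == 31)
  expect_equal(tr$S[i_wake], 14.0, tolerance = 1e-9)
  # decay thereafter per the wake equation
  i16 <- which(tr$time_h == 47)
  expect_equal(tr$S[i16], homeostatic_wake(14.0, 16, prm), tolerance = 1e-9)
  expect_equal(tr$score, tr$S) # only S contributes
})

test_that("with every process off except C the trajectory equals process C", {
  prm <- tpm_params(use_s = FALSE, use_u = FALSE, use_w = FALSE)
  sleep <- regular_sleep(2)
  tr <- alertness_trajectory(sleep, prm = prm)
  expect_equal(tr$score, process_c(tr$time_h %% 24, prm$p), tolerance = 1e-12)
})

test_that("with only S enabled the trajectory is independent of clock time", {
  prm <- tpm_params(use_c = FALSE, use_u = FALSE, use_w = FALSE)
  tr1 <- alertness_trajectory(regular_sleep(2, onset = 23), prm = prm, to = 60)
  tr2 <- alertness_trajectory(regular_sleep(2, onset = 29), prm = prm, to = 66)
  expect_equal(tr1$score, tr2$score, tolerance = 1e-12)
})

test_that("S is continuous at transitions and bounded on randomized timelines", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- sample(2:5, 1)
    onset <- cumsum(c(runif(1, 20, 26), runif(n - 1, 16, 30)))
    sleep <- data.frame(start = onset, end = onset + runif(n, 3, 10))
    prm <- tpm_params(use_brake = sample(c(TRUE, FALSE), 1))
    tr <- alertness_trajectory(sleep, prm = prm, grid_step = 1 / 60)
    expect_true(all(tr$S >= prm$la - 1e-9 & tr$S <= prm$ha + 1e-9))
    # S continuous: largest jump between 1-min grid points stays small
    expect_lt(max(abs(diff(tr$S))), 0.05)
    # exact continuity at each boundary: closed-form limits agree
    for (k in seq_len(nrow(sleep))) {
      i <- which(tr$time_h == sleep$end[k])
      if (length(i) && i < nrow(tr)) {
        left <- tr$S[i] # first wake point, equals sleep branch limit
        ss <- tr$S[which(tr$time_h == sleep$start[k])]
        dur <- sleep$end[k] - sleep$start[k]
        expected <- if (prm$use_brake) homeostatic_sleep_braked(ss, dur, prm)
                    else homeostatic_sleep(ss, dur, prm)
        expect_equal(left, expected, tolerance = 1e-9)
      }
    }
  }
})

test_that("longer prior wake lowers S at onset and during the first sleep hour", {
  prm <- tpm_params()
  mk <- function(wake_len) {
    s1 <- data.frame(start = c(23, 31 + wake_len), end = c(31, 39 + wake_len))
    alertness_trajectory(s1, prm = prm, grid_step = 1 / 12)
  }
  short <- mk(14); long <- mk(20)
  onset_s <- short$S[short$time_h == 45]
  onset_l <- long$S[long$time_h == 51]
  expect_gt(onset_s, onset_l)
  # braked S stays lower during the first hour of the second sleep
  in_first_hour <- function(tr, t0) tr$S[tr$time_h > t0 & tr$time_h <= t0 + 1]
  expect_true(all(in_first_hour(short, 45) > in_first_hour(long, 51)))
})

test_that("initial condition solves the generator score from enabled components", {
  sleep <- data.frame(start = 23.4, end = 31)
  prm <- tpm_params() # S + C + U enabled
  tr <- alertness_trajectory(sleep, prm = prm)
  tod <- 23.4 %% 24
  expect_equal(tr$S[1],
               8.38 - process_c(tod, 16.8) - process_u(tod, 16.8),
               tolerance = 1e-9)
  # U disabled: solve S + C = threshold instead
  prm2 <- tpm_params(use_u = FALSE)
  tr2 <- alertness_trajectory(sleep, prm = prm2)
  expect_equal(tr2$S[1], 8.38 - process_c(tod, 16.8), tolerance = 1e-9)
})

test_that("trajectory errors and warm-up metadata behave as specified", {
  expect_error(alertness_trajectory(data.frame(start = numeric(0),
                                               end = numeric(0))),
               "empty timeline")
  sleep <- regular_sleep(2)
  expect_error(alertness_trajectory(sleep, from = 10), "initial_sw")
  # explicit initial S permits a leading wake episode
  tr <- alertness_trajectory(sleep, from = 10, initial_sw = 14)
  expect_equal(tr$S[1], 14)
  expect_equal(attr(tr, "warmup_end"), sleep$end[2])
  expect_true(is.na(attr(alertness_trajectory(regular_sleep(1)),
                         "warmup_end")))
})

test_that("acclimatization shifts the phase used by C and U", {
  duties <- data.frame(start = c(10), end = c(20), dep_tz = 0, arr_tz = 8)
  sleep <- data.frame(start = c(-1, 23, 47), end = c(7, 31, 55))
  prm <- tpm_params(daily_rate = 0.5)
  tr <- alertness_trajectory(sleep, duties, prm)
  expect_equal(tr$phase_used[tr$time_h < 20], rep(16.8, sum(tr$time_h < 20)))
  expect_equal(tr$phase_used[tr$time_h == 44], 16.8 + 4, tolerance = 1e-9)
  expect_equal(tr$C, process_c(tr$time_h %% 24, tr$phase_used),
               tolerance = 1e-12)
})
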