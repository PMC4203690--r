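test_that("phase extraction reproduces the quadrant table", {
  expect_equal(extract_phase(0.649, 0.631), 15.05, tolerance = 5e-3)
  expect_equal(extract_phase(0, 1), 12)
  expect_equal(extract_phase(1, 0), 18)
  expect_error(extract_phase(0, 0), "undefined")
})

test_that("phase extraction inverts known-phase cosines over the full circle", {
  # brute-force oracle: sleepiness cosine with acrophase (phi + 12) has
  # sine/cosine coefficients sin(w(phi+12)), cos(w(phi+12)); extraction
  # must return phi for every phi on a 0.1 h grid
  w <- 2 * pi / 24
  phis <- seq(0, 23.9, by = 0.1)
  got <- extract_phase(sin(w * (phis + 12)), cos(w * (phis + 12)))
  expect_equal(phase_distance(got, phis), rep(0, length(phis)),
               tolerance = 1e-9)
  # cross-check one case against an lm fit on a dense sampled cosine
  tt <- seq(0, 47.9, by = 0.1)
  y <- 0.9 * cos(w * (tt - (15 + 12)))
  fit <- lm(y ~ sin(w * tt) + cos(w * tt))
  expect_equal(unname(extract_phase(coef(fit)[2], coef(fit)[3])), 15,
               tolerance = 1e-6)
  expect_equal(unname(extract_amplitude(coef(fit)[2], coef(fit)[3])), 0.9,
               tolerance = 1e-6)
})

test_that("amplitude is the Euclidean norm and rotation invariant", {
  expect_equal(extract_amplitude(0.649, 0.631), 0.905, tolerance = 1e-3)
  expect_equal(extract_amplitude(0, 1), 1)
  expect_equal(extract_amplitude(3, 4), 5)
  th <- seq(0, 2 * pi, length.out = 25)
  expect_equal(extract_amplitude(2 * sin(th), 2 * cos(th)),
               rep(2, 25), tolerance = 1e-12)
})

test_that("cosinor fit recovers a pure cosine phase exactly", {
  set.seed(7)
  tt <- runif(600, 0, 24 * 7)
  kss <- 5 + 1.1 * cos(2 * pi * (tt - (15 + 12)) / 24)
  ratings <- data.frame(kss = kss, time = tt,
                        subject_id = rep(sprintf("S%d", 1:6), each = 100))
  fit <- suppressWarnings(fit_cosinor(ratings))
  expect_equal(fit$phase, 15, tolerance = 0.02)
  expect_equal(fit$amplitude, 1.1, tolerance = 0.02)
})

test_that("empirical-Bayes subject phases shrink toward the group mean", {
  set.seed(8)
  n_sub <- 30; n_per <- 40
  true_phase <- rnorm(n_sub, 15, 0.5)
  rows <- lapply(seq_len(n_sub), function(j) {
    tt <- runif(n_per, 0, 24 * 5)
    data.frame(
      kss = 5 + 1.1 * cos(2 * pi * (tt - (true_phase[j] + 12)) / 24) +
        rnorm(n_per, 0, 1),
      time = tt, subject_id = sprintf("S%02d", j))
  })
  ratings <- do.call(rbind, rows)
  fit <- suppressWarnings(fit_cosinor(ratings, random_effects = TRUE))
  expect_equal(length(fit$subject_phases), n_sub)
  expect_equal(fit$phase, 15, tolerance = 0.25)
  # shrinkage: EB phase spread no larger than the generating spread
  expect_lte(sd(fit$subject_phases), sd(true_phase) + 0.05)
  expect_error(fit_cosinor(ratings[ratings$subject_id == "S01", ],
                           random_effects = TRUE), "2 subjects")
})

test_that("rate sweep is flat without time-zone changes and accepts one rate", {
  duties <- simulate_roster(3, "shorthaul", seed = 13) # all offsets zero
  r <- simulate_ratings(duties, n_subjects = 5, ratings_per_day = 5,
                        phase_sd = 0, seed = 13)
  sleeps <- attr(r, "sleep")
  sleep <- do.call(rbind, lapply(seq_along(sleeps), function(j)
    cbind(sleeps[[j]], subject_id = sprintf("S%03d", j))))
  sw <- suppressWarnings(rate_sweep(r, sleep, duties,
                                    rates = c(0, 0.5, 1)))
  expect_equal(diff(sw$logLik), c(0, 0), tolerance = 1e-6)
  one <- suppressWarnings(rate_sweep(r, sleep, duties, rates = 0.5))
  expect_equal(nrow(one), 1)
  expect_equal(attr(one, "best_rate"), 0.5)
  expect_error(rate_sweep(r, sleep, duties, rates = c(0.5, 1.2)), "rates")
})

test_that("model comparison flags deviance above the critical value", {
  cmp0 <- compare_models(list(logLik = -100), list(logLik = -100))
  expect_equal(cmp0$deviance, 0)
  expect_false(cmp0$significant)
  cmp <- compare_models(-100, -110)
  expect_equal(cmp$deviance, 20)
  expect_true(cmp$significant)
  # absolute difference: order of arguments does not matter
  expect_equal(compare_models(-110, -100)$deviance, 20)
})

test_that("adding a real circadian component is detected by deviance", {
  # simulated data with a true C component: S+C model beats S-only
  # (rotating roster so time of day is not confounded with time awake)
  set.seed(9)
  duties <- simulate_roster(5, "rotating", seed = 9)
  ratings <- simulate_ratings(duties, n_subjects = 15, ratings_per_day = 6,
                              sampling = "uniform", seed = 9)
  sleeps <- attr(ratings, "sleep")
  sc_s <- sc_sc <- rep(NA_real_, nrow(ratings))
  prm_s <- tpm_params(use_c = FALSE, use_u = FALSE)
  prm_sc <- tpm_params(use_u = FALSE)
  for (j in seq_along(sleeps)) {
    sel <- ratings$subject_id == sprintf("S%03d", j)
    if (!any(sel)) next
    sc_s[sel] <- alertness_trajectory(sleeps[[j]], duties, prm_s,
                                      times = ratings$time[sel])$score
    sc_sc[sel] <- alertness_trajectory(sleeps[[j]], duties, prm_sc,
                                       times = ratings$time[sel])$score
  }
  f_s <- suppressWarnings(fit_linear_transfer(
    data.frame(kss = ratings$kss, score = sc_s,
               subject_id = ratings$subject_id)))
  f_sc <- suppressWarnings(fit_linear_transfer(
    data.frame(kss = ratings$kss, score = sc_sc,
               subject_id = ratings$subject_id)))
  cmp <- compare_models(f_sc, f_s)
  expect_gt(f_sc$logLik, f_s$logLik)
  expect_true(cmp$significant)
})
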