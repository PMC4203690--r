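test_that("linear transfer maps scores to KSS with reporting clip", {
  tr <- linear_transfer("default")
  expect_equal(kss_mean(10, tr), 4.6)
  expect_equal(kss_mean(16, tr), 1.0) # exact boundary 10.6 - 9.6
  expect_equal(kss_mean(20, tr, clip = FALSE), 10.6 - 0.6 * 20)
  tr5c <- linear_transfer(a = 9.68, b = -0.46)
  expect_equal(kss_mean(8.38, tr5c), 9.68 - 0.46 * 8.38)
  expect_equal(kss_mean(8.38, tr5c), 5.825, tolerance = 1e-3)
  expect_error(linear_transfer(b = 0.5), "negative")
})

test_that("reference offsets are inverse-normal quantiles times the subject SD", {
  expect_equal(reference_offset(0.5, 0.839), 0)
  expect_equal(reference_offset(0.90, 0.839), 1.07, tolerance = 1e-2)
  expect_equal(reference_offset(0.75, 0.839), 0.57, tolerance = 1e-2)
  expect_equal(reference_offset(0.90, 1.10), 1.41, tolerance = 1e-2)
  expect_equal(reference_offset(0.75, 1.10), 0.74, tolerance = 1e-2)
  # symmetry of the normal quantile
  expect_equal(reference_offset(0.25, 1.3), -reference_offset(0.75, 1.3))
  expect_error(reference_offset(1.2, 1), "coverage")
})

test_that("ordinal probabilities are a proper, monotone distribution", {
  tr <- ordinal_transfer("s_b_c_u_5c")
  # logistic at zero: xb + offset at the 6th cut point gives P(KSS > 6) = 0.5
  score_at_k6 <- tr$cutpoints[6] / tr$slope
  expect_equal(kss_exceedance(score_at_k6, tr, level = 7), 0.5)
  # normalization and nonnegativity on a dense score grid
  p <- kss_probabilities(seq(-5, 25, by = 0.1), tr)
  expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-12)
  expect_true(all(p >= 0))
  # exceedance curves nonincreasing in k at any score
  xb <- tr$slope * 10
  exceed <- stats::plogis(xb - tr$cutpoints)
  expect_true(all(diff(exceed) <= 0))
  # sleepier (lower score) means higher severe-sleepiness probability
  p7 <- kss_exceedance(seq(20, 0, by = -0.5), tr, level = 7)
  expect_true(all(diff(p7) > 0))
  expect_error(ordinal_transfer(cutpoints = c(1:7, 5), slope = -1,
                                eta_sd = 1), "increasing")
})

test_that("linear mean and ordinal mode move in the same direction", {
  tr_lin <- linear_transfer("5c")
  tr_ord <- ordinal_transfer("s_b_c_u_5c")
  scores <- seq(2, 16, by = 0.05)
  means <- kss_mean(scores, tr_lin, clip = FALSE)
  modes <- apply(kss_probabilities(scores, tr_ord), 1, which.max)
  expect_true(all(diff(means) < 0))
  expect_true(all(diff(modes) <= 0)) # mode never increases with alertness
})

test_that("risk curves are ordered by coverage and vanish at high alertness", {
  traj <- data.frame(time_h = 0:10, score = seq(14, 4, by = -1))
  rc <- risk_curve(traj, coverages = c(0.5, 0.75, 0.9))
  expect_true(all(rc$p_ge7_90 >= rc$p_ge7_75))
  expect_true(all(rc$p_ge7_75 >= rc$p_ge7_50))
  # constant maximal alertness: near-zero severe risk
  top <- risk_curve(data.frame(time_h = 0:5, score = rep(16.8, 6)))
  expect_true(all(top$p_ge7_90 < 0.02))
  # coverage 0.5 equals the zero-offset curve
  expect_equal(rc$p_ge7_50,
               kss_exceedance(traj$score, ordinal_transfer("s_b_c_u_5c")))
})

test_that("predict_kss combines both transfers per time point", {
  sleep <- regular_sleep(2)
  tr <- alertness_trajectory(sleep)
  pk <- predict_kss(tr)
  expect_equal(nrow(pk), nrow(tr))
  expect_true(all(c("kss_mean", "kss_p1", "kss_p9", "p_ge7_50",
                    "p_ge7_75", "p_ge7_90") %in% names(pk)))
  expect_equal(rowSums(pk[, paste0("kss_p", 1:9)]), rep(1, nrow(pk)),
               tolerance = 1e-12)
  expect_true(all(pk$kss_mean >= 1 & pk$kss_mean <= 9))
})

test_that("fitting recovers a known linear transfer from simulated ratings", {
  set.seed(42)
  n_sub <- 100; n_per <- 50
  a <- 9.68; b <- -0.46; eta_sd <- 0.84; res_sd <- 1.42
  score <- runif(n_sub * n_per, 4, 14)
  subject <- rep(sprintf("S%03d", 1:n_sub), each = n_per)
  eta <- rep(rnorm(n_sub, 0, eta_sd), each = n_per)
  kss <- a + b * score + eta + rnorm(n_sub * n_per, 0, res_sd)
  fit <- fit_linear_transfer(data.frame(kss = kss, score = score,
                                        subject_id = subject))
  expect_lt(abs(fit$transfer$a - a), 2 * fit$se_a)
  expect_lt(abs(fit$transfer$b - b), 2 * fit$se_b)
  expect_equal(fit$transfer$eta_sd, eta_sd, tolerance = 0.2)
  expect_equal(fit$transfer$residual_sd, res_sd, tolerance = 0.05)
  # noiseless data recovers the coefficients exactly
  fit0 <- suppressWarnings(fit_linear_transfer(
    data.frame(kss = a + b * score, score = score, subject_id = subject)))
  expect_equal(fit0$transfer$a, a, tolerance = 1e-6)
  expect_equal(fit0$transfer$b, b, tolerance = 1e-6)
  expect_error(fit_linear_transfer(data.frame(kss = 1:5, score = rep(3, 5),
                                              subject_id = "a")),
               "zero variance")
})
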