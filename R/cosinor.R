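#' Acrophase from 24 h sine/cosine regression coefficients
#'
#' Converts cosinor coefficients for sleepiness ratings into the acrophase
#' of the underlying alertness process, in decimal hours:
#' `arctan(beta_sin/beta_cos) * 24/(2*pi) + K + 12`, where the quadrant
#' constant K is 0, 12, 12 or 24 for coefficient sign patterns (+/+), (+/-),
#' (-/-) and (-/+) respectively (zero counts as positive), wrapped to
#' `[0, 24)`. The fixed +12 h term maps the sleepiness peak onto the
#' alertness acrophase used by process C.
#'
#' @param beta_sin,beta_cos Coefficients of `sin(2*pi*tod/24)` and
#'   `cos(2*pi*tod/24)` (vectorized).
#' @return Phase in decimal hours, in `[0, 24)`.
#' @examples
#' extract_phase(0.649, 0.631) # about 15.05 h
#' @export
extract_phase <- function(beta_sin, beta_cos) {
  if (any(beta_sin == 0 & beta_cos == 0)) {
    stop("phase undefined: both coefficients are zero")
  }
  K <- ifelse(beta_sin >= 0,
              ifelse(beta_cos >= 0, 0, 12),
              ifelse(beta_cos >= 0, 24, 12))
  ph <- atan(beta_sin / beta_cos) * 24 / (2 * pi) + K + 12
  ph %% 24
}

#' Amplitude from 24 h sine/cosine regression coefficients
#'
#' Euclidean norm `sqrt(beta_sin^2 + beta_cos^2)`, in the units of the
#' regressed outcome (KSS units when fitted to sleepiness ratings).
#'
#' @inheritParams extract_phase
#' @return Amplitude (`>= 0`).
#' @examples
#' extract_amplitude(0.649, 0.631) # about 0.91
#' @export
extract_amplitude <- function(beta_sin, beta_cos) {
  sqrt(beta_sin^2 + beta_cos^2)
}

#' Circular distance between two phases
#'
#' Shortest distance on the 24 h circle, `min(|dphase|, 24 - |dphase|)`.
#'
#' @param a,b Phases in decimal hours.
#' @return Distance in hours, in `[0, 12]`.
#' @export
phase_distance <- function(a, b) {
  d <- abs((a - b) %% 24)
  pmin(d, 24 - d)
}

#' Cosinor analysis of sleepiness ratings
#'
#' Mixed-model regression of KSS on 24 h sine and cosine terms of time of
#' day with a subject random intercept, optionally with (uncorrelated)
#' random sine/cosine coefficients per subject. An optional homeostatic
#' score column is included as a covariate to remove the effect of time
#' awake before estimating the circadian shape. Group phase and amplitude
#' are derived from the fixed coefficients via [extract_phase()] and
#' [extract_amplitude()]; with random coefficients, per-subject phases are
#' empirical-Bayes (BLUP) estimates -- shrunken toward the group mean, so
#' their spread understates the true between-subject phase variance.
#'
#' @param ratings Data frame with columns `kss`, `time` (decimal hours;
#'   time of day is `time %% 24`) and `subject_id`, plus optionally the
#'   covariate named by `adjust`.
#' @param adjust Name of a covariate column to adjust for (e.g. a
#'   process-S score), or `NULL`.
#' @param random_effects Also fit per-subject random sine/cosine
#'   coefficients (required for empirical-Bayes subject phases)?
#' @return A `tpm_cosinor` object: `beta_sin`, `beta_cos`, `phase`,
#'   `amplitude`, `sd_sin`, `sd_cos`, `subject_phases`, `logLik`, `n`, and
#'   the underlying `fit`.
#' @export
fit_cosinor <- function(ratings, adjust = NULL, random_effects = FALSE) {
  stopifnot(all(c("kss", "time", "subject_id") %in% names(ratings)))
  d <- data.frame(
    kss = ratings$kss,
    sin24 = sin(2 * pi * (ratings$time %% 24) / 24),
    cos24 = cos(2 * pi * (ratings$time %% 24) / 24),
    subject_id = factor(ratings$subject_id)
  )
  if (!is.null(adjust)) d$adj <- ratings[[adjust]]
  tod <- ratings$time %% 24
  if (diff(range(tod)) < 6) {
    warning("time-of-day coverage spans < 6 h; cosinor fit will be unstable")
  }
  if (random_effects && nlevels(d$subject_id) < 2) {
    stop("random effects require at least 2 subjects")
  }
  rhs <- "sin24 + cos24"
  if (!is.null(adjust)) rhs <- paste(rhs, "+ adj")
  re <- if (random_effects) {
    "(1 | subject_id) + (0 + sin24 | subject_id) + (0 + cos24 | subject_id)"
  } else {
    "(1 | subject_id)"
  }
  f <- stats::as.formula(paste("kss ~", rhs, "+", re))
  fit <- lme4::lmer(f, data = d, REML = FALSE)
  fx <- lme4::fixef(fit)
  b_sin <- unname(fx["sin24"])
  b_cos <- unname(fx["cos24"])
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_of <- function(term) {
    i <- which(vc$var1 == term & is.na(vc$var2))
    if (length(i)) vc$sdcor[i[1]] else NA_real_
  }
  subject_phases <- NULL
  if (random_effects) {
    re_mat <- lme4::ranef(fit)$subject_id
    bs <- b_sin + (if ("sin24" %in% names(re_mat)) re_mat$sin24 else 0)
    bc <- b_cos + (if ("cos24" %in% names(re_mat)) re_mat$cos24 else 0)
    subject_phases <- stats::setNames(extract_phase(bs, bc), rownames(re_mat))
  }
  structure(list(
    beta_sin = b_sin, beta_cos = b_cos,
    phase = extract_phase(b_sin, b_cos),
    amplitude = extract_amplitude(b_sin, b_cos),
    sd_sin = sd_of("sin24"), sd_cos = sd_of("cos24"),
    subject_phases = subject_phases,
    logLik = as.numeric(stats::logLik(fit)),
    n = nrow(d), fit = fit
  ), class = "tpm_cosinor")
}

#' @export
print.tpm_cosinor <- function(x, ...) {
  cat(sprintf("Cosinor fit (n = %d): phase %.2f h, amplitude %.3f\n",
              x$n, x$phase, x$amplitude))
  cat(sprintf("  beta_sin %.3f, beta_cos %.3f, logLik %.1f\n",
              x$beta_sin, x$beta_cos, x$logLik))
  if (!is.null(x$subject_phases)) {
    cat(sprintf("  %d empirical-Bayes subject phases (SD %.2f h)\n",
                length(x$subject_phases), stats::sd(x$subject_phases)))
  }
  invisible(x)
}

#' Fit the linear alertness-to-KSS transfer by mixed regression
#'
#' Random-intercept regression of observed KSS on the model's alertness
#' score, `kss ~ score + (1 | subject)`, fitted by maximum likelihood.
#'
#' @param data Data frame with columns `kss`, `score`, `subject_id`.
#' @return A `tpm_transfer_fit`: `transfer` (a [linear_transfer()]),
#'   `se_a`, `se_b`, `logLik`, `n` and the `fit`.
#' @export
fit_linear_transfer <- function(data) {
  stopifnot(all(c("kss", "score", "subject_id") %in% names(data)))
  if (stats::sd(data$score) == 0) {
    stop("slope undefined: alertness score has zero variance")
  }
  d <- data.frame(kss = data$kss, score = data$score,
                  subject_id = factor(data$subject_id))
  fit <- lme4::lmer(kss ~ score + (1 | subject_id), data = d, REML = FALSE)
  fx <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  eta_sd <- vc$sdcor[vc$grp == "subject_id"][1]
  res_sd <- vc$sdcor[vc$grp == "Residual"][1]
  # fitted transfers report the data as-is: no sign constraint on the slope
  tr <- structure(list(a = unname(fx[1]), b = unname(fx[2]),
                       eta_sd = eta_sd, residual_sd = res_sd),
                  class = "tpm_linear_transfer")
  structure(list(
    transfer = tr,
    se_a = unname(se[1]), se_b = unname(se[2]),
    logLik = as.numeric(stats::logLik(fit)),
    n = nrow(d), fit = fit
  ), class = "tpm_transfer_fit")
}

#' @export
print.tpm_transfer_fit <- function(x, ...) {
  tr <- x$transfer
  cat(sprintf("Linear KSS transfer (n = %d): a = %.3f (SE %.3f), b = %.3f (SE %.3f)\n",
              x$n, tr$a, x$se_a, tr$b, x$se_b))
  cat(sprintf("  eta SD %.3f, residual SD %.3f, logLik %.1f\n",
              tr$eta_sd, tr$residual_sd, x$logLik))
  invisible(x)
}

#' Compare two nested model fits by deviance
#'
#' Deviance is twice the absolute log-likelihood difference. Following the
#' model-comparison convention adopted here, each added process (or process
#' modification) is charged about 2 degrees of freedom, giving a critical
#' deviance of chi-squared approximately 6 at alpha = 0.05. Nesting is the
#' caller's responsibility.
#'
#' @param fit_a,fit_b Objects with a `logLik` element (e.g.
#'   [fit_linear_transfer()] results) or bare numeric log-likelihoods.
#' @param df_assumed Assumed df difference (default 2).
#' @param critical Critical deviance (default 6).
#' @return A `tpm_fit_comparison`: `loglik_a`, `loglik_b`, `deviance`,
#'   `df_assumed`, `significant`.
#' @export
compare_models <- function(fit_a, fit_b, df_assumed = 2, critical = 6) {
  ll <- function(x) if (is.numeric(x)) x else x$logLik
  la <- ll(fit_a); lb <- ll(fit_b)
  dev <- 2 * abs(la - lb)
  structure(list(loglik_a = la, loglik_b = lb, deviance = dev,
                 df_assumed = df_assumed, significant = dev > critical),
            class = "tpm_fit_comparison")
}

#' @export
print.tpm_fit_comparison <- function(x, ...) {
  cat(sprintf("Deviance = %.1f (logL %.1f vs %.1f), df ~ %d: %s\n",
              x$deviance, x$loglik_a, x$loglik_b, x$df_assumed,
              if (x$significant) "significant (chi2 > 6)" else "not significant"))
  invisible(x)
}

#' Alertness scores at rating times for a set of subjects
#'
#' Convenience wrapper evaluating [alertness_trajectory()] per subject at
#' the exact rating times.
#'
#' @param ratings Data frame: `time`, `subject_id`, optionally
#'   `circadian_type`.
#' @param sleep Sleep episodes with `subject_id`, `start`, `end` (or no
#'   `subject_id` column when all subjects share the timeline).
#' @param duties Duty data frame (shared across subjects), or `NULL`.
#' @param prm A [tpm_params()] object.
#' @return Numeric vector of scores aligned with `ratings` rows.
#' @export
scores_at_ratings <- function(ratings, sleep, duties = NULL,
                              prm = tpm_params()) {
  out <- rep(NA_real_, nrow(ratings))
  for (sj in unique(ratings$subject_id)) {
    sel <- ratings$subject_id == sj
    sl <- if ("subject_id" %in% names(sleep)) {
      sleep[sleep$subject_id == sj, , drop = FALSE]
    } else sleep
    ct <- if ("circadian_type" %in% names(ratings)) {
      ratings$circadian_type[sel][1]
    } else NULL
    tr <- alertness_trajectory(sl, duties, prm, times = ratings$time[sel],
                               circadian_type = ct)
    out[sel] <- tr$score[match(round(ratings$time[sel], 9),
                               round(tr$time_h, 9))]
  }
  out
}

#' Sweep the daily acclimatization rate against observed ratings
#'
#' For each candidate daily rate, recomputes every subject's alertness
#' trajectory with that rate, refits the linear KSS transfer
#' (`kss ~ score + (1 | subject)`), and records the log-likelihood. The
#' best-supported rate is the one maximizing the likelihood. On data from a
#' single time zone the criterion is flat (process A never leaves zero).
#'
#' @param ratings Data frame: `time`, `kss`, `subject_id`, optionally
#'   `circadian_type`.
#' @param sleep Sleep episodes (see [scores_at_ratings()]).
#' @param duties Duty data frame with time-zone columns; drives process A.
#' @param rates Candidate daily rates in `[0, 1]` (default 0 to 1 by 0.05).
#' @param prm A [tpm_params()] object (its `daily_rate` is overridden).
#' @return A data frame of class `tpm_rate_sweep` (`rate`, `logLik`) with
#'   attribute `best_rate`.
#' @export
rate_sweep <- function(ratings, sleep, duties, rates = seq(0, 1, by = 0.05),
                       prm = tpm_params()) {
  stopifnot(all(rates >= 0 & rates <= 1))
  ll <- numeric(length(rates))
  for (i in seq_along(rates)) {
    prm_i <- prm
    prm_i$daily_rate <- rates[i]
    sc <- scores_at_ratings(ratings, sleep, duties, prm_i)
    d <- data.frame(kss = ratings$kss, score = sc,
                    subject_id = ratings$subject_id)
    ll[i] <- fit_linear_transfer(d)$logLik
  }
  out <- data.frame(rate = rates, logLik = ll)
  attr(out, "best_rate") <- rates[which.max(ll)]
  class(out) <- c("tpm_rate_sweep", "data.frame")
  out
}

#' @export
print.tpm_rate_sweep <- function(x, ...) {
  cat(sprintf("Acclimatization rate sweep over %d rates; best rate = %.0f%%\n",
              nrow(x), 100 * attr(x, "best_rate")))
  NextMethod()
}
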