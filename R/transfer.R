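#' Linear alertness-to-KSS transfer
#'
#' `KSS = a + b * score (+ eta + eps)`, the linear transformation between
#' the internal alertness score and the Karolinska Sleepiness Scale, with a
#' subject-level random intercept (SD `eta_sd`) and residual error (SD
#' `residual_sd`). The shipped preset `"5c"` carries the transfer fitted for
#' the S_B+C+U score (a = 9.68, b = -0.46, eta_sd = 0.839, residual_sd =
#' 1.417); `"default"` is the legacy transfer (a = 10.6, b = -0.6).
#'
#' @param preset `"default"` or `"5c"`, or `NULL` with fields given.
#' @param a Intercept.
#' @param b Slope (negative: higher alertness score means lower KSS).
#' @param eta_sd Between-subject SD of the random intercept.
#' @param residual_sd Residual SD.
#' @return A `tpm_linear_transfer` object.
#' @export
linear_transfer <- function(preset = c("default", "5c"), a = NULL, b = NULL,
                            eta_sd = NULL, residual_sd = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    default = list(a = 10.6, b = -0.6, eta_sd = 0.839, residual_sd = 1.42),
    `5c` = list(a = 9.68, b = -0.46, eta_sd = 0.839, residual_sd = 1.417)
  )
  tr <- list(
    a = if (is.null(a)) def$a else a,
    b = if (is.null(b)) def$b else b,
    eta_sd = if (is.null(eta_sd)) def$eta_sd else eta_sd,
    residual_sd = if (is.null(residual_sd)) def$residual_sd else residual_sd
  )
  stopifnot("slope b must be negative" = tr$b < 0,
            "eta_sd must be >= 0" = tr$eta_sd >= 0)
  class(tr) <- "tpm_linear_transfer"
  tr
}

#' Predicted mean KSS from an alertness score
#'
#' @param score Internal alertness score (vectorized).
#' @param transfer A [linear_transfer()].
#' @param offset Additive reference-limit offset (see [reference_offset()]).
#' @param clip Clip the reported prediction to the 1-9 KSS range? The
#'   unclipped value is what model fitting uses; clipping is
#'   presentation-only.
#' @return Predicted KSS.
#' @examples
#' kss_mean(10, linear_transfer("default")) # 4.6
#' @export
kss_mean <- function(score, transfer = linear_transfer("default"),
                     offset = 0, clip = TRUE) {
  k <- transfer$a + transfer$b * score + offset
  if (clip) pmin(pmax(k, 1), 9) else k
}

#' Reference-limit offset for a population coverage
#'
#' The additive offset placing a prediction line such that the stated
#' proportion of subjects falls below it: the inverse cumulative normal of
#' the coverage multiplied by the subject random-effect SD,
#' `qnorm(coverage) * sd`.
#'
#' @param coverage Proportion of subjects below the limit, in (0, 1).
#' @param sd Between-subject (random intercept) SD.
#' @return The offset, in the units of the transfer's outcome.
#' @examples
#' reference_offset(0.90, 0.839) # 1.07
#' reference_offset(0.75, 0.839) # 0.57
#' @export
reference_offset <- function(coverage, sd) {
  if (any(coverage <= 0 | coverage >= 1)) stop("coverage must be in (0, 1)")
  if (any(sd < 0)) stop("sd must be >= 0")
  stats::qnorm(coverage) * sd
}

#' Ordinal (proportional-odds) alertness-to-KSS transfer
#'
#' Cumulative-logit model over the nine KSS categories: the probability of
#' observing a rating above category `k` is
#' `plogis(slope * score + offset - K[k])` with eight ordered cut points
#' `K[1..8]`. Two presets ship with the package, named for the alertness
#' score they were fitted to:
#'
#' * `"s_b_c_u_5c"`: score S_B+C+U; cut points (-10.99, -8.95, -7.67,
#'   -6.66, -5.64, -4.30, -3.05, -0.58), subject SD 1.10.
#' * `"s_b_ct_6d"`: score S_B+C_T (type-adjusted phase, no U); cut points
#'   (-11.29, -9.18, -7.82, -6.76, -5.67, -4.27, -3.00, -0.53), subject SD
#'   1.14.
#'
#' The preset slopes (-0.589 and -0.573) are calibrated from the matching
#' linear transfers by logistic rescaling, `b * (pi/sqrt(3)) / residual_sd`
#' (see the methods vignette).
#'
#' @param preset Preset name, or `NULL` with all fields given.
#' @param cutpoints Eight strictly increasing cut points.
#' @param slope Coefficient on the alertness score in the linear predictor.
#' @param eta_sd Subject random-intercept SD on the logit scale.
#' @return A `tpm_ordinal_transfer` object.
#' @export
ordinal_transfer <- function(preset = c("s_b_c_u_5c", "s_b_ct_6d"),
                             cutpoints = NULL, slope = NULL, eta_sd = NULL) {
  if (is.null(cutpoints) || is.null(slope) || is.null(eta_sd)) {
    preset <- match.arg(preset)
    def <- switch(preset,
      s_b_c_u_5c = list(
        cutpoints = c(-10.99, -8.95, -7.67, -6.66, -5.64, -4.30, -3.05, -0.58),
        slope = -0.589, eta_sd = 1.10),
      s_b_ct_6d = list(
        cutpoints = c(-11.29, -9.18, -7.82, -6.76, -5.67, -4.27, -3.00, -0.53),
        slope = -0.573, eta_sd = 1.14)
    )
    if (is.null(cutpoints)) cutpoints <- def$cutpoints
    if (is.null(slope)) slope <- def$slope
    if (is.null(eta_sd)) eta_sd <- def$eta_sd
  }
  stopifnot(
    "exactly 8 cut points are required for the 9-point KSS" =
      length(cutpoints) == 8,
    "cut points must be strictly increasing" = all(diff(cutpoints) > 0),
    "eta_sd must be >= 0" = eta_sd >= 0
  )
  structure(list(cutpoints = cutpoints, slope = slope, eta_sd = eta_sd),
            class = "tpm_ordinal_transfer")
}

#' Probability of each KSS category from an alertness score
#'
#' Differences the cumulative exceedance curve of the proportional-odds
#' transfer: `P(KSS = k) = P(KSS > k-1) - P(KSS > k)` with `P(KSS > 0) = 1`
#' and `P(KSS > 9) = 0`. The result is a probability vector (rows sum to 1,
#' all entries nonnegative).
#'
#' @param score Internal alertness score (vectorized).
#' @param transfer A [ordinal_transfer()].
#' @param offset Additive logit-scale offset: 0 for the average subject, or
#'   [reference_offset()] of a coverage and `transfer$eta_sd` for a
#'   reference limit (positive offsets increase predicted sleepiness).
#' @return A matrix with one row per score and columns `p1`...`p9`.
#' @examples
#' p <- kss_probabilities(8.38, ordinal_transfer("s_b_c_u_5c"))
#' rowSums(p) # 1
#' @export
kss_probabilities <- function(score, transfer = ordinal_transfer("s_b_c_u_5c"),
                              offset = 0) {
  xb <- transfer$slope * score + offset
  exceed <- stats::plogis(outer(xb, transfer$cutpoints, function(x, k) x - k))
  cum <- cbind(1, exceed, 0)
  p <- cum[, 1:9, drop = FALSE] - cum[, 2:10, drop = FALSE]
  colnames(p) <- paste0("p", 1:9)
  rownames(p) <- NULL
  p
}

#' Probability of KSS at or above a level
#'
#' `P(KSS >= level) = P(KSS > level - 1)` under the ordinal transfer.
#'
#' @inheritParams kss_probabilities
#' @param level KSS level in 2..9 (default 7, "severe sleepiness").
#' @return Vector of exceedance probabilities.
#' @export
kss_exceedance <- function(score, transfer = ordinal_transfer("s_b_c_u_5c"),
                           level = 7, offset = 0) {
  stopifnot(level >= 2, level <= 9)
  xb <- transfer$slope * score + offset
  stats::plogis(xb - transfer$cutpoints[level - 1])
}

#' Severe-sleepiness risk curve with reference limits
#'
#' For each time point of a trajectory, the probability of severe
#' sleepiness (KSS >= 7) for the average subject and at each requested
#' population coverage (reference limits below which the stated proportion
#' of subjects fall).
#'
#' @param trajectory A `tpm_trajectory` (or any data frame with `time_h`
#'   and `score`).
#' @param transfer A [ordinal_transfer()].
#' @param coverages Coverage proportions (default 0.5, 0.75, 0.9).
#' @param level KSS level defining "severe" (default 7).
#' @return Data frame: `time_h`, `score`, one `p_ge<level>_<coverage>`
#'   column per coverage.
#' @export
risk_curve <- function(trajectory, transfer = ordinal_transfer("s_b_c_u_5c"),
                       coverages = c(0.5, 0.75, 0.9), level = 7) {
  out <- data.frame(time_h = trajectory$time_h, score = trajectory$score)
  for (cv in coverages) {
    off <- reference_offset(cv, transfer$eta_sd)
    out[[sprintf("p_ge%d_%.0f", level, 100 * cv)]] <-
      kss_exceedance(trajectory$score, transfer, level = level, offset = off)
  }
  out
}

#' Full KSS prediction table for a trajectory
#'
#' Combines the linear transfer (predicted mean KSS) and the ordinal
#' transfer (category probabilities and severe-sleepiness risk at the 50,
#' 75 and 90 percent reference limits) into one table per time point.
#'
#' @param trajectory A `tpm_trajectory`.
#' @param linear A [linear_transfer()].
#' @param ordinal A [ordinal_transfer()].
#' @param coverages Coverages for the severe-sleepiness reference limits.
#' @return Data frame with columns `time_h`, `score`, `kss_mean`,
#'   `kss_p1`..`kss_p9` and `p_ge7_*` risk columns.
#' @export
predict_kss <- function(trajectory, linear = linear_transfer("5c"),
                        ordinal = ordinal_transfer("s_b_c_u_5c"),
                        coverages = c(0.5, 0.75, 0.9)) {
  p <- kss_probabilities(trajectory$score, ordinal)
  colnames(p) <- paste0("kss_", colnames(p))
  out <- cbind(
    data.frame(time_h = trajectory$time_h, score = trajectory$score,
               kss_mean = kss_mean(trajectory$score, linear)),
    as.data.frame(p)
  )
  risk <- risk_curve(trajectory, ordinal, coverages)
  cbind(out, risk[, -(1:2), drop = FALSE])
}
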