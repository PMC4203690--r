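#' Model parameters for the Three Process Model
#'
#' Constructs the full fixed-parameter set of the Three Process Model (TPM)
#' of alertness. Defaults are the published model constants. The homeostatic
#' recovery rate `g` is defined by its calibration identity: eight hours of
#' (unbraked) sleep starting from S = 7.96 recovers alertness to exactly 14.0,
#' i.e. `g = log((ha - 14)/(ha - 7.96))/8`.
#'
#' @param ha Upper asymptote of the internal alertness scale.
#' @param la Lower asymptote.
#' @param d Wake decay rate per hour (negative).
#' @param g Sleep recovery rate per hour (negative); default derived from the
#'   calibration identity above.
#' @param bl Brake level: alertness level below which sleep recovery is
#'   linear ("braked") rather than exponential.
#' @param Wc Sleep inertia magnitude at the moment of waking (negative).
#' @param Wd Sleep inertia recovery rate per hour (negative).
#' @param p Circadian acrophase in decimal hours.
#' @param Ca,Cm Circadian amplitude and mesor (24 h process C).
#' @param Ua,Um Ultradian amplitude and mesor (12 h process U).
#' @param a,b Linear KSS transfer intercept and slope.
#' @param sleep_on_threshold Alertness score below which the sleep generator
#'   initiates sleep.
#' @param wake_threshold Alertness score above which the sleep generator
#'   terminates sleep.
#' @param daily_rate Fraction of the remaining time-zone difference that is
#'   acclimatized per day (process A), in `[0, 1]`.
#' @param use_s Include the homeostatic process S in the combined score?
#' @param use_c Include the circadian process C in the combined score?
#' @param use_brake Use the braked sleep recovery (process S_B)?
#' @param use_u Include the 12 h ultradian process U in the score?
#' @param use_w Include the sleep inertia process W in the score?
#' @param use_type_phase Replace `p` with the circadian-type predicted phase?
#'
#' @return An object of class `tpm_params` (a validated named list).
#' @examples
#' p <- tpm_params()
#' p$g              # approximately -0.3813
#' tpm_params(use_u = FALSE, daily_rate = 0.3)
#' @export
tpm_params <- function(ha = 14.3,
                       la = 2.4,
                       d = -0.0353,
                       g = log((ha - 14.0) / (ha - 7.96)) / 8,
                       bl = 12.2,
                       Wc = -5.72,
                       Wd = -1.51,
                       p = 16.8,
                       Ca = 2.5,
                       Cm = 0,
                       Ua = 0.5,
                       Um = -0.5,
                       a = 10.6,
                       b = -0.6,
                       sleep_on_threshold = 8.38,
                       wake_threshold = 11.38,
                       daily_rate = 0.5,
                       use_s = TRUE,
                       use_c = TRUE,
                       use_brake = TRUE,
                       use_u = TRUE,
                       use_w = FALSE,
                       use_type_phase = FALSE) {
  prm <- list(
    ha = ha, la = la, d = d, g = g, bl = bl,
    Wc = Wc, Wd = Wd,
    p = p, Ca = Ca, Cm = Cm, Ua = Ua, Um = Um,
    a = a, b = b,
    sleep_on_threshold = sleep_on_threshold,
    wake_threshold = wake_threshold,
    daily_rate = daily_rate,
    use_s = isTRUE(use_s), use_c = isTRUE(use_c),
    use_brake = isTRUE(use_brake), use_u = isTRUE(use_u),
    use_w = isTRUE(use_w), use_type_phase = isTRUE(use_type_phase)
  )
  validate_tpm_params(prm)
  structure(prm, class = "tpm_params")
}

validate_tpm_params <- function(prm) {
  stopifnot(
    "la < bl < ha is required" = prm$la < prm$bl && prm$bl < prm$ha,
    "wake decay rate d must be negative" = prm$d < 0,
    "sleep recovery rate g must be negative" = prm$g < 0,
    "inertia recovery rate Wd must be negative" = prm$Wd < 0,
    "amplitudes must be nonnegative" = prm$Ca >= 0 && prm$Ua >= 0,
    "daily_rate must be in [0, 1]" = prm$daily_rate >= 0 && prm$daily_rate <= 1,
    "phase p must be in [0, 24)" = prm$p >= 0 && prm$p < 24,
    "sleep_on_threshold must be below wake_threshold" =
      prm$sleep_on_threshold < prm$wake_threshold
  )
  invisible(prm)
}

#' @export
print.tpm_params <- function(x, ...) {
  cat("Three Process Model parameters\n")
  cat(sprintf("  homeostatic: ha=%.3g la=%.3g d=%.4g g=%.4g bl=%.3g (brake %s)\n",
              x$ha, x$la, x$d, x$g, x$bl, if (x$use_brake) "on" else "off"))
  cat(sprintf("  circadian:   p=%.3g Ca=%.3g Cm=%.3g | ultradian %s: Ua=%.3g Um=%.3g\n",
              x$p, x$Ca, x$Cm, if (x$use_u) "on" else "off", x$Ua, x$Um))
  cat(sprintf("  inertia %s:  Wc=%.3g Wd=%.3g\n",
              if (x$use_w) "on " else "off", x$Wc, x$Wd))
  cat(sprintf("  transfer:    a=%.3g b=%.3g | thresholds %.3g/%.3g | daily rate %.0f%%\n",
              x$a, x$b, x$sleep_on_threshold, x$wake_threshold, 100 * x$daily_rate))
  invisible(x)
}

#' Read or write model parameters as flat JSON
#'
#' Parameters are serialized as a flat JSON object keyed by symbol name so
#' configurations can be versioned alongside rosters.
#'
#' @param prm A `tpm_params` object.
#' @param path File path of the JSON document.
#' @return `read_tpm_params` returns a `tpm_params` object;
#'   `write_tpm_params` invisibly returns `path`.
#' @export
write_tpm_params <- function(prm, path) {
  stopifnot(inherits(prm, "tpm_params"))
  jsonlite::write_json(unclass(prm), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tpm_params
#' @export
read_tpm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(tpm_params, x)
}
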