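#' Homeostatic process during wake
#'
#' Exponential decay of alertness from the level at awakening (`sw`) toward
#' the lower asymptote `la` at rate `d` per hour:
#' `S(taw) = la + (sw - la) * exp(d * taw)`.
#'
#' @param sw Alertness level S at the time of awakening, in `[la, ha]`.
#' @param taw Hours awake since that awakening (vectorized, `>= 0`).
#' @param prm A [tpm_params()] object.
#' @return S values, bounded in `[la, sw]`.
#' @examples
#' prm <- tpm_params()
#' homeostatic_wake(14.3, 16, prm)   # about 9.16 after 16 h awake
#' @export
homeostatic_wake <- function(sw, taw, prm = tpm_params()) {
  if (any(taw < 0)) stop("taw must be >= 0")
  if (sw < prm$la || sw > prm$ha) stop("sw must lie in [la, ha]")
  prm$la + (sw - prm$la) * exp(prm$d * taw)
}

#' Homeostatic process during sleep (unbraked)
#'
#' Exponential recovery from the level at sleep onset (`ss`) toward the upper
#' asymptote `ha` at rate `g` per hour:
#' `S'(tas) = ha + (ss - ha) * exp(g * tas)`.
#' With the default `g`, eight hours of sleep from `ss = 7.96` reach exactly
#' 14.0 (the calibration that defines `g`).
#'
#' @param ss Alertness level S at sleep onset, in `[la, ha]`.
#' @param tas Hours asleep since onset (vectorized, `>= 0`).
#' @param prm A [tpm_params()] object.
#' @return S values, bounded in `[ss, ha]`.
#' @export
homeostatic_sleep <- function(ss, tas, prm = tpm_params()) {
  if (any(tas < 0)) stop("tas must be >= 0")
  if (ss < prm$la || ss > prm$ha) stop("ss must lie in [la, ha]")
  prm$ha + (ss - prm$ha) * exp(prm$g * tas)
}

#' Brake point of the braked sleep recovery
#'
#' Hours of sleep after which the linear low-pressure branch reaches the
#' brake level `bl` and hands over to the exponential branch. Zero when sleep
#' starts at or above `bl`.
#'
#' @inheritParams homeostatic_sleep
#' @return Brake point `bt` in hours (`>= 0`).
#' @export
brake_point <- function(ss, prm = tpm_params()) {
  if (ss >= prm$bl) return(0)
  (prm$bl - ss) / (-prm$g * (prm$ha - prm$bl))
}

#' Homeostatic process during sleep with the recovery brake
#'
#' Splits sleep recovery into a high-pressure branch S'_1 below the brake
#' level `bl` and the exponential branch S'_2 above it. Below `bl` recovery
#' is linear at the rate the exponential would have at `bl`,
#' `(-g) * (ha - bl)` per hour, which slows recovery during most of the
#' sleep; from the brake point `bt` on (see [brake_point()]) the ordinary
#' exponential applies. The two branches are continuous at `tas = bt`.
#'
#' @inheritParams homeostatic_sleep
#' @return S values, nondecreasing in `tas`, bounded above by `ha`.
#' @export
homeostatic_sleep_braked <- function(ss, tas, prm = tpm_params()) {
  if (any(tas < 0)) stop("tas must be >= 0")
  if (ss < prm$la || ss > prm$ha) stop("ss must lie in [la, ha]")
  bt <- brake_point(ss, prm)
  anchor <- if (ss >= prm$bl) ss else prm$bl # level where S'_2 takes over
  lin <- ss + (-prm$g) * (prm$ha - prm$bl) * tas
  exp_branch <- prm$ha + (anchor - prm$ha) * exp(prm$g * pmax(tas - bt, 0))
  ifelse(tas < bt, lin, exp_branch)
}

#' Sleep inertia process W
#'
#' Transient alertness reduction immediately after waking with exponential
#' recovery: `W(taw) = Wc * exp(Wd * taw)`; `W(0) = Wc` and `W -> 0` as time
#' awake grows.
#'
#' @param taw Hours awake since awakening (vectorized, `>= 0`).
#' @param prm A [tpm_params()] object.
#' @return W values in `[Wc, 0]`.
#' @export
sleep_inertia <- function(taw, prm = tpm_params()) {
  if (any(taw < 0)) stop("taw must be >= 0")
  prm$Wc * exp(prm$Wd * taw)
}
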