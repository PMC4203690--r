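Package: tpma
Title: Three Process Model of Alertness for Roster and Aircrew Fatigue Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the extended Three Process Model (TPM) of alertness:
    homeostatic sleep/wake dynamics with the recovery "brake", circadian and
    ultradian processes, sleep inertia, circadian-type phase adjustment and
    gradual time-zone acclimatization. Computes alertness trajectories over
    sleep/wake/duty histories, generates model-based sleep from threshold
    rules, and converts alertness scores into predicted Karolinska Sleepiness
    Scale (KSS) means, individual reference limits and per-category
    probabilities for fatigue-risk assessment of shift schedules and rosters.
    Includes a cosinor / mixed-model validation harness and a synthetic roster
    and ratings simulator for end-to-end parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    lme4
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
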