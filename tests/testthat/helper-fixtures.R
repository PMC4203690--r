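# shared builders for small in-code fixtures

# regular 23:00-07:00 sleeps for n nights, decimal hours from day-0 midnight
regular_sleep <- function(n_nights = 3, onset = 23, length_h = 8) {
  data.frame(start = onset + 24 * (seq_len(n_nights) - 1),
             end = onset + length_h + 24 * (seq_len(n_nights) - 1))
}

# random but structurally valid duty sets for property tests
random_duties <- function(n_days, seed) {
  set.seed(seed)
  st <- 24 * (seq_len(n_days) - 1) + runif(n_days, 6, 12)
  len <- runif(n_days, 4, 10)
  data.frame(start = st, end = st + len, dep_tz = 0, arr_tz = 0,
             label = "duty")
}

# does every generated sleep respect the structural constraints?
check_generator_constraints <- function(sleep, duties, rule) {
  gen <- sleep[sleep$provenance == "generated", , drop = FALSE]
  ok <- TRUE
  for (k in seq_len(nrow(gen))) {
    # duty buffer: no overlap of sleep with [duty start - buffer, duty end + buffer)
    for (d in seq_len(nrow(duties))) {
      if (gen$start[k] < duties$end[d] + rule$duty_buffer &&
          gen$end[k] > duties$start[d] - rule$duty_buffer) {
        ok <- FALSE
      }
    }
    if (gen$end[k] - gen$start[k] < rule$min_sleep - 1e-9) ok <- FALSE
  }
  # min wake gap between successive sleeps
  if (nrow(sleep) > 1) {
    gaps <- sleep$start[-1] - sleep$end[-nrow(sleep)]
    if (any(gaps < rule$min_wake_before_sleep - 1e-9)) ok <- FALSE
  }
  ok
}
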