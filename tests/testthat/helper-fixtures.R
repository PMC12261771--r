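# Programmatic fixtures: small waveform records with known structure.

# A record with four plausible channels over `dur` seconds; channels can be
# overridden or dropped.
make_test_record <- function(dur = 120, drop = character(0),
                             labs = data.frame(time_s = 60, lactate = 1),
                             patient_id = "T001") {
  mk <- function(fs, f) list(fs = fs, samples = f(seq(0, dur - 1 / fs,
                                                      by = 1 / fs)))
  channels <- list(
    ABP = mk(50, function(t) 90 + 20 * sin(2 * pi * 1.2 * t)),
    ECG = mk(100, function(t) 0.05 * sin(2 * pi * 1.2 * t)),
    RESP = mk(10, function(t) sin(2 * pi * t / 4)),
    SPO2 = mk(1, function(t) rep(97, length(t))))
  channels <- channels[setdiff(names(channels), drop)]
  waveform_record(patient_id, channels, labs = labs,
                  covariates = list(age = 60, sex = "F", bmi = 27,
                                    neck = 38, waist = 95))
}

# Triangular ABP beats: rise from lo to hi over half the beat, fall back
# over the other half; the waveform mean is exactly (lo + hi) / 2.
make_triangle_abp <- function(n_beats = 30, beat_s = 1, fs = 50,
                              lo = 60, hi = 100) {
  t <- seq(0, n_beats * beat_s - 1 / fs, by = 1 / fs)
  phase <- (t %% beat_s) / beat_s
  x <- ifelse(phase < 0.5, lo + (hi - lo) * 2 * phase,
              hi - (hi - lo) * 2 * (phase - 0.5))
  list(fs = fs, t0 = 0, samples = x, valid = rep(TRUE, length(x)))
}

# A long low-rate record suitable for window-geometry tests (hours of
# span without waveform bulk).
make_span_record <- function(dur_s, labs = NULL, patient_id = "S001") {
  n <- ceiling(dur_s * 0.1)
  waveform_record(patient_id,
                  list(ABP = list(fs = 0.1, samples = rep(90, n))),
                  labs = labs)
}

# Small drifted cohort shared across property tests (memoised per session).
.cohort_cache <- new.env(parent = emptyenv())
get_small_cohort <- function(n = 8, seed = 402, drift = drift_spec()) {
  key <- paste0("c", n, "_", seed, "_", paste(unlist(drift), collapse = "_"))
  if (is.null(.cohort_cache[[key]])) {
    cfg <- sim_config(n_patients = n, seed = seed, drift = drift)
    .cohort_cache[[key]] <- simulate_cohort(cfg)
  }
  .cohort_cache[[key]]
}
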