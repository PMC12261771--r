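# Generator contracts: determinism, event realizability, drift locality
# and direction, null exchangeability at the feature level.

test_that("identical config and seed give identical patients", {
  cfg <- sim_config(n_patients = 2, seed = 314)
  a <- simulate_patient(cfg, 1)
  b <- simulate_patient(cfg, 1)
  for (nm in names(a$record$channels))
    expect_identical(a$record$channels[[nm]]$samples,
                     b$record$channels[[nm]]$samples)
  expect_identical(a$record$labs, b$record$labs)
  expect_identical(a$truth$onset, b$truth$onset)
  # different patient index gives a different patient
  c2 <- simulate_patient(cfg, 2)
  expect_false(identical(a$record$channels$ABP$samples,
                         c2$record$channels$ABP$samples))
})

test_that("shock prevalence tracks the configured fraction", {
  cfg <- sim_config(n_patients = 100, seed = 56, shock_fraction = 0.5)
  shocks <- vapply(seq_len(100), function(i) {
    set.seed((cfg$seed * 1009L + i * 7919L) %% 2147483647L)
    # replicate only the cheap part of the draw: patient then shock flag
    invisible(shockcast:::.draw_patient(cfg))
    runif(1) < cfg$shock_fraction
  }, logical(1))
  expect_gte(sum(shocks), 35)   # binomial 99.9% interval at n=100, p=0.5
  expect_lte(sum(shocks), 65)
})

test_that("simulated shock satisfies the labeling rule at the true onset", {
  cohort <- get_small_cohort(n = 4, seed = 402)
  for (p in cohort) {
    expect_true(p$truth$shock)
    lab <- label_record(p$record)
    expect_false(is.null(lab$event))
    # detected onset within 2 s of truth (one MAP sample + beat phase)
    expect_lt(abs(lab$event$onset - p$truth$onset), 2.01)
    # the hypotensive excursion happens once, at the event: every detected
    # episode (masking can fragment the run) lies inside the event interval
    ms <- beatwise_map_series(p$record)
    eps <- detect_hypotension_episodes(ms$map_1hz)
    expect_gte(nrow(eps), 1)
    expect_true(all(eps$start >= p$truth$onset - 2 &
                      eps$end <= p$truth$onset + 600))
  }
})

test_that("non-shock patients trigger no events", {
  cfg <- sim_config(n_patients = 2, seed = 88, shock_fraction = 0)
  for (i in 1:2) {
    sim <- simulate_patient(cfg, i)
    expect_false(sim$truth$shock)
    lab <- label_record(sim$record)
    expect_null(lab$event)
    expect_true(all(sim$record$labs$lactate < 2))
  }
})

test_that("zero-effect injection reproduces the record bit for bit", {
  cfg <- sim_config(n_patients = 1, seed = 13, drift = zero_drift())
  sim <- simulate_patient(cfg, 1)
  re <- inject_preshock_drift(sim$record, sim$truth$onset, zero_drift())
  for (nm in names(sim$record$channels))
    expect_identical(re$channels[[nm]]$samples,
                     sim$record$channels[[nm]]$samples)
})

test_that("drift injection never leaks outside its window", {
  cfg <- sim_config(n_patients = 1, seed = 14, drift = zero_drift())
  sim <- simulate_patient(cfg, 1)
  onset <- sim$truth$onset
  drifted <- inject_preshock_drift(sim$record, onset, drift_spec())
  for (nm in names(sim$record$channels)) {
    fs <- sim$record$channels[[nm]]$fs
    w0 <- floor((onset - 5400) * fs) + 1
    w1 <- ceiling(onset * fs)
    a <- sim$record$channels[[nm]]$samples
    b <- drifted$channels[[nm]]$samples
    expect_identical(a[-(w0:w1)], b[-(w0:w1)])
    if (nm != "SPO2")   # SpO2 carries no drift effect
      expect_false(identical(a[w0:w1], b[w0:w1]))
  }
  expect_error(inject_preshock_drift(sim$record, onset - 999, drift_spec()),
               "outside")
})

test_that("respiratory rate effect moves the detected cycle rate", {
  cfg <- sim_config(n_patients = 1, seed = 15, drift = zero_drift())
  sim <- simulate_patient(cfg, 1)
  onset <- sim$truth$onset
  eff <- zero_drift(); eff$resp_rate_bpm <- -3
  drifted <- inject_preshock_drift(sim$record, onset, eff)
  rate_in <- function(rec, iv) {
    sl <- channel_slice(rec, "RESP", iv)
    br <- detect_breath_cycles(sl$samples, sl$fs)
    mean(60 / (br$next_trough_t - br$trough_t))
  }
  iv <- c(onset - 5400, onset - 3600)
  expect_equal(rate_in(drifted, iv), rate_in(sim$record, iv) - 3,
               tolerance = 0.5)
})

test_that("injected feature-family shifts point the documented way", {
  cohort <- get_small_cohort(n = 6, seed = 402)
  keys <- c(pnn50 = "ECG_HRV_pNN50", t2d = "ABP_TimeSBP2DBP_SampEn",
            adbp = "ABP_AmplitudeDBP_Median", width = "RESP_Width_Mean",
            rate = "RESP_Cycle_Rate_Mean")
  dirs <- c(pnn50 = 1, t2d = 1, adbp = -1, width = -1, rate = -1)
  deltas <- matrix(NA_real_, length(cohort), length(keys),
                   dimnames = list(NULL, names(keys)))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    lab <- label_record(p$record)
    fo <- extract_window(p$record, lab$windows[1, ])
    fc <- extract_window(p$record, lab$windows[2, ])
    deltas[i, ] <- colMeans(fo[, keys]) - colMeans(fc[, keys])
  }
  # sign test per family: every patient shifts in the injected direction
  for (k in names(keys))
    expect_true(all(sign(deltas[, k]) == dirs[k]),
                info = paste("family", k))
})

test_that("with zero drift, observation and control features are exchangeable", {
  # one value per (patient, window): sub-windows of a window are strongly
  # correlated, so testing them as independent rows would be miscalibrated
  cohort <- get_small_cohort(n = 10, seed = 402, drift = zero_drift())
  obs <- list(); ctl <- list()
  for (p in cohort) {
    lab <- label_record(p$record)
    fo <- extract_window(p$record, lab$windows[1, ])
    fc <- extract_window(p$record, lab$windows[2, ])
    feats <- shock_catalog()$all
    obs[[length(obs) + 1]] <- colMeans(as.matrix(fo[, feats]), na.rm = TRUE)
    ctl[[length(ctl) + 1]] <- colMeans(as.matrix(fc[, feats]), na.rm = TRUE)
  }
  O <- do.call(rbind, obs); C <- do.call(rbind, ctl)
  pvals <- vapply(seq_len(ncol(O)), function(j) {
    x <- O[is.finite(O[, j]), j]; y <- C[is.finite(C[, j]), j]
    if (length(x) < 5 || length(y) < 5 || (sd(x) == 0 && sd(y) == 0))
      return(NA_real_)
    suppressWarnings(stats::wilcox.test(x, y)$p.value)
  }, 0)
  # after multiplicity control across the whole catalog nothing separates
  padj <- stats::p.adjust(pvals[!is.na(pvals)], method = "holm")
  expect_gte(min(padj), 0.05)
})

test_that("the generator's scenario bookkeeping matches the record span", {
  cfg <- sim_config(n_patients = 1, seed = 19)
  sim <- simulate_patient(cfg, 1)
  expect_true(sim$truth$scenario1_feasible)
  expect_false(sim$truth$scenario2_feasible)
  lab <- label_record(sim$record)
  expect_equal(lab$windows$scenario[lab$windows$role == "control"], "1")
  expect_error(sim_config(n_patients = 1, pre_onset_hours = 1),
               "too short")
})
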