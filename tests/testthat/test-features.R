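test_that("stat battery returns exactly ten statistics in fixed order", {
  v <- stat_battery(c(1, 2, 3, 4, 5))
  expect_length(v, 10)
  expect_identical(names(v), c("Min", "Mean", "Max", "Median", "STD",
                               "Skewness", "Kurtosis", "Hurst", "Lyapunov",
                               "SampEn"))
  # hand-computed moments for 1..5: m2 = 2, m3 = 0, m4 = 6.8
  expect_equal(unname(v["Min"]), 1)
  expect_equal(unname(v["Mean"]), 3)
  expect_equal(unname(v["Max"]), 5)
  expect_equal(unname(v["Median"]), 3)
  expect_equal(unname(v["STD"]), sqrt(2.5))
  expect_equal(unname(v["Skewness"]), 0)
  expect_equal(unname(v["Kurtosis"]), 6.8 / 4 - 3)
})

test_that("stat battery degenerate contracts", {
  v <- stat_battery(rep(7, 20))
  expect_equal(unname(v[c("Min", "Mean", "Max", "Median")]), rep(7, 4))
  expect_equal(unname(v[c("STD", "Skewness", "Kurtosis", "SampEn",
                          "Lyapunov")]), rep(0, 5))
  expect_equal(unname(v["Hurst"]), 0.5)
  expect_true(all(is.na(stat_battery(numeric(0)))))
  expect_length(stat_battery(numeric(0)), 10)
})

test_that("ABP beat parameters recover construction on periodic beats", {
  cfg <- sim_config(n_patients = 1, seed = 5)
  # noise-free strictly periodic beats via the triangle fixture
  tri <- make_triangle_abp(n_beats = 60, beat_s = 0.8, lo = 70, hi = 120)
  pars <- abp_beat_parameters(tri)
  inner <- function(v) v[3:(length(v) - 2)]
  expect_equal(unname(inner(pars$series$Psys)), rep(120, length(inner(pars$series$Psys))),
               tolerance = 0.01)
  expect_equal(median(pars$series$Pdias), 70, tolerance = 0.5)
  expect_equal(median(pars$series$HR), 75, tolerance = 1)
  # identical beats: consecutive systolic/diastolic differences all zero
  expect_true(all(inner(pars$series$AmplitudeSBP) < 0.01))
  expect_true(all(inner(pars$series$AmplitudeDBP) < 0.51))
  expect_lt(sd(inner(pars$series$TimeSBP2DBP)), 0.05)
  # MAP identity: DBP + PP/3
  expect_equal(pars$series$MAP,
               pars$series$Pdias + pars$series$PP / 3)
})

test_that("AmplitudeSBP median is the absolute consecutive difference", {
  # alternating systolic 120/130 -> all consecutive differences 10 mmHg
  fs <- 50; beat <- 0.8
  n_beats <- 40
  sbps <- rep(c(120, 130), n_beats / 2)
  t <- seq(0, beat - 1 / fs, by = 1 / fs)
  x <- unlist(lapply(sbps, function(s)
    ifelse(t %% beat < 0.4, 70 + (s - 70) * (t %% beat) / 0.4,
           s - (s - 70) * ((t %% beat) - 0.4) / 0.4)))
  pars <- abp_beat_parameters(list(fs = fs, t0 = 0, samples = x,
                                   valid = rep(TRUE, length(x))))
  amp <- pars$series$AmplitudeSBP
  expect_equal(median(amp[2:(length(amp) - 1)]), 10, tolerance = 0.2)
})

test_that("per-modality extraction emits exact catalog cardinalities", {
  cohort <- get_small_cohort(n = 4, seed = 402)
  rec <- cohort[[1]]$record
  lab <- label_record(rec)
  w <- lab$windows[1, ]
  iv <- c(w$start, w$start + 600)
  abp <- extract_abp_features(rec, iv)
  ecg <- extract_ecg_features(rec, iv)
  resp <- extract_resp_features(rec, iv)
  spo2 <- extract_spo2_features(rec, iv)
  expect_length(abp, 90); expect_length(ecg, 89)
  expect_length(resp, 112); expect_length(spo2, 8)
  cat <- shock_catalog()
  expect_identical(names(abp), cat$abp)
  expect_identical(names(ecg), cat$ecg)
  expect_identical(names(resp), cat$resp)
  expect_identical(names(spo2), cat$spo2)
  expect_gt(mean(is.finite(c(abp, ecg, resp, spo2))), 0.97)
})

test_that("degenerate windows still emit full key sets as missing-markers", {
  rec <- make_test_record(dur = 700)
  rec$channels$ABP$samples[] <- NA
  rec$channels$ABP$valid[] <- FALSE
  abp <- extract_abp_features(rec, c(0, 600))
  expect_length(abp, 90)
  expect_true(all(is.na(abp)))
  # absent channel: keys present, all NA
  rec2 <- make_test_record(dur = 700, drop = "SPO2")
  spo2 <- extract_spo2_features(rec2, c(0, 600))
  expect_length(spo2, 8)
  expect_true(all(is.na(spo2)))
})

test_that("pNN50 matches the hand count on a four-interval series", {
  v <- hrv_features(c(800, 860, 900, 955))
  # diffs 60, 40, 55 -> two of three exceed 50 ms
  expect_equal(unname(v["pNN50"]), 2 / 3)
  expect_equal(unname(v["MeanNN"]), mean(c(800, 860, 900, 955)))
  expect_equal(unname(v["MCVNN"]),
               mad(c(800, 860, 900, 955)) / median(c(800, 860, 900, 955)))
})

test_that("HRV indices on constant R-R collapse to their zero values", {
  v <- hrv_features(rep(800, 100))
  expect_equal(unname(v[c("SDNN", "RMSSD", "SDSD", "pNN50", "SD1", "SD2")]),
               rep(0, 6))
  expect_equal(unname(v["MeanHR"]), 75)
})

test_that("the full HRV set has 89 members and sane frequency content", {
  set.seed(61)
  n <- 700
  t <- cumsum(rep(0.8, n))
  # 0.1 Hz oscillation (LF band) on the tachogram
  rr <- 800 + 40 * sin(2 * pi * 0.1 * t) + rnorm(n, sd = 5)
  v <- hrv_features(rr, rr_t = t)
  expect_length(v, 89)
  expect_gt(v[["LF"]], v[["HF"]])     # LF tone dominates
  expect_gt(v[["LFn"]], 0.5)
  hf <- hrv_features(800 + 40 * sin(2 * pi * 0.3 * t) + rnorm(n, sd = 5),
                     rr_t = t)
  expect_gt(hf[["HF"]], hf[["LF"]])   # HF tone dominates
})

test_that("SpO2 extraction: constant trace hits the documented fallbacks", {
  rec <- make_test_record(dur = 700)
  v <- extract_spo2_features(rec, c(0, 600))
  expect_equal(unname(v[c("SPO2_Smin", "SPO2_Smean", "SPO2_Smax",
                          "SPO2_Smedian")]), rep(98, 4) - 1)
  expect_equal(unname(v["SPO2_Ssd"]), 0)
  expect_equal(unname(v["SPO2_SampEn"]), 0)
  expect_equal(unname(v["SPO2_CTM"]), 1)
})

test_that("RESP symmetric cycles give 0.5 rise-decay symmetry and exact rate", {
  fs <- 10
  dur <- 660
  t <- seq(0, dur - 1 / fs, by = 1 / fs)
  rec <- make_test_record(dur = dur)
  rec$channels$RESP$samples <- sin(2 * pi * t / 5)  # 12 cycles/min
  rec$channels$RESP$valid <- rep(TRUE, length(t))
  v <- extract_resp_features(rec, c(0, 600))
  expect_length(v, 112)
  expect_equal(unname(v["RESP_Cycle_Rate_Mean"]), 12, tolerance = 0.1)
  expect_equal(unname(v["RESP_Cycle_Symmetry_RiseDecay_Mean"]), 0.5,
               tolerance = 0.03)
  expect_equal(unname(v["RESP_RRV_MeanBB"]), 5, tolerance = 0.05)
})

test_that("window extraction yields five labeled rows with all 299 keys", {
  cohort <- get_small_cohort(n = 4, seed = 402)
  p <- cohort[[2]]
  lab <- label_record(p$record)
  fv <- extract_window(p$record, lab$windows[1, ])
  expect_equal(nrow(fv), 5)
  expect_equal(fv$sub_window, 0:4)
  expect_true(all(fv$label == 1))
  expect_true(all(shock_catalog()$all %in% names(fv)))
  fc <- extract_window(p$record, lab$windows[2, ])
  expect_true(all(fc$label == 0))
  # cohort-level row count: patients x 2 windows x 5 sub-windows
  cohort_feats <- extract_cohort_features(lapply(cohort[1:2], function(q)
    list(record = q$record, windows = label_record(q$record)$windows)))
  expect_equal(nrow(cohort_feats), 2 * 2 * 5)
})
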