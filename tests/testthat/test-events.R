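map_df <- function(map, t0 = 0) data.frame(t = t0 + seq_along(map) - 1,
                                           map = map)

test_that("episode rule boundaries: strictly more than one minute", {
  base <- rep(80, 300)
  m61 <- base; m61[100:160] <- 64          # 61 consecutive seconds
  expect_equal(nrow(detect_hypotension_episodes(map_df(m61))), 1)
  m60 <- base; m60[100:159] <- 64          # exactly 60 s: not an episode
  expect_equal(nrow(detect_hypotension_episodes(map_df(m60))), 0)
  # threshold is inclusive: exactly 65 counts as below-or-at
  m65 <- base; m65[100:170] <- 65
  expect_equal(nrow(detect_hypotension_episodes(map_df(m65))), 1)
})

test_that("two sub-threshold runs separated by recovery give two episodes", {
  m <- rep(80, 400)
  m[50:139] <- 60     # 90 s
  m[150:239] <- 60    # 90 s after 10 s above threshold
  eps <- detect_hypotension_episodes(map_df(m))
  expect_equal(nrow(eps), 2)
  expect_equal(eps$start, c(49, 149))
  expect_true(all(eps$end - eps$start == 90))
})

test_that("episode detector equals a brute-force run-length oracle (fuzz)", {
  set.seed(77)
  for (i in 1:1000) {
    n <- sample(80:400, 1)
    map <- 65 + cumsum(rnorm(n, sd = 2)) + rnorm(n, sd = 4)
    if (i %% 7 == 0) map[sample(n, sample(1:20, 1))] <- NA
    got <- detect_hypotension_episodes(map_df(map))
    want <- episode_oracle(map)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
    }
  }
})

test_that("lactate qualification applies threshold and 12-hour window", {
  eps <- data.frame(start = 10000, end = 10300)
  qual <- function(t_h, val, op = ">=")
    qualify_shock_event(eps, data.frame(time_s = 10000 + t_h * 3600,
                                        lactate = val), lactate_op = op)
  expect_s3_class(qual(6, 2.5), "shock_event")
  expect_s3_class(qual(11.9, 2.0), "shock_event")    # >= 2 at 11.9 h: in
  expect_null(qual(12.5, 2.0))                       # outside 12 h
  expect_null(qual(1, 1.9))                          # below threshold
  expect_null(qual(11.9, 2.0, op = ">"))             # strict operator
  expect_s3_class(qual(-6, 2.2), "shock_event")      # before the event
})

test_that("first qualifying episode wins; unqualified episodes are skipped", {
  eps <- data.frame(start = c(1000, 8200), end = c(1100, 8300))
  labs <- data.frame(time_s = 8200 + 3600, lactate = 3)
  # only the second episode has lactate within 12 h? both do here (11.8 h
  # from the first) - the first episode then wins
  ev <- qualify_shock_event(eps, labs)
  expect_equal(ev$onset, 1000)
  # push the lab out of the first episode's window: second episode wins
  labs2 <- data.frame(time_s = 1000 + 13 * 3600, lactate = 3)
  ev2 <- qualify_shock_event(eps, labs2)
  expect_equal(ev2$onset, 8200)
})

test_that("window construction follows the two washout scenarios", {
  ev <- structure(list(episode_start = 26 * 3600, episode_end = 26 * 3600 +
                         300, onset = 26 * 3600, lactate_time = 27 * 3600,
                       lactate_value = 3), class = "shock_event")
  # record spanning onset - 26 h .. onset + 1 h: scenario 1 fits
  rec <- make_span_record(27 * 3600)
  w <- build_windows(ev, rec)
  expect_equal(nrow(w), 2)
  obs <- w[w$role == "observation", ]
  expect_equal(obs$start, 26 * 3600 - 90 * 60)
  expect_equal(obs$end, 26 * 3600 - 60 * 60)
  expect_equal(obs$label, 1L)
  ctl <- w[w$role == "control", ]
  expect_equal(ctl$scenario, "1")
  expect_equal(ctl$start, 26 * 3600 - 24 * 3600 - 1800)
  expect_equal(ctl$end, 26 * 3600 - 24 * 3600)
  expect_equal(ctl$label, 0L)

  # record starting onset - 2 h and ending onset + 8 d: scenario 2
  ev2 <- ev; ev2$onset <- 2 * 3600; ev2$episode_start <- 2 * 3600
  rec2 <- make_span_record(2 * 3600 + 8 * 86400)
  w2 <- build_windows(ev2, rec2)
  ctl2 <- w2[w2$role == "control", ]
  expect_equal(ctl2$scenario, "2")
  expect_equal(ctl2$start, 2 * 3600 + 7 * 86400)
  expect_equal(ctl2$end, 2 * 3600 + 7 * 86400 + 1800)

  # record spanning only onset +/- 3 h: observation only, no control
  ev3 <- ev; ev3$onset <- 3 * 3600; ev3$episode_start <- 3 * 3600
  rec3 <- make_span_record(6 * 3600)
  w3 <- build_windows(ev3, rec3)
  expect_equal(w3$role, "observation")
  expect_false(any(w3$role == "control"))
})

test_that("windows never overlap the one-hour prediction blackout", {
  for (onset_h in c(26, 30, 40)) {
    ev <- structure(list(episode_start = onset_h * 3600,
                         episode_end = onset_h * 3600 + 120,
                         onset = onset_h * 3600, lactate_time = 0,
                         lactate_value = 3), class = "shock_event")
    w <- build_windows(ev, make_span_record((onset_h + 1) * 3600))
    blackout <- c(ev$onset - 3600, ev$onset)
    expect_true(all(w$end <= blackout[1] | w$start >= blackout[2]))
  }
})

test_that("exclusion rules trigger in order with logged reasons", {
  ev <- structure(list(episode_start = 26 * 3600, episode_end = 26 * 3600 +
                         300, onset = 26 * 3600, lactate_time = 27 * 3600,
                       lactate_value = 3), class = "shock_event")
  mk <- function(record, event = ev,
                 windows = build_windows(ev, record)) {
    list(record = record, event = event, windows = windows)
  }
  # complete patient with all four channels over 26 h at token rates
  full_rec <- waveform_record("F1", list(
    ABP = list(fs = 0.1, samples = rep(90, 27 * 360)),
    ECG = list(fs = 0.1, samples = rep(0, 27 * 360)),
    RESP = list(fs = 0.1, samples = rep(0, 27 * 360)),
    SPO2 = list(fs = 0.1, samples = rep(97, 27 * 360))))
  res <- apply_exclusions(list(mk(full_rec)))
  expect_equal(res$log$status, "included")

  # missing channel
  rec_noresp <- full_rec; rec_noresp$channels$RESP <- NULL
  res <- apply_exclusions(list(mk(rec_noresp)))
  expect_match(res$log$reason, "missing channel")

  # no event
  res <- apply_exclusions(list(mk(full_rec, event = NULL,
                                  windows = full_rec["patient_id"])))
  expect_match(res$log$reason, "no qualifying shock event")

  # under 90 min of pre-onset data (80 min)
  ev80 <- ev; ev80$onset <- 80 * 60; ev80$episode_start <- 80 * 60
  res <- apply_exclusions(list(mk(full_rec, event = ev80,
                                  windows = build_windows(ev80, full_rec))))
  expect_match(res$log$reason, "pre-onset data shorter")

  # 51% masked ABP in the observation window
  rec_miss <- full_rec
  w <- build_windows(ev, rec_miss)
  obs <- w[w$role == "observation", ]
  idx <- shockcast::channel_slice(rec_miss, "ABP",
                                  c(obs$start, obs$end))
  n_obs <- length(idx$samples)
  i0 <- round(obs$start * 0.1) + 1
  kill <- i0:(i0 + ceiling(0.51 * n_obs) - 1)
  rec_miss$channels$ABP$samples[kill] <- NA
  rec_miss$channels$ABP$valid[kill] <- FALSE
  res <- apply_exclusions(list(mk(rec_miss, windows = w)))
  expect_match(res$log$reason, "missing in observation")

  # no feasible control
  ev3h <- ev; ev3h$onset <- 3 * 3600; ev3h$episode_start <- 3 * 3600
  rec_short <- waveform_record("F2", lapply(full_rec$channels, function(ch)
    list(fs = ch$fs, samples = ch$samples[1:(6 * 3600 * ch$fs)])))
  res <- apply_exclusions(list(mk(rec_short, event = ev3h,
                                  windows = build_windows(ev3h, rec_short))))
  expect_match(res$log$reason, "no feasible control")
})

test_that("beat-wise MAP: constant and triangular-beat oracles", {
  # constant 65 mmHg: every beat mean is exactly 65 (where beats exist)
  tri <- make_triangle_abp(n_beats = 40, lo = 65, hi = 65.0001)
  ms <- beatwise_map_series(tri)
  expect_true(all(abs(ms$beats$map - 65) < 0.01))
  # triangular beats: waveform mean is exactly (lo + hi) / 2
  tri2 <- make_triangle_abp(n_beats = 40, lo = 60, hi = 100)
  ms2 <- beatwise_map_series(tri2)
  inner <- ms2$beats$map[3:(nrow(ms2$beats) - 3)]
  expect_true(all(abs(inner - 80) < 1.5))
  expect_equal(median(inner), 80, tolerance = 0.01)
  # flat span raises
  flat <- list(fs = 50, t0 = 0, samples = rep(80, 5000),
               valid = rep(TRUE, 5000))
  expect_error(beatwise_map_series(flat), "no detectable beats")
})
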