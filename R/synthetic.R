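# Seedable generator of multi-channel ICU records with ground-truth shock
# events and configurable pre-shock physiological drift.
#
# Geometry: shock onset sits `pre_onset_hours` into the record. Waveform
# samples are rendered inside "active segments" - a control region suitable
# for the 24-hour-washout control window and a peri-event region covering
# [onset - 2 h, onset + 30 min) - with invalid-masked gaps in between,
# emulating segmented ICU waveform archives. The 90-minute pre-onset drift
# window is realized by switching generative parameters at the drift
# boundary inside a continuous peri-event stream, so injection is local
# without introducing a phase discontinuity into the observation window.
#
# Arterial pressure is a beat train (half-cosine upstroke to the systolic
# peak, exponential-style decay to the next diastolic onset); ECG is an
# R-R-level point process rendered as a spike train; respiration is an
# asymmetric-cosine cycle signal; SpO2 a slowly varying percentage.

#' Pre-shock drift specification
#'
#' Generative-parameter shifts active only inside the 90-minute pre-onset
#' window, targeting the five headline feature families: successive R-R
#' difference jitter (raises pNN50); the white component of the
#' systolic-to-diastolic timing jitter (the baseline timing variation is
#' smooth/autocorrelated, so added white jitter raises the TimeSBP2DBP
#' sample entropy); beat-to-beat diastolic jitter (negative shift lowers
#' the AmplitudeDBP median); respiratory rate; and the relative breath
#' width (rise interval), which is shifted independently of the rate
#' change so a negative value lowers the mean cycle width outright.
#'
#' @param rr_hf_ms Added white R-R jitter SD, ms.
#' @param t2d_white_ms Added white systolic-peak timing jitter SD, ms.
#' @param dbp_jitter_mmhg Change in per-beat diastolic jitter SD, mmHg
#'   (negative = steadier diastolic values).
#' @param resp_rate_bpm Change in respiratory rate, breaths/min.
#' @param width_rel Relative change in the breath rise interval (e.g.
#'   -0.25 = 25% narrower), applied on top of the rate change.
#' @return List of class `drift_spec`.
#' @export
drift_spec <- function(rr_hf_ms = 23, t2d_white_ms = 25,
                       dbp_jitter_mmhg = -1.5, resp_rate_bpm = -3,
                       width_rel = -0.25) {
  structure(list(rr_hf_ms = rr_hf_ms, t2d_white_ms = t2d_white_ms,
                 dbp_jitter_mmhg = dbp_jitter_mmhg,
                 resp_rate_bpm = resp_rate_bpm, width_rel = width_rel),
            class = "drift_spec")
}

#' @rdname drift_spec
#' @export
zero_drift <- function() drift_spec(0, 0, 0, 0, 0)

#' Simulation configuration
#'
#' @param n_patients Cohort size.
#' @param seed Integer seed fixing the full output stream.
#' @param shock_fraction Probability a patient hosts a shock event. The
#'   default 1 mirrors the self-controlled study design in which every
#'   included patient met the shock criteria.
#' @param drift A [drift_spec()]; applied only to shock patients inside
#'   `[onset - 90 min, onset)`.
#' @param rates Per-channel sampling rates (Hz).
#' @param pre_onset_hours,post_onset_hours Record span around the onset.
#' @param ramp_min Minutes over which mean arterial pressure ramps from
#'   baseline towards the threshold (inside the 1-hour blackout).
#' @param episode_min Minutes the hypotensive episode is sustained.
#' @param episode_map Target waveform mean arterial pressure during the
#'   episode (mmHg).
#' @param missing_rate Expected fraction of active samples masked invalid.
#' @param baselines Named list of population means/SDs for patient-level
#'   baselines (systolic/diastolic pressure, heart rate, respiratory rate,
#'   SpO2).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_patients = 20, seed = 1L, shock_fraction = 1,
                       drift = drift_spec(),
                       rates = list(ABP = 50, ECG = 100, RESP = 10,
                                    SPO2 = 1),
                       pre_onset_hours = 24.75, post_onset_hours = 0.5,
                       ramp_min = 10, episode_min = 5, episode_map = 55,
                       missing_rate = 0.02,
                       baselines = list(sbp = c(120, 10), dbp = c(70, 6),
                                        hr = c(80, 8), resp = c(16, 1.5),
                                        spo2 = c(97, 0.8))) {
  stopifnot(n_patients >= 1, shock_fraction >= 0, shock_fraction <= 1,
            missing_rate >= 0, missing_rate <= 1)
  if (shock_fraction > 0 && pre_onset_hours < 2)
    stop("record too short to host the washout and event: need >= 2 h ",
         "of pre-onset data")
  structure(list(n_patients = as.integer(n_patients), seed = as.integer(seed),
                 shock_fraction = shock_fraction, drift = drift,
                 rates = rates, pre_onset_hours = pre_onset_hours,
                 post_onset_hours = post_onset_hours, ramp_min = ramp_min,
                 episode_min = episode_min, episode_map = episode_map,
                 missing_rate = missing_rate, baselines = baselines,
                 # fixed generative noise scales (baseline values; drift
                 # shifts some of them inside the drift window)
                 noise = list(rr_slow_ms = 20, rr_phi = 0.95,
                              rr_hf_ms = 12, sbp_jitter = 2.5,
                              dbp_jitter = 2.5, t2d_ar_ms = 40,
                              t2d_white_ms = 3, s_frac = 0.30,
                              resp_T_sd = 0.25, resp_pf_sd = 0.02,
                              resp_amp_sd = 0.15, peak_frac = 0.35,
                              ecg_noise = 0.03, abp_noise = 0.4,
                              resp_noise = 0.03, spo2_noise = 0.15)),
            class = "sim_config")
}

# ---- latent machinery ----------------------------------------------------

# Sample indices of channel `fs` whose support [i/fs,(i+1)/fs) starts in
# [t0, t1); returns 1-based index range.
.seg_idx <- function(t0, t1, fs) {
  i0 <- max(0L, as.integer(ceiling(t0 * fs - 1e-9)))
  i1 <- as.integer(ceiling(t1 * fs - 1e-9)) - 1L
  if (i1 < i0) return(integer(0))
  seq.int(i0 + 1L, i1 + 1L)
}

# Segment table for one patient. The peri-event segment is one continuous
# stream from two hours before onset to onset: the drift window
# [onset-90min, onset) is realized by switching generative parameters at
# the boundary per beat/cycle, so there is no phase discontinuity inside
# any analysis window, while all time shifts induced by drift stay inside
# the drift window (locality by construction).
.segment_table <- function(onset, cfg) {
  segs <- list(
    list(name = "peri",  t0 = onset - 7200, t1 = onset,
         drift_from = onset - 5400),
    list(name = "event", t0 = onset,        t1 = onset + 1800))
  if (cfg$pre_onset_hours >= 24.5)
    segs <- c(list(list(name = "control1", t0 = onset - 24.6 * 3600,
                        t1 = onset - 23.9 * 3600)), segs)
  if (cfg$post_onset_hours >= 24 * 7 + 0.6)
    segs <- c(segs, list(list(name = "control2",
                              t0 = onset + 7 * 86400 - 360,
                              t1 = onset + 7 * 86400 + 2160)))
  segs
}

# Patient-level baseline draws and derived hemodynamic targets.
.draw_patient <- function(cfg) {
  b <- cfg$baselines
  sbp <- rnorm(1, b$sbp[1], b$sbp[2])
  dbp <- rnorm(1, b$dbp[1], b$dbp[2])
  dbp <- min(dbp, sbp - 25)            # keep a sane pulse pressure
  s_frac <- cfg$noise$s_frac
  # analytic waveform-mean factor for the beat morphology (half-cosine rise,
  # exp(-3) decay): MAP_wave = DBP + kappa * PP
  kappa <- s_frac * 0.5 + (1 - s_frac) * (1 - exp(-3)) / 3
  map0 <- dbp + kappa * (sbp - dbp)
  list(sbp = sbp, dbp = dbp, map0 = map0, kappa = kappa,
       hr = max(45, rnorm(1, b$hr[1], b$hr[2])),
       resp_rate = max(8, rnorm(1, b$resp[1], b$resp[2])),
       spo2 = min(99.5, rnorm(1, b$spo2[1], b$spo2[2])),
       age = round(min(95, max(18, rnorm(1, 65, 15)))),
       sex = if (runif(1) < 0.53) "M" else "F",
       bmi = round(max(15, rnorm(1, 29.6, 7.4)), 1),
       neck = round(max(28, rnorm(1, 38, 4)), 1),
       waist = round(max(60, rnorm(1, 100, 12)), 1))
}

# Pressure level multiplier (scales SBP and DBP so the waveform MAP follows
# the ramp/episode trajectory). Identity for non-shock patients.
.make_level_fun <- function(shock, onset, pat, cfg) {
  if (!shock) return(function(t) rep(1, length(t)))
  f_ramp <- 72 / pat$map0        # ramp ends just above the 65 mmHg rule
  f_ep <- cfg$episode_map / pat$map0
  t_ramp <- onset - cfg$ramp_min * 60
  t_ep_end <- onset + cfg$episode_min * 60
  t_rec <- t_ep_end + 120
  function(t) {
    lvl <- rep(1, length(t))
    i <- t >= t_ramp & t < onset
    lvl[i] <- 1 + (f_ramp - 1) * (t[i] - t_ramp) / (onset - t_ramp)
    i <- t >= onset & t < t_ep_end
    lvl[i] <- f_ep
    i <- t >= t_ep_end & t < t_rec
    lvl[i] <- f_ep + (1 - f_ep) * (t[i] - t_ep_end) / (t_rec - t_ep_end)
    lvl
  }
}

# Per-segment innovation draws. Counts depend only on baseline parameters,
# so re-rendering with shifted parameters reuses the same draws.
.draw_innovations <- function(seg, pat, cfg) {
  len <- seg$t1 - seg$t0
  nb <- ceiling(len / (60 / pat$hr) * 1.6) + 10   # beats, with margin
  nc <- ceiling(len / (60 / (pat$resp_rate + 4))) + 10  # breath cycles
  ns <- length(.seg_idx(seg$t0, seg$t1, cfg$rates$SPO2))
  list(
    abp = list(rr_slow = rnorm(nb), rr_hf = rnorm(nb), sbp = rnorm(nb),
               dbp = rnorm(nb + 1), t2d = rnorm(nb), t2d_w = rnorm(nb)),
    ecg = list(rr_slow = rnorm(nb), rr_hf = rnorm(nb)),
    resp = list(T = rnorm(nc), pf = rnorm(nc), amp = rnorm(nc)),
    spo2 = list(ar = rnorm(ns), noise = rnorm(ns)))
}

# Stationary AR(1): the first draw carries the full marginal SD so every
# segment starts in the stationary regime (no burn-in asymmetry between
# early and late windows).
.ar1 <- function(innov, phi, sdev) {
  scaled <- innov * sdev * sqrt(1 - phi^2)
  scaled[1] <- innov[1] * sdev
  as.numeric(stats::filter(scaled, phi, method = "recursive"))
}

# Per-beat/cycle drift gating: TRUE where the event time (relative to
# segment start) falls at or after the drift boundary.
.in_drift <- function(t_rel, seg) {
  if (is.null(seg$drift_from)) rep(FALSE, length(t_rel))
  else t_rel >= (seg$drift_from - seg$t0)
}

# Beat schedule for a segment: onset times (relative to segment start),
# durations, pressures and systolic-peak fractions. `par` carries baseline
# and drifted values; drifted values apply to beats starting inside the
# drift window.
.abp_beats <- function(seg, pat, cfg, inn, lvl_fun, par) {
  base_rr <- 60 / pat$hr
  nb <- length(inn$rr_slow)
  rr <- base_rr + .ar1(inn$rr_slow, cfg$noise$rr_phi,
                       cfg$noise$rr_slow_ms / 1000) +
    inn$rr_hf * cfg$noise$rr_hf_ms / 1000
  rr <- pmax(rr, 0.35)
  on <- cumsum(c(0, rr[-nb]))
  keep <- on < (seg$t1 - seg$t0)
  on <- on[keep]; rr <- rr[keep]
  k <- length(on)
  dr <- .in_drift(on, seg)
  lvl <- lvl_fun(seg$t0 + on)
  sbp <- pat$sbp * lvl + inn$sbp[seq_len(k)] * cfg$noise$sbp_jitter
  # diastolic value j is shared by beat j (onset) and beat j-1 (decay
  # target); it may only take the drifted jitter when both beats start
  # inside the drift window, otherwise the straddling beat's samples
  # before the boundary would change under injection
  dr_pad <- c(dr, dr[k])
  dr_dbp <- dr_pad & c(FALSE, dr)
  dbp_jit <- ifelse(dr_dbp, par$drift$dbp_jitter, par$base$dbp_jitter)
  dbp_all <- pat$dbp * c(lvl, lvl[k]) + inn$dbp[seq_len(k + 1)] * dbp_jit
  # timing offset of the systolic peak: a smooth autocorrelated part plus
  # a white part; pre-shock drift widens only the white part, which is what
  # raises the sample entropy of the peak-to-diastolic interval series
  t2d_w_sd <- ifelse(dr, par$drift$t2d_white_ms, par$base$t2d_white_ms)
  t2d <- .ar1(inn$t2d, 0.97, cfg$noise$t2d_ar_ms / 1000)[seq_len(k)] +
    inn$t2d_w[seq_len(k)] * t2d_w_sd / 1000
  ps <- pmin(pmax((cfg$noise$s_frac * rr - t2d) / rr, 0.1), 0.75)
  list(on = on, rr = rr, sbp = sbp, dbp = dbp_all[seq_len(k)],
       dbp_next = dbp_all[seq_len(k) + 1], ps = ps)
}

# Vectorized ABP waveform rendering for one segment.
.render_abp <- function(seg, beats, fs, noise_sd, noise) {
  idx <- .seg_idx(seg$t0, seg$t1, fs)
  n <- length(idx)
  t_rel <- (idx - 1) / fs - seg$t0
  k <- findInterval(t_rel, beats$on)
  x <- rep(beats$dbp[1], n)
  inb <- k >= 1
  kk <- k[inb]
  p <- (t_rel[inb] - beats$on[kk]) / beats$rr[kk]
  p <- pmin(p, 1)
  ps <- beats$ps[kk]
  rise <- p < ps
  xx <- numeric(sum(inb))
  xx[rise] <- beats$dbp[kk][rise] +
    (beats$sbp[kk][rise] - beats$dbp[kk][rise]) *
    (1 - cos(pi * p[rise] / ps[rise])) / 2
  dec <- !rise
  xx[dec] <- beats$dbp_next[kk][dec] +
    (beats$sbp[kk][dec] - beats$dbp_next[kk][dec]) *
    exp(-3 * (p[dec] - ps[dec]) / (1 - ps[dec]))
  x[inb] <- xx
  x + noise[seq_len(n)] * noise_sd
}

.render_ecg <- function(seg, pat, cfg, inn, par, fs) {
  idx <- .seg_idx(seg$t0, seg$t1, fs)
  n <- length(idx)
  base_rr <- 60 / pat$hr
  nb <- length(inn$rr_slow)
  core <- base_rr + .ar1(inn$rr_slow, cfg$noise$rr_phi,
                         cfg$noise$rr_slow_ms / 1000)
  rr <- pmax(core + inn$rr_hf * par$base$rr_hf_ms / 1000, 0.35)
  rt <- cumsum(c(0.3, rr[-nb]))
  dr <- .in_drift(rt, seg)
  if (any(dr)) {
    # widen the white R-R jitter for spikes inside the drift window; the
    # induced time shifts stay inside the window because it extends to the
    # segment end
    rr[dr] <- pmax(core[dr] + inn$rr_hf[dr] * par$drift$rr_hf_ms / 1000,
                   0.35)
    rt <- cumsum(c(0.3, rr[-nb]))
  }
  rt <- rt[rt < (seg$t1 - seg$t0) - 1 / fs]
  x <- numeric(n)
  ri <- round(rt * fs) + 1L
  ri <- ri[ri >= 2 & ri <= n - 1]
  x[ri] <- 1.0
  x[ri - 1L] <- x[ri - 1L] + 0.25
  x[ri + 1L] <- x[ri + 1L] + 0.25
  x
}

.resp_cycles <- function(seg, pat, cfg, inn, par) {
  baseT0 <- 60 / max(4, pat$resp_rate)
  baseT1 <- 60 / max(4, pat$resp_rate + par$drift$resp_rate_bpm)
  nc <- length(inn$T)
  Tc <- pmax(baseT0 + inn$T * cfg$noise$resp_T_sd, 1.6)
  on <- cumsum(c(0, Tc[-nc]))
  dr <- .in_drift(on, seg)
  if (any(dr)) {
    Tc[dr] <- pmax(baseT1 + inn$T[dr] * cfg$noise$resp_T_sd, 1.6)
    on <- cumsum(c(0, Tc[-nc]))
    dr <- .in_drift(on, seg)
  }
  # hold the absolute rise interval at its baseline value times
  # (1 + width_rel), whatever the rate shift did to the cycle period
  pf0 <- ifelse(dr,
                cfg$noise$peak_frac * (1 + par$drift$width_rel) *
                  baseT0 / baseT1,
                cfg$noise$peak_frac)
  pf <- pmin(pmax(pf0 + inn$pf * cfg$noise$resp_pf_sd, 0.08), 0.9)
  amp <- pmax(1 + inn$amp * cfg$noise$resp_amp_sd, 0.25)
  keep <- on < (seg$t1 - seg$t0)
  list(on = on[keep], T = Tc[keep], pf = pf[keep], amp = amp[keep])
}

.render_resp <- function(seg, cyc, fs, noise_sd, noise) {
  idx <- .seg_idx(seg$t0, seg$t1, fs)
  n <- length(idx)
  t_rel <- (idx - 1) / fs - seg$t0
  k <- findInterval(t_rel, cyc$on)
  x <- numeric(n)
  inb <- k >= 1
  kk <- k[inb]
  p <- pmin((t_rel[inb] - cyc$on[kk]) / cyc$T[kk], 1)
  pf <- cyc$pf[kk]
  a <- cyc$amp[kk] / 2
  xx <- numeric(sum(inb))
  rise <- p < pf
  xx[rise] <- -a[rise] * cos(pi * p[rise] / pf[rise])
  xx[!rise] <- a[!rise] * cos(pi * (p[!rise] - pf[!rise]) /
                                (1 - pf[!rise]))
  x[inb] <- xx
  x + noise[seq_len(n)] * noise_sd
}

.render_spo2 <- function(seg, pat, cfg, inn) {
  drifted <- pat$spo2 + .ar1(inn$ar, 0.99, 0.08)
  pmin(pmax(drifted + inn$noise * cfg$noise$spo2_noise, 70), 100)
}

# Random invalid gaps for one segment/channel (stored so re-rendering can
# re-apply them identically).
.draw_gaps <- function(seg, fs, rate) {
  idx <- .seg_idx(seg$t0, seg$t1, fs)
  n <- length(idx)
  if (n == 0 || rate <= 0) return(integer(0))
  mean_gap <- max(1, round(fs))           # ~1 s gaps
  n_gaps <- stats::rpois(1, n * rate / mean_gap)
  if (n_gaps == 0) return(integer(0))
  starts <- sort(sample.int(n, n_gaps, replace = TRUE))
  lens <- pmax(1, round(rexp(n_gaps, 1 / mean_gap)))
  bad <- unique(unlist(mapply(function(s, l) s:min(s + l - 1, n),
                              starts, lens, SIMPLIFY = FALSE)))
  bad
}

# Baseline and drifted values of the drift-sensitive parameters; the
# renderers pick per beat/cycle by position relative to the drift boundary.
.drift_params <- function(cfg, effects) {
  base <- list(rr_hf_ms = cfg$noise$rr_hf_ms,
               t2d_white_ms = cfg$noise$t2d_white_ms,
               dbp_jitter = cfg$noise$dbp_jitter, resp_rate_bpm = 0,
               width_rel = 0)
  drift <- list(rr_hf_ms = cfg$noise$rr_hf_ms + effects$rr_hf_ms,
                t2d_white_ms = cfg$noise$t2d_white_ms +
                  effects$t2d_white_ms,
                dbp_jitter = max(0.1, cfg$noise$dbp_jitter +
                                   effects$dbp_jitter_mmhg),
                resp_rate_bpm = effects$resp_rate_bpm,
                width_rel = effects$width_rel)
  list(base = base, drift = drift)
}

# Render one segment into the channel sample arrays (in place via returned
# patch list): list(channel -> list(idx, values)).
.render_segment <- function(seg, pat, cfg, inn, lvl_fun, par) {
  patches <- list()
  fs <- cfg$rates
  beats <- .abp_beats(seg, pat, cfg, inn$abp, lvl_fun, par)
  patches$ABP <- list(idx = .seg_idx(seg$t0, seg$t1, fs$ABP),
                      values = .render_abp(seg, beats, fs$ABP,
                                           cfg$noise$abp_noise, inn$noise$ABP))
  patches$ECG <- list(idx = .seg_idx(seg$t0, seg$t1, fs$ECG),
                      values = .render_ecg(seg, pat, cfg, inn$ecg, par,
                                           fs$ECG) +
                        inn$noise$ECG[seq_along(.seg_idx(seg$t0, seg$t1,
                                                         fs$ECG))] *
                        cfg$noise$ecg_noise)
  cyc <- .resp_cycles(seg, pat, cfg, inn$resp, par)
  patches$RESP <- list(idx = .seg_idx(seg$t0, seg$t1, fs$RESP),
                       values = .render_resp(seg, cyc, fs$RESP,
                                             cfg$noise$resp_noise,
                                             inn$noise$RESP))
  patches$SPO2 <- list(idx = .seg_idx(seg$t0, seg$t1, fs$SPO2),
                       values = .render_spo2(seg, pat, cfg, inn$spo2))
  patches
}

#' Simulate one patient
#'
#' @param config A [sim_config()].
#' @param patient_index 1-based patient index; together with the config
#'   seed it fully determines the patient.
#' @return List with `record` (a [waveform_record()], carrying its latent
#'   generative state as an attribute) and `truth` (shock flag, true onset,
#'   control-scenario feasibility and the injected effect vector).
#' @export
simulate_patient <- function(config, patient_index) {
  # derive the per-patient seed in double precision (exact below 2^53)
  # so large config seeds cannot overflow integer arithmetic
  set.seed(as.integer((as.numeric(config$seed) * 1009 +
                         patient_index * 7919) %% 2147483647))
  pat <- .draw_patient(config)
  shock <- runif(1) < config$shock_fraction
  onset <- config$pre_onset_hours * 3600
  total <- (config$pre_onset_hours + config$post_onset_hours) * 3600
  segs <- .segment_table(onset, config)
  lvl_fun <- .make_level_fun(shock, onset, pat, config)

  # per-segment innovations, rendering noise and gap masks (drawn once)
  latents <- lapply(segs, function(seg) {
    inn <- .draw_innovations(seg, pat, config)
    inn$noise <- lapply(config$rates[c("ABP", "ECG", "RESP")], function(f)
      rnorm(length(.seg_idx(seg$t0, seg$t1, f))))
    names(inn$noise) <- c("ABP", "ECG", "RESP")
    gaps <- lapply(config$rates, function(f)
      .draw_gaps(seg, f, config$missing_rate))
    list(seg = seg, inn = inn, gaps = gaps)
  })

  # labs and covariates
  if (shock) {
    lag <- runif(1, 1, 6) * 3600
    labs <- data.frame(
      time_s = c(onset - 20 * 3600, onset - 8 * 3600, onset + lag),
      lactate = c(round(runif(2, 0.7, 1.6), 1), round(runif(1, 2.5, 5), 1)))
  } else {
    labs <- data.frame(time_s = c(onset - 20 * 3600, onset - 8 * 3600,
                                  onset + 3600),
                       lactate = round(pmin(runif(3, 0.7, 1.7), 1.8), 1))
  }
  labs <- labs[labs$time_s >= 0, , drop = FALSE]  # labs may post-date the
  # waveform span (lactate panels continue after monitoring stops)

  channels <- sapply(names(config$rates), function(nm) {
    fs <- config$rates[[nm]]
    list(fs = fs, samples = rep(NA_real_, ceiling(total * fs)))
  }, simplify = FALSE)

  # drift-affected parameters apply only inside the drift window of shock
  # patients; the per-beat gating in the renderers enforces that
  par <- .drift_params(config,
                       if (shock) config$drift else zero_drift())
  for (lt in latents) {
    patches <- .render_segment(lt$seg, pat, config, lt$inn, lvl_fun, par)
    for (nm in names(patches)) {
      p <- patches[[nm]]
      v <- p$values
      if (length(lt$gaps[[nm]])) v[lt$gaps[[nm]]] <- NA_real_
      channels[[nm]]$samples[p$idx] <- v
    }
  }

  record <- waveform_record(
    sprintf("P%04d", patient_index), channels, record_start = 0, labs = labs,
    covariates = pat[c("age", "sex", "bmi", "neck", "waist")])
  attr(record, "latent") <- list(pat = pat, cfg = config, latents = latents,
                                 lvl_shock = shock, onset = onset)

  s1 <- config$pre_onset_hours >= 24.5
  s2 <- config$post_onset_hours >= 24 * 7 + 0.6
  truth <- list(patient_id = record$patient_id, shock = shock,
                onset = if (shock) onset else NA_real_,
                scenario1_feasible = s1, scenario2_feasible = s2,
                effects = if (shock) config$drift else zero_drift(),
                baselines = pat)
  list(record = record, truth = truth)
}

#' Inject pre-shock drift into a simulated record
#'
#' Re-renders the `[onset - 90 min, onset)` segment of a generator-produced
#' record with the generative parameters shifted per `effects`, reusing the
#' stored innovation stream so that all samples outside the window are
#' bit-identical and an all-zero effect vector reproduces the record
#' exactly.
#'
#' @param record A record produced by [simulate_patient()] (it must carry
#'   its latent generative state).
#' @param onset True event onset (seconds from record start).
#' @param effects A [drift_spec()].
#' @return The modified record.
#' @export
inject_preshock_drift <- function(record, onset, effects) {
  lat <- attr(record, "latent")
  if (is.null(lat)) stop("record carries no generative state")
  hit <- Filter(function(l) !is.null(l$seg$drift_from) &&
                  isTRUE(all.equal(l$seg$drift_from, onset - 5400)) &&
                  isTRUE(all.equal(l$seg$t1, onset)), lat$latents)
  if (!length(hit)) stop("drift window outside the record's segments")
  lt <- hit[[1]]
  lvl_fun <- .make_level_fun(lat$lvl_shock, lat$onset, lat$pat, lat$cfg)
  par <- .drift_params(lat$cfg, effects)
  patches <- .render_segment(lt$seg, lat$pat, lat$cfg, lt$inn, lvl_fun, par)
  for (nm in names(patches)) {
    p <- patches[[nm]]
    v <- p$values
    if (length(lt$gaps[[nm]])) v[lt$gaps[[nm]]] <- NA_real_
    record$channels[[nm]]$samples[p$idx] <- v
    record$channels[[nm]]$valid[p$idx] <- !is.na(v)
  }
  record
}

#' Simulate a cohort
#'
#' @param config A [sim_config()].
#' @return List of `list(record, truth)`, one per patient. Reproducible:
#'   the same config (including seed) yields an identical cohort.
#' @export
simulate_cohort <- function(config) {
  lapply(seq_len(config$n_patients),
         function(i) simulate_patient(config, i))
}
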