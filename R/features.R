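# Feature engine: computes the fixed 299-feature catalog per 10-minute
# sub-window. Every extractor always returns its full key set; degenerate
# sub-windows carry NA missing-markers, never dropped keys.

#' Ten-statistic summary battery
#'
#' Fixed-order battery applied to every beat/cycle parameter series:
#' minimum, mean, maximum, median, standard deviation, skewness, kurtosis
#' (moment definitions, excess), Hurst exponent, largest Lyapunov exponent
#' and sample entropy. Zero-variance series fall back to 0 for the shape
#' and entropy statistics; an empty series yields ten missing-markers.
#'
#' @param x Numeric series.
#' @param params A [metric_params()].
#' @return Named numeric vector of length 10.
#' @export
stat_battery <- function(x, params = metric_params()) {
  out <- setNames(rep(NA_real_, length(.stat_names)), .stat_names)
  x <- x[is.finite(x)]
  if (!length(x)) return(out)
  out["Min"] <- min(x); out["Mean"] <- mean(x); out["Max"] <- max(x)
  out["Median"] <- median(x)
  s <- if (length(x) > 1) sd(x) else 0
  out["STD"] <- s
  if (s == 0) {
    out[c("Skewness", "Kurtosis", "SampEn")] <- 0
    out["Hurst"] <- 0.5; out["Lyapunov"] <- 0
  } else {
    out["Skewness"] <- e1071::skewness(x, type = 1)
    out["Kurtosis"] <- e1071::kurtosis(x, type = 1)
    out["Hurst"] <- hurst_exponent(x, params)
    out["Lyapunov"] <- largest_lyapunov(x, params)
    out["SampEn"] <- sample_entropy(x, params)
  }
  out
}

# ---- ABP -----------------------------------------------------------------

#' Beat-level arterial-pressure parameter series
#'
#' Detects beat onsets on a quality-masked ABP slice and derives the nine
#' per-beat series: systolic pressure, diastolic pressure, pulse pressure,
#' waveform-average pressure between adjacent onsets (MeanAP), formulaic
#' MAP (DBP + PP/3), heart rate, the systolic-peak to next-diastolic-point
#' interval, and the absolute differences between consecutive systolic and
#' consecutive diastolic values.
#'
#' @param slice Channel slice (see [channel_slice()]) of quality-masked ABP.
#' @return Named list of nine numeric series (empty when no beats).
#' @export
abp_beat_parameters <- function(slice) {
  x <- fill_short_gaps(slice$samples, slice$fs)
  fs <- slice$fs
  empty <- list(t = numeric(0),
                series = setNames(rep(list(numeric(0)),
                                      length(.abp_params)), .abp_params))
  if (all(is.na(x))) return(empty)
  slope_thr <- 0.25 * quantile(diff(x) * fs, 0.98, na.rm = TRUE,
                               names = FALSE)
  if (!is.finite(slope_thr) || slope_thr <= 0) return(empty)
  on <- cpp_pulse_onsets(x, fs, slope_thr, 0.3) + 1L
  if (length(on) < 4) return(empty)
  a <- on[-length(on)]; b <- on[-1]
  bs <- cpp_beat_stats(x, on - 1L)
  dur <- (b - a) / fs
  # physiological validity: discard pseudo-beats spanning masked gaps or
  # detector misses (duration outside 0.3-2 s, i.e. 30-200 bpm)
  keep <- dur >= 0.3 & dur <= 2 & !is.na(bs$max) & !is.na(x[a])
  if (sum(keep) < 3) return(empty)
  a <- a[keep]; b <- b[keep]; dur <- dur[keep]
  sys_v <- bs$max[keep]
  sys_idx <- bs$argmax[keep] + 1L
  meanap <- bs$mean[keep]
  dbp <- x[a]          # diastolic point = beat onset value
  pp <- sys_v - dbp
  list(t = slice$t0 + (a - 1) / fs,
       series = list(Psys = sys_v, Pdias = dbp, PP = pp, MeanAP = meanap,
                     MAP = dbp + pp / 3, HR = 60 / dur,
                     TimeSBP2DBP = (b - sys_idx) / fs,
                     AmplitudeSBP = abs(diff(sys_v)),
                     AmplitudeDBP = abs(diff(dbp))))
}

#' Extract the 90 arterial-pressure features for one sub-window
#'
#' @param record A [waveform_record()].
#' @param interval Half-open sub-window `[start, end)` in seconds.
#' @param params A [metric_params()].
#' @return Named vector over the 90 ABP catalog keys.
#' @export
extract_abp_features <- function(record, interval,
                                 params = metric_params()) {
  cat90 <- shock_catalog()$abp
  out <- setNames(rep(NA_real_, length(cat90)), cat90)
  sl <- tryCatch(channel_slice(record, "ABP", interval),
                 error = function(e) NULL)
  if (is.null(sl)) return(out)
  ok <- abp_quality_mask(sl$samples, sl$fs)
  sl$samples[!ok] <- NA_real_
  pars <- abp_beat_parameters(sl)
  for (p in .abp_params) {
    v <- stat_battery(pars$series[[p]], params)
    out[paste0("ABP_", p, "_", .stat_names)] <- v
  }
  out
}

# ---- ECG / HRV -----------------------------------------------------------

.hrv_bands <- list(ULF = c(1e-4, 0.0033), VLF = c(0.0033, 0.04),
                   LF = c(0.04, 0.15), HF = c(0.15, 0.4),
                   VHF = c(0.4, 0.5))

#' Heart-rate-variability indices from a cleaned R-R series
#'
#' The 89-member versioned HRV set: time-domain deviation and difference
#' statistics, Welch band powers (frequency bands: ULF < 0.0033, VLF
#' 0.0033-0.04, LF 0.04-0.15, HF 0.15-0.4, VHF 0.4-0.5 Hz, on the 4 Hz
#' interpolated tachogram), short-time Fourier and Haar-wavelet band
#' summaries, Poincare geometry, fragmentation indices and nonlinear
#' complexity measures.
#'
#' @param rr R-R intervals in ms (cleaned).
#' @param rr_t Time of each interval's closing beat (s); defaults to the
#'   cumulative sum.
#' @param params A [metric_params()].
#' @return Named vector over the 89 `ECG_HRV_*` catalog keys (prefix
#'   stripped internally).
#' @export
hrv_features <- function(rr, rr_t = NULL, params = metric_params()) {
  out <- setNames(rep(NA_real_, length(.hrv_names)), .hrv_names)
  rr <- rr[is.finite(rr)]
  n <- length(rr)
  if (n < 4) return(out)
  if (is.null(rr_t)) rr_t <- cumsum(rr) / 1000
  d <- diff(rr)
  out["MeanNN"] <- mean(rr); out["MinNN"] <- min(rr)
  out["MaxNN"] <- max(rr); out["RangeNN"] <- max(rr) - min(rr)
  out["MedianNN"] <- median(rr); out["SDNN"] <- sd(rr)
  out["RMSSD"] <- sqrt(mean(d^2)); out["SDSD"] <- sd(d)
  out["CVNN"] <- sd(rr) / mean(rr); out["CVSD"] <- out["RMSSD"] / mean(rr)
  out["MadNN"] <- mad(rr); out["MCVNN"] <- mad(rr) / median(rr)
  out["IQRNN"] <- IQR(rr)
  # 1e-6 ms slack: detector output is quantized to the sampling grid, so
  # differences can sit exactly on a pNN threshold; without slack the
  # strict comparison is decided by float rounding of the timestamps
  out["pNN10"] <- mean(abs(d) > 10 + 1e-6)
  out["pNN20"] <- mean(abs(d) > 20 + 1e-6)
  out["pNN50"] <- mean(abs(d) > 50 + 1e-6)
  seg <- floor((rr_t - rr_t[1]) / 300)        # 5-min segments
  segmeans <- tapply(rr, seg, mean); segsds <- tapply(rr, seg, sd)
  out["SDANN"] <- if (length(segmeans) > 1) sd(segmeans) else NA_real_
  out["SDNNI"] <- mean(segsds, na.rm = TRUE)
  h <- tabulate(floor((rr - min(rr)) / 7.8125) + 1)
  out["HTI"] <- n / max(h)
  out["TINN"] <- .tinn(rr)
  out["MeanHR"] <- 60000 / mean(rr)

  # frequency domain on the 4 Hz interpolated tachogram
  fs_i <- 4
  if (diff(range(rr_t)) > 30) {
    tg <- seq(min(rr_t), max(rr_t), by = 1 / fs_i)
    xi <- approx(rr_t, rr, xout = tg)$y
    psd <- welch_psd(xi, fs_i, nseg = min(512, length(xi)))
    bp <- vapply(.hrv_bands, function(b) band_power(psd, b), 0)
    tot <- sum(bp)
    out["ULF"] <- bp["ULF"]; out["VLF"] <- bp["VLF"]; out["LF"] <- bp["LF"]
    out["HF"] <- bp["HF"]; out["VHF"] <- bp["VHF"]; out["TotalPower"] <- tot
    out["LnVLF"] <- log(bp["VLF"] + 1e-12); out["LnLF"] <- log(bp["LF"] + 1e-12)
    out["LnHF"] <- log(bp["HF"] + 1e-12)
    out["LFHF"] <- if (bp["HF"] > 0) bp["LF"] / bp["HF"] else NA_real_
    lh <- bp["LF"] + bp["HF"]
    out["LFn"] <- if (lh > 0) bp["LF"] / lh else NA_real_
    out["HFn"] <- if (lh > 0) bp["HF"] / lh else NA_real_
    out["PeakLF"] <- peak_frequency(psd, .hrv_bands$LF)
    out["PeakHF"] <- peak_frequency(psd, .hrv_bands$HF)
    out["RelLF"] <- if (tot > 0) bp["LF"] / tot else NA_real_
    out["RelHF"] <- if (tot > 0) bp["HF"] / tot else NA_real_
    out[names(stft_band_summaries(xi, fs_i))] <-
      stft_band_summaries(xi, fs_i)
    wb <- haar_band_summaries(xi, fs_i,
                              list(WT_VLF = c(1e-4, 0.04),
                                   WT_LF = c(0.04, 0.15),
                                   WT_HF = c(0.15, 0.5)))
    out[c("WT_VLF", "WT_LF", "WT_HF")] <- wb$power
    out["WT_LFHF"] <- if (wb$power["WT_HF"] > 0)
      wb$power["WT_LF"] / wb$power["WT_HF"] else NA_real_
    if (is.finite(wb$total) && wb$total > 0) {
      out[c("WT_RelVLF", "WT_RelLF", "WT_RelHF")] <- wb$power / wb$total
    }
    out["WT_Entropy"] <- wb$entropy
  }

  pc <- poincare_descriptors(rr)
  out["SD1"] <- pc["SD1"]; out["SD2"] <- pc["SD2"]
  out["SD1SD2"] <- if (pc["SD2"] > 0) pc["SD1"] / pc["SD2"] else NA_real_
  out["EllipseArea"] <- pi * pc["SD1"] * pc["SD2"]
  out["CSI"] <- if (pc["SD1"] > 0) pc["SD2"] / pc["SD1"] else NA_real_
  out["CVI"] <- if (pc["SD1"] > 0 && pc["SD2"] > 0)
    log10(16 * pc["SD1"] * pc["SD2"]) else NA_real_
  out[c("PIP", "IALS", "PSS", "PAS")] <- .fragmentation(rr)

  out["ApEn"] <- approximate_entropy(rr, params)
  out["SampEn"] <- sample_entropy(rr, params)
  mse <- multiscale_entropy(rr, params)
  out[paste0("MSE_Scale", 1:10)] <- mse
  out["MSE_Mean"] <- mean(mse, na.rm = TRUE)
  sc <- seq_along(mse)[is.finite(mse)]
  out["MSE_Slope"] <- if (length(sc) >= 3)
    unname(coef(lm.fit(cbind(1, sc), mse[sc]))[2]) else NA_real_
  out["DFA_Alpha1"] <- dfa_alpha(rr, params,
                                 scales = 4:min(16, floor(n / 4)))
  out["DFA_Alpha2"] <- if (n >= 64)
    dfa_alpha(rr, params, scales = unique(round(seq(16, floor(n / 4),
                                                    length.out = 8))))
    else NA_real_
  out["MFDFA_Alpha1_Peak"] <- mfdfa_alpha1_peak(rr, params)
  out["CD"] <- correlation_dimension(rr, params)
  out["Hurst"] <- hurst_exponent(rr, params)
  out["Lyapunov"] <- largest_lyapunov(rr, params)
  out["LZC"] <- lempel_ziv_complexity(rr)
  out["CTM"] <- central_tendency_measure(rr, params = params)
  out["ShanEn"] <- shannon_entropy(rr)
  out["FuzzyEn"] <- fuzzy_entropy(rr, params)
  out["PermEn"] <- permutation_entropy(rr)
  out["KFD"] <- katz_fd(rr)
  out
}

# Triangular interpolation of the NN histogram (TINN, ms): least-squares
# triangle through the modal bin.
.tinn <- function(rr, bin = 7.8125) {
  edges <- seq(floor(min(rr) / bin) * bin, max(rr) + bin, by = bin)
  if (length(edges) < 4) return(0)
  h <- tabulate(findInterval(rr, edges), nbins = length(edges) - 1)
  mids <- edges[-1] - bin / 2
  pk <- which.max(h)
  best <- Inf; nm <- c(mids[1], mids[length(mids)])
  for (i in seq_len(pk)) {
    for (j in pk:length(mids)) {
      if (j <= i) next
      tri <- numeric(length(mids))
      up <- i:pk; dn <- pk:j
      if (pk > i) tri[up] <- h[pk] * (mids[up] - mids[i]) / (mids[pk] - mids[i])
      if (j > pk) tri[dn] <- h[pk] * (mids[j] - mids[dn]) / (mids[j] - mids[pk])
      tri[pk] <- h[pk]
      sse <- sum((h - tri)^2)
      if (sse < best) { best <- sse; nm <- c(mids[i], mids[j]) }
    }
  }
  nm[2] - nm[1]
}

# Heart-rate fragmentation indices (inflection-point based).
.fragmentation <- function(rr) {
  d <- diff(rr)
  if (length(d) < 3) return(rep(NA_real_, 4))
  s <- sign(d); s[s == 0] <- 1
  infl <- diff(s) != 0
  pip <- mean(infl)
  runs <- rle(s)
  ials <- 1 / mean(runs$lengths)
  pss <- sum(runs$lengths[runs$lengths < 3]) / length(d)
  alt <- rle(as.integer(infl))
  pas <- sum(alt$lengths[alt$values == 1 & alt$lengths >= 3] + 1) /
    length(d)
  c(PIP = pip, IALS = ials, PSS = pss, PAS = min(pas, 1))
}

#' Extract the 89 ECG (HRV) features for one sub-window
#'
#' Band-passes the ECG slice (3-45 Hz, zero-phase), detects R peaks,
#' cleans the R-R series to the (400, 1500) ms validity band and computes
#' [hrv_features()].
#'
#' @inheritParams extract_abp_features
#' @export
extract_ecg_features <- function(record, interval,
                                 params = metric_params()) {
  cat89 <- shock_catalog()$ecg
  out <- setNames(rep(NA_real_, length(cat89)), cat89)
  sl <- tryCatch(channel_slice(record, "ECG", interval),
                 error = function(e) NULL)
  if (is.null(sl)) return(out)
  filt <- tryCatch(bandpass_ecg(sl$samples, sl$fs), error = function(e) NULL)
  if (is.null(filt)) return(out)
  pk <- tryCatch(detect_r_peaks(filt, sl$fs), error = function(e) NULL)
  if (is.null(pk) || length(pk) < 6) return(out)
  rr <- diff(pk) * 1000
  rr <- tryCatch(clean_rr_intervals(rr), error = function(e) NULL)
  if (is.null(rr)) return(out)
  v <- hrv_features(rr, rr_t = pk[-1], params = params)
  out[paste0("ECG_HRV_", names(v))] <- v
  out
}

# ---- RESP ----------------------------------------------------------------

.rrv_bands <- list(LF = c(0.01, 0.05), HF = c(0.05, 0.3))

#' Respiratory-rate-variability indices
#'
#' The 22-member versioned RRV set on the breath-to-breath (trough to
#' trough) interval series: time-domain statistics, LF/HF band powers
#' (LF 0.01-0.05, HF 0.05-0.3 Hz of the interval modulation) via Burg,
#' Welch and Lomb-Scargle spectra, sample entropy and Poincare widths, a
#' Haar-wavelet LF/HF ratio and the multifractal singularity-spectrum
#' peak.
#'
#' @param bb Breath-to-breath intervals (s).
#' @param bb_t Time of each interval's closing trough (s).
#' @param params A [metric_params()].
#' @return Named vector over the 22 RRV keys.
#' @export
rrv_features <- function(bb, bb_t = NULL, params = metric_params()) {
  out <- setNames(rep(NA_real_, length(.rrv_names)), .rrv_names)
  bb <- bb[is.finite(bb)]
  n <- length(bb)
  if (n < 4) return(out)
  if (is.null(bb_t)) bb_t <- cumsum(bb)
  d <- diff(bb)
  out["MeanBB"] <- mean(bb); out["SDBB"] <- sd(bb)
  out["RMSSD"] <- sqrt(mean(d^2)); out["SDSD"] <- sd(d)
  out["CVBB"] <- sd(bb) / mean(bb)
  out["MCVBB"] <- mad(bb) / median(bb)
  out["MedianBB"] <- median(bb); out["MadBB"] <- mad(bb)
  if (diff(range(bb_t)) > 60) {
    fs_i <- 1
    tg <- seq(min(bb_t), max(bb_t), by = 1 / fs_i)
    xi <- approx(bb_t, bb, xout = tg)$y
    for (est in c("Burg", "Welch")) {
      psd <- if (est == "Burg") burg_psd(xi, fs_i, order = 10)
             else welch_psd(xi, fs_i, nseg = min(128, length(xi)))
      lf <- band_power(psd, .rrv_bands$LF)
      hf <- band_power(psd, .rrv_bands$HF)
      out[paste0(est, "_LF")] <- lf; out[paste0(est, "_HF")] <- hf
      out[paste0(est, "_LFHF")] <- if (hf > 0) lf / hf else NA_real_
    }
    lp <- lomb_psd(bb_t, bb, seq(0.005, 0.35, by = 0.005))
    lf <- band_power(lp, .rrv_bands$LF); hf <- band_power(lp, .rrv_bands$HF)
    out["Lomb_LF"] <- lf; out["Lomb_HF"] <- hf
    out["Lomb_LFHF"] <- if (hf > 0) lf / hf else NA_real_
    wb <- haar_band_summaries(xi, fs_i, .rrv_bands)
    out["WT_LFHF"] <- if (wb$power["HF"] > 0)
      wb$power["LF"] / wb$power["HF"] else NA_real_
  }
  out["SampEn"] <- sample_entropy(bb, params)
  pc <- poincare_descriptors(bb)
  out["SD1"] <- pc["SD1"]; out["SD2"] <- pc["SD2"]
  out["MFDFA_Alpha1_Peak"] <- mfdfa_alpha1_peak(bb, params)
  out
}

#' Extract the 112 respiratory features for one sub-window
#'
#' Nine per-cycle parameter series (cycle amplitude, width = rise
#' interval, peak-to-peak and trough-to-trough intervals, peak amplitude,
#' cycle rate, respiratory volume per time, peak-trough amplitude symmetry
#' and rise-decay symmetry) crossed with the ten-statistic battery, plus
#' the 22 RRV indices.
#'
#' @inheritParams extract_abp_features
#' @export
extract_resp_features <- function(record, interval,
                                  params = metric_params()) {
  keys <- shock_catalog()$resp
  out <- setNames(rep(NA_real_, length(keys)), keys)
  sl <- tryCatch(channel_slice(record, "RESP", interval),
                 error = function(e) NULL)
  if (is.null(sl)) return(out)
  x <- fill_short_gaps(sl$samples, sl$fs)
  cyc <- tryCatch(detect_breath_cycles(x, sl$fs), error = function(e) NULL)
  if (!is.null(cyc) && nrow(cyc) >= 3) {
    period <- cyc$next_trough_t - cyc$trough_t
    tt <- diff(cyc$trough_t)
    pars <- list(
      Cycle_Amplitude = cyc$amplitude,
      Width = cyc$width,
      PeakInterval = diff(cyc$peak_t),
      TroughInterval = tt,
      Amplitude = cyc$peak_v,
      Cycle_Rate = 60 / period,
      RVT = cyc$amplitude / period,
      Cycle_Symmetry_PeakTrough = abs(cyc$peak_v) /
        (abs(cyc$peak_v) + abs((cyc$trough_v + cyc$next_trough_v) / 2)),
      Cycle_Symmetry_RiseDecay = cyc$rise / period)
    for (p in .resp_params)
      out[paste0("RESP_", p, "_", .stat_names)] <-
        stat_battery(pars[[p]], params)
    rv <- rrv_features(tt, bb_t = cyc$trough_t[-1], params = params)
    out[paste0("RESP_RRV_", names(rv))] <- rv
  }
  out
}

# ---- SpO2 ----------------------------------------------------------------

#' Extract the 8 oxygen-saturation features for one sub-window
#'
#' Five linear statistics (min, mean, max, median, SD) and three nonlinear
#' measures (sample entropy, Lempel-Ziv complexity, central tendency
#' measure) of the SpO2 trace.
#'
#' @inheritParams extract_abp_features
#' @export
extract_spo2_features <- function(record, interval,
                                  params = metric_params()) {
  keys <- shock_catalog()$spo2
  out <- setNames(rep(NA_real_, length(keys)), keys)
  sl <- tryCatch(channel_slice(record, "SPO2", interval),
                 error = function(e) NULL)
  if (is.null(sl)) return(out)
  x <- sl$samples[is.finite(sl$samples)]
  if (length(x) < 4) return(out)
  out["SPO2_Smin"] <- min(x); out["SPO2_Smean"] <- mean(x)
  out["SPO2_Smax"] <- max(x); out["SPO2_Smedian"] <- median(x)
  out["SPO2_Ssd"] <- if (length(x) > 1) sd(x) else 0
  out["SPO2_SampEn"] <- sample_entropy(x, params)
  out["SPO2_LZC"] <- lempel_ziv_complexity(x)
  out["SPO2_CTM"] <- central_tendency_measure(x, params = params)
  out
}

# ---- window / cohort -----------------------------------------------------

# One-shot preprocessing shared by the five sub-windows of an analysis
# window: quality-masked ABP beat parameters, band-passed ECG R-R series
# and detected breath cycles over the whole 30 minutes; sub-windows then
# subset fiducials by time instead of re-running the detectors.
.preprocess_window <- function(record, iv) {
  prep <- list()
  prep$abp <- tryCatch({
    sl <- channel_slice(record, "ABP", iv)
    ok <- abp_quality_mask(sl$samples, sl$fs)
    sl$samples[!ok] <- NA_real_
    abp_beat_parameters(sl)
  }, error = function(e) NULL)
  # interval series are derived from slice-relative fiducial times;
  # absolute times serve only for sub-window membership (adding a large
  # offset before differencing would perturb the last floating-point bits
  # in a position-dependent way)
  prep$ecg <- tryCatch({
    sl <- channel_slice(record, "ECG", iv)
    filt <- bandpass_ecg(sl$samples, sl$fs)
    pk <- detect_r_peaks(filt, sl$fs)
    rr <- clean_rr_intervals(diff(pk) * 1000)
    list(rr = rr, t_rel = pk[-1], t = pk[-1] + sl$t0)
  }, error = function(e) NULL)
  prep$resp <- tryCatch({
    sl <- channel_slice(record, "RESP", iv)
    cyc <- detect_breath_cycles(fill_short_gaps(sl$samples, sl$fs), sl$fs)
    cyc$t0 <- sl$t0
    cyc
  }, error = function(e) NULL)
  prep$spo2 <- tryCatch({
    sl <- channel_slice(record, "SPO2", iv)
    list(t = sl$t0 + (seq_along(sl$samples) - 1) / sl$fs,
         v = sl$samples)
  }, error = function(e) NULL)
  prep
}

.abp_feats_sub <- function(prep, iv, params) {
  keys <- shock_catalog()$abp
  out <- setNames(rep(NA_real_, length(keys)), keys)
  ab <- prep$abp
  if (!is.null(ab) && length(ab$t)) {
    sel <- ab$t >= iv[1] & ab$t < iv[2]
    for (p in .abp_params) {
      v <- ab$series[[p]]
      ss <- if (length(v) == length(sel)) sel else sel[-length(sel)]
      out[paste0("ABP_", p, "_", .stat_names)] <-
        stat_battery(v[ss], params)
    }
  }
  out
}

.ecg_feats_sub <- function(prep, iv, params) {
  keys <- shock_catalog()$ecg
  out <- setNames(rep(NA_real_, length(keys)), keys)
  ec <- prep$ecg
  if (!is.null(ec)) {
    sel <- ec$t >= iv[1] & ec$t < iv[2]
    if (sum(sel) >= 6) {
      v <- hrv_features(ec$rr[sel], rr_t = ec$t_rel[sel], params = params)
      out[paste0("ECG_HRV_", names(v))] <- v
    }
  }
  out
}

.resp_feats_sub <- function(prep, iv, params) {
  keys <- shock_catalog()$resp
  out <- setNames(rep(NA_real_, length(keys)), keys)
  cyc <- prep$resp
  if (!is.null(cyc)) {
    t_abs <- cyc$trough_t + cyc$t0
    cyc <- cyc[t_abs >= iv[1] & t_abs < iv[2], ]
    if (nrow(cyc) >= 3) {
      period <- cyc$next_trough_t - cyc$trough_t
      tt <- diff(cyc$trough_t)
      pars <- list(
        Cycle_Amplitude = cyc$amplitude,
        Width = cyc$width,
        PeakInterval = diff(cyc$peak_t),
        TroughInterval = tt,
        Amplitude = cyc$peak_v,
        Cycle_Rate = 60 / period,
        RVT = cyc$amplitude / period,
        Cycle_Symmetry_PeakTrough = abs(cyc$peak_v) /
          (abs(cyc$peak_v) + abs((cyc$trough_v + cyc$next_trough_v) / 2)),
        Cycle_Symmetry_RiseDecay = cyc$rise / period)
      for (p in .resp_params)
        out[paste0("RESP_", p, "_", .stat_names)] <-
          stat_battery(pars[[p]], params)
      rv <- rrv_features(tt, bb_t = cyc$trough_t[-1], params = params)
      out[paste0("RESP_RRV_", names(rv))] <- rv
    }
  }
  out
}

.spo2_feats_sub <- function(prep, iv, params) {
  keys <- shock_catalog()$spo2
  out <- setNames(rep(NA_real_, length(keys)), keys)
  sp <- prep$spo2
  if (!is.null(sp)) {
    x <- sp$v[sp$t >= iv[1] & sp$t < iv[2]]
    x <- x[is.finite(x)]
    if (length(x) >= 4) {
      out["SPO2_Smin"] <- min(x); out["SPO2_Smean"] <- mean(x)
      out["SPO2_Smax"] <- max(x); out["SPO2_Smedian"] <- median(x)
      out["SPO2_Ssd"] <- if (length(x) > 1) sd(x) else 0
      out["SPO2_SampEn"] <- sample_entropy(x, params)
      out["SPO2_LZC"] <- lempel_ziv_complexity(x)
      out["SPO2_CTM"] <- central_tendency_measure(x, params = params)
    }
  }
  out
}

#' Extract all 299 features for one 30-minute analysis window
#'
#' Tiles the window into five 10-minute sub-windows (5-minute hop) and
#' computes the full catalog per sub-window. Preprocessing (quality
#' masking, band-pass filtering, fiducial detection) runs once over the
#' whole window; sub-windows subset the detected beats/cycles by time.
#'
#' @param record A [waveform_record()].
#' @param window One row of a [build_windows()] data frame.
#' @param params A [metric_params()].
#' @return Data frame: one row per sub-window with identifiers
#'   (`patient_id`, `window_id`, `sub_window`, `role`, `scenario`,
#'   `label`), covariates and the 299 feature columns.
#' @export
extract_window <- function(record, window, params = metric_params()) {
  subs <- rolling_subwindows(window$start, window$end)
  cat <- shock_catalog()
  prep <- .preprocess_window(record, c(window$start, window$end))
  rows <- lapply(seq_len(nrow(subs)), function(i) {
    iv <- subs[i, ]
    vals <- c(.abp_feats_sub(prep, iv, params),
              .ecg_feats_sub(prep, iv, params),
              .resp_feats_sub(prep, iv, params),
              .spo2_feats_sub(prep, iv, params))
    stopifnot(identical(names(vals), cat$all))
    cov <- record$covariates
    cbind(data.frame(patient_id = record$patient_id,
                     window_id = paste0(record$patient_id, "_",
                                        window$role),
                     sub_window = i - 1L, role = window$role,
                     scenario = window$scenario, label = window$label,
                     age = cov$age %||% NA_real_,
                     sex = cov$sex %||% NA_character_,
                     bmi = cov$bmi %||% NA_real_,
                     neck = cov$neck %||% NA_real_,
                     waist = cov$waist %||% NA_real_),
          as.data.frame(as.list(vals)))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract features for a labeled cohort
#'
#' @param included List of per-patient lists with `record` and `windows`
#'   (e.g. from [apply_exclusions()]).
#' @param params A [metric_params()].
#' @param progress Print per-patient progress to stderr.
#' @return Combined feature data frame (one row per patient, window,
#'   sub-window).
#' @export
extract_cohort_features <- function(included, params = metric_params(),
                                    progress = FALSE) {
  rows <- lapply(seq_along(included), function(i) {
    p <- included[[i]]
    if (progress) message("features: patient ", p$record$patient_id)
    do.call(rbind, lapply(seq_len(nrow(p$windows)), function(w)
      extract_window(p$record, p$windows[w, ], params)))
  })
  do.call(rbind, rows)
}
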