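# Signal conditioning: ECG band-pass and R-R cleaning, ABP signal-quality
# masking, breath-cycle detection, chained-equation imputation of the
# feature table, and the rolling sub-window tiling.

#' Zero-phase ECG band-pass filter
#'
#' Forward-backward Butterworth band-pass (default 3-45 Hz, order 4), so no
#' phase distortion biases interval measurements. Output length equals
#' input length; interior NA gaps shorter than `max_gap_s` are linearly
#' bridged before filtering and the remaining invalid spans are restored to
#' NA afterwards.
#'
#' @param x ECG samples (mV).
#' @param fs Sampling rate (Hz); must exceed twice the upper band edge.
#' @param low,high Band edges in Hz.
#' @param order Butterworth order.
#' @param max_gap_s Longest invalid run bridged by interpolation (seconds).
#' @return Filtered samples, same length as `x`.
#' @export
bandpass_ecg <- function(x, fs, low = 3, high = 45, order = 4,
                         max_gap_s = 2) {
  if (fs <= 2 * high)
    stop("sampling rate ", fs, " Hz too low for a ", high, " Hz band edge")
  filled <- fill_short_gaps(x, fs, max_gap_s)
  bad <- is.na(filled)
  if (all(bad)) stop("no valid ECG samples to filter")
  filled[bad] <- 0
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, filled)
  y[bad] <- NA_real_
  y
}

# Linear interpolation across interior NA runs no longer than max_gap_s.
fill_short_gaps <- function(x, fs, max_gap_s = 2) {
  if (!anyNA(x)) return(x)
  r <- rle(is.na(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- which(!is.na(x))
  if (length(ok) < 2) return(x)
  out <- x
  for (i in which(r$values)) {
    if (r$lengths[i] > max_gap_s * fs) next
    if (starts[i] == 1 || ends[i] == length(x)) next
    idx <- starts[i]:ends[i]
    out[idx] <- approx(c(starts[i] - 1, ends[i] + 1),
                       x[c(starts[i] - 1, ends[i] + 1)], xout = idx)$y
  }
  out
}

#' Detect R peaks
#'
#' Amplitude-threshold local-maximum detector with a 200 ms refractory
#' period, intended for band-passed ECG. The threshold adapts to the
#' signal: `threshold_frac` times the 99th percentile of the absolute
#' amplitude.
#'
#' @param x Filtered ECG samples.
#' @param fs Sampling rate (Hz).
#' @param threshold_frac Fraction of the 99th absolute-amplitude percentile.
#' @param refractory Minimum peak separation (s).
#' @return Vector of R-peak times in seconds from the start of `x`.
#' @export
detect_r_peaks <- function(x, fs, threshold_frac = 0.5, refractory = 0.2) {
  amp <- quantile(abs(x), 0.99, na.rm = TRUE, names = FALSE)
  if (!is.finite(amp) || amp == 0) stop("no peaks found: flat signal")
  idx <- cpp_spike_peaks(x, fs, threshold_frac * amp, refractory)
  if (!length(idx)) stop("no peaks found")
  idx / fs  # idx is 0-based so this is the sample time
}

#' Clean an R-R interval series
#'
#' Intervals outside the open interval (400, 1500) ms - heart rates above
#' 150 or below 40 bpm - are replaced by linear interpolation from the
#' nearest valid neighbours; valid intervals are untouched, making the
#' operation idempotent.
#'
#' @param rr R-R intervals in ms (length >= 3).
#' @param lower,upper Validity bounds in ms (exclusive).
#' @return Corrected series, same length.
#' @export
clean_rr_intervals <- function(rr, lower = 400, upper = 1500) {
  stopifnot(length(rr) >= 3)
  valid <- rr > lower & rr < upper & !is.na(rr)
  if (!any(valid)) stop("no valid R-R intervals to anchor interpolation")
  if (all(valid)) return(rr)
  idx <- seq_along(rr)
  out <- rr
  out[!valid] <- approx(idx[valid], rr[valid], xout = idx[!valid],
                        rule = 2)$y
  out
}

#' Arterial-pressure signal-quality mask
#'
#' Marks 0.5-second check windows invalid when any sample lies outside the
#' physiologic pressure range, the window is flat (zero variance), the slew
#' rate exceeds a physiologic limit, or the window contains invalid
#' samples. Granularity is the check window: a single bad sample
#' invalidates exactly its window.
#'
#' @param x ABP samples (mmHg).
#' @param fs Sampling rate (Hz).
#' @param win Check-window length (s).
#' @param p_lo,p_hi Admissible pressure range (mmHg).
#' @param max_slew Maximum |dP/dt| (mmHg/s).
#' @return Logical per-sample mask, `TRUE` where valid.
#' @export
abp_quality_mask <- function(x, fs, win = 0.5, p_lo = 20, p_hi = 300,
                             max_slew = 2500) {
  n <- length(x)
  w <- max(1L, round(win * fs))
  k <- ceiling(n / w)
  # pad the tail so windows tile exactly, then test per-window columns
  pad <- k * w - n
  xm <- matrix(c(x, rep(NA_real_, pad)), nrow = w)
  # a slew event between samples i and i+1 belongs to sample i's window
  slew <- matrix(c(abs(diff(x)) * fs, rep(0, pad + 1)), nrow = w)
  bad_sample <- is.na(xm) | xm < p_lo | xm > p_hi
  bad_sample[is.na(bad_sample)] <- TRUE
  sums <- colSums(xm); sq <- colSums(xm^2)
  cm <- sums / w
  flat <- (sq / w - cm^2) <= 1e-9 * pmax(cm^2, 1)   # zero variance
  flat[is.na(flat)] <- FALSE
  bad_win <- colSums(bad_sample) > 0 | flat |
    colSums(slew > max_slew, na.rm = TRUE) > 0
  if (pad > 0) {
    # ignore synthetic padding when judging the final partial window
    last <- seq.int(n - (w - pad) + 1L, n)
    bad_win[k] <- anyNA(x[last]) || any(x[last] < p_lo | x[last] > p_hi) ||
      (length(last) > 1 && var(x[last]) == 0)
  }
  rep(!bad_win, each = w)[seq_len(n)]
}

#' Detect breath cycles
#'
#' Prominence-gated alternating trough/peak detection with a minimum cycle
#' duration. Each returned cycle runs trough -> peak -> next trough.
#'
#' @param x Respiration samples (arbitrary units).
#' @param fs Sampling rate (Hz).
#' @param min_cycle Minimum cycle duration (s).
#' @param prominence_frac Minimum peak-trough amplitude as a fraction of
#'   the 10-90 percentile signal range.
#' @return Object of class `breath_series`: data frame with columns
#'   `trough_t`, `peak_t`, `next_trough_t`, `trough_v`, `peak_v`,
#'   `next_trough_v`, `amplitude`, `width` (rise, s), `rise`, `decay`
#'   (s).
#' @export
detect_breath_cycles <- function(x, fs, min_cycle = 1.5,
                                 prominence_frac = 0.25) {
  keep <- !is.na(x)
  if (!any(keep)) stop("no breaths found: empty signal")
  rng <- diff(quantile(x, c(0.1, 0.9), na.rm = TRUE, names = FALSE))
  if (rng == 0) stop("no breaths found: flat signal")
  prom <- prominence_frac * rng
  ext <- .alternating_extrema(x, fs, min_half = min_cycle / 2, prom = prom)
  if (is.null(ext) || nrow(ext) < 3) stop("no breaths found")
  # assemble trough-peak-trough triples
  ti <- which(ext$type == "trough")
  ti <- ti[ti + 2 <= nrow(ext)]
  ti <- ti[ext$type[ti + 1] == "peak" & ext$type[ti + 2] == "trough"]
  if (!length(ti)) stop("no breaths found")
  cyc <- data.frame(
    trough_t = ext$t[ti], peak_t = ext$t[ti + 1],
    next_trough_t = ext$t[ti + 2],
    trough_v = ext$v[ti], peak_v = ext$v[ti + 1],
    next_trough_v = ext$v[ti + 2])
  cyc$amplitude <- cyc$peak_v - (cyc$trough_v + cyc$next_trough_v) / 2
  cyc$rise <- cyc$peak_t - cyc$trough_t
  cyc$decay <- cyc$next_trough_t - cyc$peak_t
  cyc$width <- cyc$rise
  class(cyc) <- c("breath_series", "data.frame")
  cyc
}

# Alternating local extrema with prominence and minimum half-cycle spacing.
.alternating_extrema <- function(x, fs, min_half, prom) {
  d <- diff(x)
  d[is.na(d)] <- 0
  sgn <- sign(d)
  sgn[sgn == 0] <- NA
  ok <- which(!is.na(sgn))
  if (length(ok) < 2) return(NULL)
  # carry the last nonzero slope sign through plateaus
  sgn <- approx(ok, sgn[ok], xout = seq_along(sgn), method = "constant",
                rule = 2)$y
  turns <- which(diff(sgn) != 0 & !is.na(diff(sgn))) + 1L
  if (!length(turns)) return(NULL)
  type <- ifelse(sgn[turns - 1] > 0, "peak", "trough")
  t <- (turns - 1) / fs
  v <- x[turns]
  keep <- logical(length(turns))
  last_kept <- 0L
  for (i in seq_along(turns)) {
    if (is.na(v[i])) next
    if (last_kept == 0L) { keep[i] <- TRUE; last_kept <- i; next }
    if (type[i] == type[last_kept]) {
      # same kind twice: keep the more extreme
      better <- if (type[i] == "peak") v[i] > v[last_kept]
                else v[i] < v[last_kept]
      if (better) { keep[last_kept] <- FALSE; keep[i] <- TRUE
                    last_kept <- i }
      next
    }
    if (t[i] - t[last_kept] < min_half) next
    if (abs(v[i] - v[last_kept]) < prom) next
    keep[i] <- TRUE; last_kept <- i
  }
  out <- data.frame(t = t[keep], v = v[keep], type = type[keep])
  out[order(out$t), ]
}

#' Chained-equation imputation of a feature table
#'
#' Iterated conditional regression in the style of multivariate imputation
#' by chained equations: missing cells are initialized at the column mean,
#' then refreshed for a fixed number of sweeps by linear regression on the
#' most-correlated observed columns (deterministic predictive-mean
#' variant, so a fixed seed reproduces the output exactly). Observed cells
#' are never altered.
#'
#' @param df Data frame of numeric feature columns with `NA`
#'   missing-markers.
#' @param max_iter Number of chained sweeps.
#' @param n_pred Maximum number of predictor columns per regression.
#' @param seed RNG seed (retained for interface stability; the default
#'   imputation path draws no random numbers).
#' @return Completed data frame, same shape.
#' @export
impute_chained <- function(df, max_iter = 10, n_pred = 10, seed = 1L) {
  stopifnot(is.data.frame(df))
  X <- as.matrix(df)
  if (!is.numeric(X)) stop("all columns must be numeric")
  miss <- is.na(X)
  if (!any(miss)) return(df)
  nobs <- colSums(!miss)
  if (any(nobs < 2))
    stop("column(s) with fewer than 2 observed values: ",
         paste(colnames(X)[nobs < 2], collapse = ", "))
  set.seed(seed)
  mu <- colMeans(X, na.rm = TRUE)
  for (j in which(colSums(miss) > 0)) X[miss[, j], j] <- mu[j]
  targets <- which(colSums(miss) > 0)
  # predictor choice from the initialized matrix, fixed across sweeps
  sds <- apply(X, 2, sd)
  usable <- which(sds > 0)
  cm <- if (length(usable) > 1) abs(suppressWarnings(cor(X[, usable]))) else NULL
  for (iter in seq_len(max_iter)) {
    for (j in targets) {
      mj <- miss[, j]
      preds <- integer(0)
      if (!is.null(cm) && (j %in% usable)) {
        cj <- cm[, match(j, usable)]
        cj[match(j, usable)] <- NA
        ord <- order(cj, decreasing = TRUE, na.last = NA)
        preds <- usable[ord[seq_len(min(n_pred, length(ord)))]]
      }
      if (!length(preds)) { X[mj, j] <- mu[j]; next }
      A <- cbind(1, X[!mj, preds, drop = FALSE])
      fit <- tryCatch(lm.fit(A, X[!mj, j]), error = function(e) NULL)
      if (is.null(fit)) { X[mj, j] <- mu[j]; next }
      beta <- fit$coefficients
      beta[is.na(beta)] <- 0
      X[mj, j] <- cbind(1, X[mj, preds, drop = FALSE]) %*% beta
    }
  }
  out <- as.data.frame(X)
  names(out) <- names(df)
  out
}

#' Rolling 10-minute sub-windows
#'
#' Tiles a half-open analysis window with fixed-width sub-windows at a
#' fixed hop (default 10-minute width, 5-minute hop, so a 30-minute window
#' yields five sub-windows with 5-minute overlaps between neighbours).
#'
#' @param start,end Window bounds in seconds (half-open).
#' @param width Sub-window width (s).
#' @param step Hop between sub-window starts (s).
#' @return Two-column matrix (`start`, `end`), one row per sub-window.
#' @export
rolling_subwindows <- function(start, end, width = 600, step = 300) {
  len <- end - start
  if (len < width) stop("window shorter than one sub-window")
  offs <- seq(0, len - width, by = step)
  cbind(start = start + offs, end = start + offs + width)
}
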