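# Spectral estimation helpers shared by the HRV / RRV feature sets:
# Welch and Burg power spectral densities, a Lomb-Scargle periodogram for
# the unevenly sampled breath series, short-time Fourier band summaries
# and a Haar filter-bank (dyadic wavelet) band decomposition.

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Welch power spectral density
#'
#' Hann-windowed, 50%-overlapping averaged periodograms, one-sided density
#' scaling (power units^2 per Hz).
#'
#' @param x Regularly sampled series (mean is removed).
#' @param fs Sampling rate (Hz).
#' @param nseg Segment length (clamped to the series length).
#' @return Data frame `f`, `psd`.
#' @keywords internal
welch_psd <- function(x, fs, nseg = 256) {
  x <- x - mean(x)
  n <- length(x)
  nseg <- min(nseg, n)
  hop <- max(1, floor(nseg / 2))
  w <- .hann(nseg)
  scale <- fs * sum(w^2)
  starts <- seq(1, n - nseg + 1, by = hop)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)] * w
    p <- abs(fft(seg))^2 / scale
    acc <- acc + p[seq_along(acc)]
  }
  psd <- acc / length(starts)
  psd[-1] <- 2 * psd[-1]                      # one-sided
  if (nseg %% 2 == 0) psd[length(psd)] <- psd[length(psd)] / 2
  data.frame(f = (seq_along(psd) - 1) * fs / nseg, psd = psd)
}

#' Burg (autoregressive) power spectral density
#' @keywords internal
burg_psd <- function(x, fs, order = NULL, nfreq = 256) {
  x <- x - mean(x)
  if (is.null(order)) order <- max(2, min(16, floor(length(x) / 3)))
  fit <- tryCatch(ar.burg(x, aic = FALSE, order.max = order),
                  error = function(e) NULL)
  f <- seq(0, fs / 2, length.out = nfreq)
  if (is.null(fit) || !length(fit$ar))
    return(data.frame(f = f, psd = rep(0, nfreq)))
  a <- fit$ar
  den <- vapply(f, function(ff) {
    z <- exp(-2i * pi * ff / fs * seq_along(a))
    Mod(1 - sum(a * z))^2
  }, 0)
  data.frame(f = f, psd = fit$var.pred / fs / den * 2)
}

#' Lomb-Scargle periodogram for unevenly sampled series
#' @keywords internal
lomb_psd <- function(t, x, freqs) {
  x <- x - mean(x)
  v <- var(x)
  if (v == 0) return(data.frame(f = freqs, psd = rep(0, length(freqs))))
  p <- vapply(freqs, function(f) {
    w <- 2 * pi * f
    tau <- atan2(sum(sin(2 * w * t)), sum(cos(2 * w * t))) / (2 * w)
    ct <- cos(w * (t - tau)); st <- sin(w * (t - tau))
    0.5 * (sum(x * ct)^2 / sum(ct^2) + sum(x * st)^2 / sum(st^2)) / v
  }, 0)
  data.frame(f = freqs, psd = p)
}

# Trapezoidal band power over a PSD data frame; interpolates the PSD onto
# a fine grid so narrow bands on coarse grids still integrate sensibly.
band_power <- function(psd, band) {
  if (band[2] <= band[1]) return(0)
  grid <- seq(band[1], band[2], length.out = 64)
  y <- approx(psd$f, psd$psd, xout = grid, rule = 2)$y
  sum((y[-1] + y[-length(y)]) / 2 * diff(grid))
}

peak_frequency <- function(psd, band) {
  sel <- psd$f >= band[1] & psd$f <= band[2]
  if (!any(sel)) return(NA_real_)
  psd$f[sel][which.max(psd$psd[sel])]
}

# Short-time band-power summaries: Hann-windowed frames, per-frame LF/HF
# band powers, mean and SD across frames.
stft_band_summaries <- function(x, fs, frame_s = 60, hop_s = 30,
                                lf = c(0.04, 0.15), hf = c(0.15, 0.4)) {
  n <- length(x)
  fl <- round(frame_s * fs); hp <- round(hop_s * fs)
  out <- c(STFT_LF_Mean = NA_real_, STFT_LF_SD = NA_real_,
           STFT_HF_Mean = NA_real_, STFT_HF_SD = NA_real_,
           STFT_LFHF_Mean = NA_real_, STFT_LFHF_SD = NA_real_,
           STFT_Total_Mean = NA_real_, STFT_Total_SD = NA_real_)
  if (n < fl) return(out)
  starts <- seq(1, n - fl + 1, by = hp)
  vals <- t(vapply(starts, function(s) {
    p <- welch_psd(x[s:(s + fl - 1)], fs, nseg = fl)
    l <- band_power(p, lf); h <- band_power(p, hf)
    c(l, h, if (h > 0) l / h else NA_real_, band_power(p, c(0.0033, 0.5)))
  }, numeric(4)))
  m <- colMeans(vals, na.rm = TRUE)
  s <- apply(vals, 2, sd, na.rm = TRUE)
  out[] <- c(m[1], s[1], m[2], s[2], m[3], s[3], m[4], s[4])
  out
}

# Haar filter-bank decomposition: power per dyadic detail level, assigned
# to a frequency band by the level's centre frequency.
haar_levels <- function(x, fs) {
  x <- x - mean(x)
  n0 <- length(x)
  lev <- list()
  j <- 0
  while (length(x) >= 4) {
    j <- j + 1
    m <- floor(length(x) / 2) * 2
    ev <- x[seq(2, m, by = 2)]; od <- x[seq(1, m - 1, by = 2)]
    d <- (od - ev) / sqrt(2)
    x <- (od + ev) / sqrt(2)
    lev[[j]] <- list(level = j, power = sum(d^2) / n0,
                     centre = 0.75 * fs / 2^j,
                     lo = fs / 2^(j + 1), hi = fs / 2^j)
  }
  lev
}

haar_band_summaries <- function(x, fs, bands) {
  lev <- haar_levels(x, fs)
  if (!length(lev)) {
    out <- setNames(rep(NA_real_, length(bands)), names(bands))
    return(list(power = out, total = NA_real_, entropy = NA_real_))
  }
  centres <- vapply(lev, `[[`, 0, "centre")
  powers <- vapply(lev, `[[`, 0, "power")
  out <- vapply(bands, function(b)
    sum(powers[centres >= b[1] & centres < b[2]]), 0)
  total <- sum(powers)
  p <- powers[powers > 0] / total
  ent <- if (total > 0) -sum(p * log(p)) else 0
  list(power = out, total = total, entropy = ent)
}
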