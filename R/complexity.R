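# Nonlinear / fractal complexity measures used across all four modalities.
# Pure functions of a numeric series and a parameter object; deterministic;
# degenerate inputs (zero variance, too short) return documented fallback
# constants or NA missing-markers rather than raising, so feature extraction
# never aborts a window.

#' Parameters for the complexity metrics
#'
#' @param m Embedding dimension for entropy measures (default 2).
#' @param r_frac Tolerance as a fraction of the series' own standard
#'   deviation (default 0.2); using the sub-window's own SD makes sample
#'   entropy scale-invariant.
#' @param ctm_rho_frac Central-tendency-measure radius as a fraction of the
#'   series SD (default 0.1).
#' @param mse_scales Coarse-graining scales for multiscale entropy.
#' @param mfdfa_q Moment orders for multifractal DFA (0 excluded internally).
#' @param min_len_regression Minimum series length for the regression-based
#'   estimators (Hurst, DFA, Lyapunov, correlation dimension); shorter series
#'   yield `NA`.
#' @param max_len_embedding Longest series the pairwise embedding-based
#'   estimators (Lyapunov, correlation dimension, fuzzy entropy) operate
#'   on; longer series use their first `max_len_embedding` points, the
#'   usual practice for these quadratic-cost estimators on long windows.
#' @return A list of class `metric_params`.
#' @export
metric_params <- function(m = 2L, r_frac = 0.2, ctm_rho_frac = 0.1,
                          mse_scales = 1:10, mfdfa_q = -5:5,
                          min_len_regression = 64L,
                          max_len_embedding = 256L) {
  stopifnot(m >= 1, r_frac > 0, ctm_rho_frac > 0)
  structure(list(m = as.integer(m), r_frac = r_frac,
                 ctm_rho_frac = ctm_rho_frac, mse_scales = mse_scales,
                 mfdfa_q = mfdfa_q,
                 min_len_regression = as.integer(min_len_regression),
                 max_len_embedding = as.integer(max_len_embedding)),
            class = "metric_params")
}

.finite <- function(x) x[is.finite(x)]

.zero_var <- function(x) length(x) < 2 || sd(x) == 0 || !is.finite(sd(x))

#' Sample entropy
#'
#' SampEn(m, r) = -ln(A/B) where B counts template pairs of length `m`
#' matching within Chebyshev distance `r` and A those still matching at
#' length `m + 1`; self-matches excluded. Zero-variance input returns 0.
#'
#' @param x Numeric series.
#' @param params A [metric_params()] object.
#' @param r Absolute tolerance; defaults to `r_frac * sd(x)`.
#' @return Nonnegative scalar, or `NA` if the series is too short or no
#'   template pair matches.
#' @export
sample_entropy <- function(x, params = metric_params(), r = NULL) {
  x <- .finite(x)
  if (length(x) < params$m + 2) return(NA_real_)
  if (.zero_var(x)) return(0)
  x <- head(x, params$max_len_embedding %||% length(x))
  if (is.null(r)) r <- params$r_frac * sd(x)
  cpp_sampen(x, params$m, r)
}

#' Approximate entropy
#'
#' Pincus ApEn(m, r) with self-matches included. Zero-variance input
#' returns 0.
#' @inheritParams sample_entropy
#' @export
approximate_entropy <- function(x, params = metric_params(), r = NULL) {
  x <- .finite(x)
  if (length(x) < params$m + 2) return(NA_real_)
  if (.zero_var(x)) return(0)
  x <- head(x, params$max_len_embedding %||% length(x))
  if (is.null(r)) r <- params$r_frac * sd(x)
  cpp_apen(x, params$m, r)
}

#' Multiscale entropy
#'
#' Sample entropy of non-overlapping coarse-grained averages at each scale.
#' The tolerance is fixed from the original series SD (Costa convention),
#' so scale 1 equals [sample_entropy()] exactly.
#'
#' @inheritParams sample_entropy
#' @param scales Integer scales (default from `params`).
#' @return Named numeric vector of SampEn by scale.
#' @export
multiscale_entropy <- function(x, params = metric_params(),
                               scales = params$mse_scales) {
  x <- .finite(x)
  out <- setNames(rep(NA_real_, length(scales)), paste0("scale", scales))
  if (length(x) < params$m + 2) return(out)
  if (.zero_var(x)) { out[] <- 0; return(out) }
  x <- head(x, params$max_len_embedding %||% length(x))
  r <- params$r_frac * sd(x)
  for (i in seq_along(scales)) {
    s <- scales[i]
    nseg <- floor(length(x) / s)
    if (nseg < params$m + 2) next
    cg <- colMeans(matrix(x[seq_len(nseg * s)], nrow = s))
    if (.zero_var(cg)) { out[i] <- 0; next }
    out[i] <- cpp_sampen(cg, params$m, r)
  }
  out
}

#' Lempel-Ziv complexity
#'
#' LZ76 phrase count of the median-binarized sequence, normalized by
#' `n / log2(n)`. Deterministic and parameter-free.
#'
#' @param x Numeric series (length >= 2).
#' @param normalize If `FALSE`, return the raw phrase count.
#' @return Normalized complexity (or phrase count).
#' @export
lempel_ziv_complexity <- function(x, normalize = TRUE) {
  x <- .finite(x)
  n <- length(x)
  if (n < 2) return(NA_real_)
  b <- as.integer(x > median(x))
  cc <- cpp_lz76(b)
  if (!normalize) return(as.numeric(cc))
  cc * log2(n) / n
}

#' Central tendency measure
#'
#' Fraction of successive-difference scatter points
#' `(x[i+1]-x[i], x[i+2]-x[i+1])` lying strictly inside radius `rho`.
#' Constant series return 1.
#'
#' @param x Numeric series (length >= 3).
#' @param rho Radius; defaults to `ctm_rho_frac * sd(x)` (so with a fixed
#'   relative radius the measure is scale-invariant; an absolute `rho` is
#'   not).
#' @param params A [metric_params()] object.
#' @export
central_tendency_measure <- function(x, rho = NULL,
                                     params = metric_params()) {
  x <- .finite(x)
  if (length(x) < 3) return(NA_real_)
  if (.zero_var(x)) return(1)
  if (is.null(rho)) rho <- params$ctm_rho_frac * sd(x)
  cpp_ctm(x, rho)
}

#' Poincare descriptors SD1 and SD2
#'
#' SD1 = SD of successive differences / sqrt(2); SD2 via the ellipse
#' identity SD1^2 + SD2^2 = 2 * Var(x) (population variance), so the
#' identity holds exactly.
#'
#' @param x Interval series (e.g. R-R in ms), length >= 3.
#' @return Named vector `c(SD1, SD2)`.
#' @export
poincare_descriptors <- function(x) {
  x <- .finite(x)
  if (length(x) < 3) return(c(SD1 = NA_real_, SD2 = NA_real_))
  pvar <- function(v) mean((v - mean(v))^2)
  sd1 <- sqrt(pvar(diff(x)) / 2)
  sd2sq <- 2 * pvar(x) - sd1^2
  c(SD1 = sd1, SD2 = sqrt(max(sd2sq, 0)))
}

#' Hurst exponent (rescaled-range estimate)
#'
#' Log-log regression of the rescaled range R/S over dyadic segment sizes.
#' White noise gives ~0.5, persistent series approach 1. Zero-variance
#' fallback 0.5; series shorter than `min_len_regression` give `NA`.
#'
#' @inheritParams sample_entropy
#' @export
hurst_exponent <- function(x, params = metric_params()) {
  x <- .finite(x)
  n <- length(x)
  if (.zero_var(x)) return(0.5)
  if (n < params$min_len_regression) return(NA_real_)
  sizes <- unique(floor(n / 2^(0:floor(log2(n / 8)))))
  sizes <- sizes[sizes >= 8]
  if (length(sizes) < 3) return(NA_real_)
  rs <- vapply(sizes, function(s) {
    k <- floor(n / s)
    vals <- vapply(seq_len(k), function(i) {
      seg <- x[((i - 1) * s + 1):(i * s)]
      z <- cumsum(seg - mean(seg))
      r <- max(z) - min(z)
      ssd <- sd(seg)
      if (ssd == 0) NA_real_ else r / ssd
    }, 0)
    mean(vals, na.rm = TRUE)
  }, 0)
  ok <- is.finite(rs) & rs > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm.fit(cbind(1, log(sizes[ok])), log(rs[ok])))[2])
}

#' Detrended fluctuation analysis exponent
#'
#' DFA-1: RMS fluctuation of the linearly detrended integrated profile over
#' a range of box sizes; alpha is the log-log slope. White noise gives
#' ~0.5. Zero-variance fallback 0.5.
#'
#' @inheritParams sample_entropy
#' @param scales Box sizes; default dyadic spread between 4 and n/4.
#' @export
dfa_alpha <- function(x, params = metric_params(), scales = NULL) {
  x <- .finite(x)
  n <- length(x)
  if (.zero_var(x)) return(0.5)
  if (n < params$min_len_regression) return(NA_real_)
  if (is.null(scales))
    scales <- unique(round(exp(seq(log(4), log(n / 4), length.out = 10))))
  f <- .dfa_fluct(x, scales)
  ok <- is.finite(f) & f > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm.fit(cbind(1, log(scales[ok])), log(f[ok])))[2])
}

# RMS fluctuation per box size for the integrated, per-box linearly
# detrended profile.
.dfa_fluct <- function(x, scales) {
  y <- cumsum(x - mean(x))
  n <- length(y)
  vapply(scales, function(s) {
    k <- floor(n / s)
    if (k < 1) return(NA_real_)
    t <- seq_len(s)
    sst <- sum((t - mean(t))^2)
    res2 <- vapply(seq_len(k), function(i) {
      seg <- y[((i - 1) * s + 1):(i * s)]
      b <- sum((t - mean(t)) * (seg - mean(seg))) / sst
      a <- mean(seg) - b * mean(t)
      sum((seg - a - b * t)^2)
    }, 0)
    sqrt(sum(res2) / (k * s))
  }, 0)
}

#' Multifractal DFA: singularity-spectrum peak
#'
#' Computes generalized fluctuation exponents h(q) over `mfdfa_q`, the mass
#' exponent tau(q) = q h(q) - 1, the Legendre transform alpha = dtau/dq and
#' f(alpha) = q alpha - tau; returns the alpha at which f is maximal (the
#' spectrum mode). Zero-variance fallback 0.5.
#'
#' @inheritParams sample_entropy
#' @export
mfdfa_alpha1_peak <- function(x, params = metric_params()) {
  x <- .finite(x)
  n <- length(x)
  if (.zero_var(x)) return(0.5)
  if (n < 32) return(NA_real_)
  q <- setdiff(params$mfdfa_q, 0)
  scales <- unique(round(exp(seq(log(8), log(max(n / 4, 10)),
                                 length.out = 6))))
  scales <- scales[scales >= 4 & scales <= n / 2]
  if (length(scales) < 3) return(NA_real_)
  y <- cumsum(x - mean(x))
  # per-scale, per-box squared fluctuations
  f2 <- lapply(scales, function(s) {
    k <- floor(n / s)
    t <- seq_len(s)
    sst <- sum((t - mean(t))^2)
    vapply(seq_len(k), function(i) {
      seg <- y[((i - 1) * s + 1):(i * s)]
      b <- sum((t - mean(t)) * (seg - mean(seg))) / sst
      a <- mean(seg) - b * mean(t)
      mean((seg - a - b * t)^2)
    }, 0)
  })
  hq <- vapply(q, function(qq) {
    fq <- vapply(f2, function(v) {
      v <- v[v > 0]
      if (!length(v)) return(NA_real_)
      mean(v^(qq / 2))^(1 / qq)
    }, 0)
    ok <- is.finite(fq) & fq > 0
    if (sum(ok) < 3) return(NA_real_)
    unname(coef(lm.fit(cbind(1, log(scales[ok])), log(fq[ok])))[2])
  }, 0)
  ok <- is.finite(hq)
  if (sum(ok) < 3) return(NA_real_)
  q <- q[ok]; hq <- hq[ok]
  tau <- q * hq - 1
  alpha <- diff(tau) / diff(q)
  qm <- (q[-1] + q[-length(q)]) / 2
  f_alpha <- qm * alpha - (tau[-1] + tau[-length(tau)]) / 2
  alpha[which.max(f_alpha)]
}

#' Correlation dimension (Grassberger-Procaccia)
#'
#' Slope of log C(r) against log r over a mid-range of radii, embedding
#' dimension `m`, delay 1, Chebyshev norm. Zero-variance fallback 0.
#'
#' @inheritParams sample_entropy
#' @export
correlation_dimension <- function(x, params = metric_params()) {
  x <- .finite(x)
  if (.zero_var(x)) return(0)
  if (length(x) < params$min_len_regression) return(NA_real_)
  x <- head(x, params$max_len_embedding %||% length(x))
  s <- sd(x)
  rvals <- s * exp(seq(log(0.1), log(1), length.out = 8))
  cs <- cpp_corr_sum(x, params$m, rvals)
  ok <- is.finite(cs) & cs > 0
  if (sum(ok) < 3) return(NA_real_)
  unname(coef(lm.fit(cbind(1, log(rvals[ok])), log(cs[ok])))[2])
}

#' Largest Lyapunov exponent (Rosenstein)
#'
#' Mean log divergence of nearest-neighbour trajectories against step,
#' embedding dimension `m`, delay 1, Theiler window 10; the exponent is the
#' initial slope (per sample). Zero-variance fallback 0.
#'
#' @inheritParams sample_entropy
#' @export
largest_lyapunov <- function(x, params = metric_params()) {
  x <- .finite(x)
  if (.zero_var(x)) return(0)
  if (length(x) < params$min_len_regression) return(NA_real_)
  x <- head(x, params$max_len_embedding %||% length(x))
  kmax <- min(20L, floor(length(x) / 5))
  curve <- cpp_rosenstein_curve(x, params$m, 1L, 10L, kmax)
  ok <- is.finite(curve)
  if (sum(ok) < 3) return(NA_real_)
  k <- seq_len(kmax)[ok]
  unname(coef(lm.fit(cbind(1, k), curve[ok]))[2])
}

# ---- small auxiliary entropies used in the HRV catalog -------------------

# Shannon entropy (nats) of a fixed-bin histogram.
shannon_entropy <- function(x, bins = 10) {
  x <- .finite(x)
  if (length(x) < 2 || .zero_var(x)) return(0)
  h <- tabulate(cut(x, breaks = bins, labels = FALSE), nbins = bins)
  p <- h[h > 0] / sum(h)
  -sum(p * log(p))
}

# Permutation entropy, order 3, delay 1, normalized to [0, 1].
permutation_entropy <- function(x, order = 3L) {
  x <- .finite(x)
  n <- length(x) - order + 1
  if (n < 2 || .zero_var(x)) return(0)
  pat <- vapply(seq_len(n), function(i)
    paste(order(x[i:(i + order - 1)]), collapse = ""), "")
  p <- table(pat) / n
  -sum(p * log(p)) / log(factorial(order))
}

# Fuzzy entropy: exponential membership exp(-(d/r)^2) on mean-centred
# templates.
fuzzy_entropy <- function(x, params = metric_params()) {
  x <- .finite(x)
  if (length(x) < params$m + 2) return(NA_real_)
  if (.zero_var(x)) return(0)
  x <- head(x, params$max_len_embedding %||% length(x))
  r <- params$r_frac * sd(x)
  phi <- function(mm) {
    nt <- length(x) - mm
    tm <- t(vapply(seq_len(nt), function(i) {
      v <- x[i:(i + mm - 1)]; v - mean(v)
    }, numeric(mm)))
    d <- as.matrix(stats::dist(tm, method = "maximum"))
    diag(d) <- NA
    mean(exp(-(d / r)^2), na.rm = TRUE)
  }
  log(phi(params$m)) - log(phi(params$m + 1L))
}

# Katz fractal dimension.
katz_fd <- function(x) {
  x <- .finite(x)
  n <- length(x)
  if (n < 3 || .zero_var(x)) return(1)
  L <- sum(sqrt(1 + diff(x)^2))
  d <- max(sqrt((seq_len(n) - 1)^2 + (x - x[1])^2))
  log10(n - 1) / (log10(n - 1) + log10(d / L))
}
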