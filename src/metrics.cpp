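#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Sample entropy: -log(A/B) with template pairs (i, j), i < j, matching
// within Chebyshev distance r; self-matches excluded by construction.
// Both counts run over the first n - m templates so A <= B.
// [[Rcpp::export]]
double cpp_sampen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  double B = 0.0, A = 0.0;
  {
    int nt = n - m;          // number of m-templates considered
    for (int i = 0; i < nt - 1; ++i) {
      for (int j = i + 1; j < nt; ++j) {
        bool match = true;
        for (int k = 0; k < m; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
        }
        if (match) {
          B += 1.0;
          if (std::fabs(x[i + m] - x[j + m]) <= r) A += 1.0;
        }
      }
    }
  }
  if (B == 0.0) return NA_REAL;
  if (A == 0.0) return NA_REAL;
  return -std::log(A / B);
}

// [[Rcpp::export]]
double cpp_apen(NumericVector x, int m, double r) {
  int n = x.size();
  if (n < m + 2) return NA_REAL;
  double phi[2];
  for (int pass = 0; pass < 2; ++pass) {
    int mm = m + pass;
    int nt = n - mm + 1;
    double s = 0.0;
    for (int i = 0; i < nt; ++i) {
      double c = 0.0;
      for (int j = 0; j < nt; ++j) {
        bool match = true;
        for (int k = 0; k < mm; ++k) {
          if (std::fabs(x[i + k] - x[j + k]) > r) { match = false; break; }
        }
        if (match) c += 1.0;  // self-match included, per Pincus
      }
      s += std::log(c / nt);
    }
    phi[pass] = s / nt;
  }
  return phi[0] - phi[1];
}

// LZ76 phrase count of a 0/1 sequence (exhaustive history scan).
// [[Rcpp::export]]
int cpp_lz76(IntegerVector s) {
  int n = s.size();
  if (n == 0) return 0;
  int c = 1;       // first phrase is s[0]
  int i = 1;       // start of current phrase
  while (i < n) {
    int l = 1;     // current candidate extension length
    // find longest prefix of s[i..] reproducible from s[0..i+l-2]
    while (i + l <= n) {
      bool found = false;
      for (int j = 0; j <= i + l - 1 - l; ++j) {
        bool eq = true;
        for (int k = 0; k < l; ++k) {
          if (s[j + k] != s[i + k]) { eq = false; break; }
        }
        if (eq) { found = true; break; }
      }
      if (!found) break;
      ++l;
    }
    c += 1;
    i += l;
  }
  return c;
}

// Central tendency measure: fraction of (dx_{i+1}, dx_i) points with radius < rho.
// [[Rcpp::export]]
double cpp_ctm(NumericVector x, double rho) {
  int n = x.size();
  if (n < 3) return NA_REAL;
  double inside = 0.0;
  int np = n - 2;
  for (int i = 0; i < np; ++i) {
    double d1 = x[i + 1] - x[i];
    double d2 = x[i + 2] - x[i + 1];
    if (std::sqrt(d1 * d1 + d2 * d2) < rho) inside += 1.0;
  }
  return inside / np;
}

// Correlation sums C(r) for Grassberger-Procaccia, embedding dim m, delay 1.
// [[Rcpp::export]]
NumericVector cpp_corr_sum(NumericVector x, int m, NumericVector rvals) {
  int n = x.size();
  int nv = n - m + 1;
  int nr = rvals.size();
  NumericVector out(nr);
  if (nv < 2) { out.fill(NA_REAL); return out; }
  std::vector<double> counts(nr, 0.0);
  for (int i = 0; i < nv - 1; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;  // Chebyshev norm
      }
      for (int q = 0; q < nr; ++q) if (d < rvals[q]) counts[q] += 1.0;
    }
  }
  double np = 0.5 * (double)nv * (nv - 1);
  for (int q = 0; q < nr; ++q) out[q] = counts[q] / np;
  return out;
}

// Rosenstein largest-Lyapunov scaffold: mean log divergence at steps 1..kmax
// from each point's nearest neighbour (Theiler exclusion w).
// [[Rcpp::export]]
NumericVector cpp_rosenstein_curve(NumericVector x, int m, int tau, int w, int kmax) {
  int n = x.size();
  int nv = n - (m - 1) * tau;
  NumericVector out(kmax);
  if (nv - kmax < 2 * w + 2) { out.fill(NA_REAL); return out; }
  int nuse = nv - kmax;
  std::vector<int> nn(nuse, -1);
  for (int i = 0; i < nuse; ++i) {
    double best = R_PosInf;
    for (int j = 0; j < nuse; ++j) {
      if (std::abs(i - j) <= w) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = x[i + k * tau] - x[j + k * tau];
        d += dk * dk;
      }
      if (d < best && d > 0.0) { best = d; nn[i] = j; }
    }
  }
  for (int s = 1; s <= kmax; ++s) {
    double acc = 0.0; int cnt = 0;
    for (int i = 0; i < nuse; ++i) {
      int j = nn[i];
      if (j < 0) continue;
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = x[i + s + k * tau] - x[j + s + k * tau];
        d += dk * dk;
      }
      if (d > 0.0) { acc += 0.5 * std::log(d); cnt += 1; }
    }
    out[s - 1] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}

// Pulse (beat) onset detection on an arterial-pressure waveform.
// A beat onset is the local minimum preceding a sustained upstroke whose
// slope exceeds `slope_thresh` (physical units per second); `refractory`
// seconds must separate onsets. NA samples break the search.
// [[Rcpp::export]]
IntegerVector cpp_pulse_onsets(NumericVector x, double fs, double slope_thresh,
                               double refractory) {
  int n = x.size();
  std::vector<int> onsets;
  int refr = (int)std::floor(refractory * fs);
  int look = (int)std::floor(0.4 * fs);  // search-back span for the trough
  if (look < 1) look = 1;
  int last = -refr - 1;
  for (int i = 1; i < n; ++i) {
    if (ISNAN(x[i]) || ISNAN(x[i - 1])) continue;
    double slope = (x[i] - x[i - 1]) * fs;
    if (slope > slope_thresh && i - last > refr) {
      // walk back to the local minimum
      int j = i - 1;
      int lo = std::max(0, i - look);
      int argmin = j;
      double vmin = x[j];
      while (j > lo && !ISNAN(x[j - 1])) {
        --j;
        if (x[j] < vmin) { vmin = x[j]; argmin = j; }
      }
      if (onsets.empty() || argmin - onsets.back() > refr) {
        onsets.push_back(argmin);
        last = i;
      }
    }
  }
  return wrap(onsets);  // 0-based; caller adjusts
}

// Spike-train peak detector (for synthetic/filtered ECG): local maxima above
// `thresh` separated by at least `refractory` seconds.
// [[Rcpp::export]]
IntegerVector cpp_spike_peaks(NumericVector x, double fs, double thresh,
                              double refractory) {
  int n = x.size();
  std::vector<int> peaks;
  int refr = (int)std::floor(refractory * fs);
  int last = -refr - 1;
  for (int i = 1; i < n - 1; ++i) {
    if (ISNAN(x[i])) continue;
    if (x[i] >= thresh && !ISNAN(x[i - 1]) && !ISNAN(x[i + 1]) &&
        x[i] >= x[i - 1] && x[i] > x[i + 1]) {
      if (i - last > refr) {
        peaks.push_back(i);
        last = i;
      } else if (!peaks.empty() && x[i] > x[peaks.back()]) {
        peaks.back() = i;  // keep the taller peak inside the refractory span
        last = i;
      }
    }
  }
  return wrap(peaks);
}

// Per-beat summaries between consecutive onsets: max value, index of the
// max (0-based, absolute), and mean over the beat's samples (NA-aware).
// [[Rcpp::export]]
List cpp_beat_stats(NumericVector x, IntegerVector onsets) {
  int nb = onsets.size() - 1;
  NumericVector vmax(nb), vmean(nb);
  IntegerVector imax(nb);
  for (int k = 0; k < nb; ++k) {
    int a = onsets[k], b = onsets[k + 1];  // 0-based, beat covers [a, b)
    double mx = R_NegInf, sum = 0.0; int arg = a, cnt = 0;
    for (int i = a; i < b; ++i) {
      double v = x[i];
      if (ISNAN(v)) continue;
      if (v > mx) { mx = v; arg = i; }
      sum += v; cnt += 1;
    }
    vmax[k] = cnt ? mx : NA_REAL;
    imax[k] = arg;
    vmean[k] = cnt ? sum / cnt : NA_REAL;
  }
  return List::create(_["max"] = vmax, _["argmax"] = imax,
                      _["mean"] = vmean);
}
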