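# Fixed feature catalog: 299 features across four waveform modalities.
# The catalog is a compile-time constant; extraction functions key into it,
# and its per-modality cardinalities (ABP 90, ECG 89, RESP 112, SpO2 8) are
# asserted in the test suite.

# Ten summary statistics applied to every per-beat / per-cycle parameter
# series, in fixed order.
.stat_names <- c("Min", "Mean", "Max", "Median", "STD", "Skewness",
                 "Kurtosis", "Hurst", "Lyapunov", "SampEn")

# Nine beat-level arterial-pressure parameters: systolic and diastolic
# pressure, pulse pressure, waveform-average pressure between adjacent
# onsets (MeanAP), formulaic mean arterial pressure (DBP + PP/3), heart
# rate, systolic-peak to next diastolic-point interval, and the absolute
# differences between consecutive systolic / diastolic values.
.abp_params <- c("Psys", "Pdias", "PP", "MeanAP", "MAP", "HR",
                 "TimeSBP2DBP", "AmplitudeSBP", "AmplitudeDBP")

# Nine breath-cycle parameters.
.resp_params <- c("Cycle_Amplitude", "Width", "PeakInterval",
                  "TroughInterval", "Amplitude", "Cycle_Rate", "RVT",
                  "Cycle_Symmetry_PeakTrough", "Cycle_Symmetry_RiseDecay")

# 89 heart-rate-variability indices over time, frequency, time-frequency
# and nonlinear domains. The membership is fixed and versioned; counts are
# asserted in tests.
.hrv_names <- c(
  # time domain (21)
  "MeanNN", "MinNN", "MaxNN", "RangeNN", "MedianNN", "SDNN", "RMSSD",
  "SDSD", "CVNN", "CVSD", "MCVNN", "MadNN", "IQRNN", "pNN10", "pNN20",
  "pNN50", "SDANN", "SDNNI", "HTI", "TINN", "MeanHR",
  # frequency domain (16)
  "ULF", "VLF", "LF", "HF", "VHF", "TotalPower", "LnVLF", "LnLF", "LnHF",
  "LFHF", "LFn", "HFn", "PeakLF", "PeakHF", "RelLF", "RelHF",
  # short-time Fourier summaries (8)
  "STFT_LF_Mean", "STFT_LF_SD", "STFT_HF_Mean", "STFT_HF_SD",
  "STFT_LFHF_Mean", "STFT_LFHF_SD", "STFT_Total_Mean", "STFT_Total_SD",
  # wavelet summaries (8)
  "WT_VLF", "WT_LF", "WT_HF", "WT_LFHF", "WT_RelVLF", "WT_RelLF",
  "WT_RelHF", "WT_Entropy",
  # Poincare geometry (6)
  "SD1", "SD2", "SD1SD2", "EllipseArea", "CSI", "CVI",
  # fragmentation (4)
  "PIP", "IALS", "PSS", "PAS",
  # nonlinear / complexity (26)
  "ApEn", "SampEn",
  paste0("MSE_Scale", 1:10), "MSE_Mean", "MSE_Slope",
  "DFA_Alpha1", "DFA_Alpha2", "MFDFA_Alpha1_Peak", "CD", "Hurst",
  "Lyapunov", "LZC", "CTM", "ShanEn", "FuzzyEn", "PermEn", "KFD")

# 22 respiratory-rate-variability indices on the breath-to-breath interval
# series: time domain, parametric/nonparametric/irregular-sampling spectra,
# nonlinear and wavelet summaries, and the multifractal singularity peak.
.rrv_names <- c(
  "MeanBB", "SDBB", "RMSSD", "SDSD", "CVBB", "MCVBB", "MedianBB", "MadBB",
  "Burg_LF", "Burg_HF", "Burg_LFHF",
  "Welch_LF", "Welch_HF", "Welch_LFHF",
  "Lomb_LF", "Lomb_HF", "Lomb_LFHF",
  "SampEn", "SD1", "SD2", "WT_LFHF", "MFDFA_Alpha1_Peak")

.spo2_names <- c("Smin", "Smean", "Smax", "Smedian", "Ssd",
                 "SampEn", "LZC", "CTM")

#' The fixed 299-feature catalog
#'
#' Returns the versioned, immutable feature catalog used by every pipeline
#' stage: 90 arterial-blood-pressure features (nine beat parameters crossed
#' with ten statistics), 89 heart-rate-variability features, 112 respiratory
#' features (nine cycle parameters crossed with ten statistics plus 22
#' breath-to-breath variability indices) and 8 oxygen-saturation features.
#'
#' @return An object of class `feature_catalog`: a list with per-modality
#'   ordered name vectors (`abp`, `ecg`, `resp`, `spo2`), the combined
#'   vector `all`, a `modality` lookup and a `version` tag.
#' @examples
#' cat <- shock_catalog()
#' length(cat$all)      # 299
#' length(cat$abp)      # 90
#' @export
shock_catalog <- function() {
  abp  <- as.vector(t(outer(.abp_params, .stat_names,
                            function(p, s) paste0("ABP_", p, "_", s))))
  ecg  <- paste0("ECG_HRV_", .hrv_names)
  resp <- c(as.vector(t(outer(.resp_params, .stat_names,
                              function(p, s) paste0("RESP_", p, "_", s)))),
            paste0("RESP_RRV_", .rrv_names))
  spo2 <- paste0("SPO2_", .spo2_names)
  all  <- c(abp, ecg, resp, spo2)
  stopifnot(!anyDuplicated(all))
  structure(list(
    abp = abp, ecg = ecg, resp = resp, spo2 = spo2, all = all,
    modality = setNames(rep(c("ABP", "ECG", "RESP", "SPO2"),
                            c(length(abp), length(ecg), length(resp),
                              length(spo2))), all),
    version = "1.0.0"), class = "feature_catalog")
}

#' @export
print.feature_catalog <- function(x, ...) {
  cat("<feature_catalog v", x$version, "> ",
      length(x$abp), " ABP + ", length(x$ecg), " ECG + ",
      length(x$resp), " RESP + ", length(x$spo2), " SpO2 = ",
      length(x$all), " features\n", sep = "")
  invisible(x)
}

#' Write the catalog manifest
#'
#' Serializes the ordered feature name lists and version tag as JSON, the
#' sidecar format carried alongside every feature table the package writes.
#'
#' @param catalog A `feature_catalog`.
#' @param path Output file path.
#' @export
write_catalog_manifest <- function(catalog, path) {
  jsonlite::write_json(
    list(version = catalog$version, abp = catalog$abp, ecg = catalog$ecg,
         resp = catalog$resp, spo2 = catalog$spo2),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
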