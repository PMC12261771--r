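# WaveformRecord: one patient's aligned multi-channel signals with
# per-channel sampling rates and validity masks, plus timestamped lactate
# labs and demographic covariates.
#
# Time convention: all intervals are half-open [start, end) in seconds from
# record start; sample i of a channel at rate fs covers [i/fs, (i+1)/fs).
# Channels keep their native rates; there is no global resampling.

.modalities <- c("ABP", "ECG", "RESP", "SPO2")

#' Construct a waveform record
#'
#' @param patient_id Opaque patient identifier (string).
#' @param channels Named list over a subset of `ABP`, `ECG`, `RESP`, `SPO2`;
#'   each element a list with `fs` (Hz), `samples` (numeric; `NA` allowed
#'   where invalid) and optionally `valid` (logical mask, defaults to
#'   `!is.na(samples)`). Units: ABP mmHg, ECG mV, RESP arbitrary, SpO2 %.
#' @param record_start Absolute start time in seconds (numeric; default 0).
#'   All other times in the record are relative to it.
#' @param labs Data frame with columns `time_s` and `lactate` (mmol/L).
#' @param covariates Named list/vector: `age` (years), `sex` ("M"/"F"),
#'   `bmi` (kg/m2), `neck` (cm), `waist` (cm).
#' @return An object of class `waveform_record`.
#' @export
waveform_record <- function(patient_id, channels, record_start = 0,
                            labs = NULL, covariates = NULL) {
  stopifnot(is.character(patient_id), length(patient_id) == 1L)
  if (is.null(labs))
    labs <- data.frame(time_s = numeric(0), lactate = numeric(0))
  bad <- setdiff(names(channels), .modalities)
  if (length(bad)) stop("unknown channel(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(names(channels))) stop("duplicate channel names")
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (is.null(ch$fs) || ch$fs <= 0) stop("channel ", nm, ": fs must be > 0")
    if (is.null(ch$valid)) {
      ch$valid <- !is.na(ch$samples)       # derived mask; samples untouched
    } else {
      if (length(ch$valid) != length(ch$samples))
        stop("channel ", nm, ": samples and valid mask differ in length")
      if (!all(ch$valid)) ch$samples[!ch$valid] <- NA_real_
    }
    channels[[nm]] <- ch[c("fs", "samples", "valid")]
  }
  if (nrow(labs) && any(labs$lactate < 0, na.rm = TRUE))
    stop("lactate values must be >= 0")
  structure(list(patient_id = patient_id, channels = channels,
                 record_start = record_start, labs = labs,
                 covariates = covariates),
            class = "waveform_record")
}

#' @export
print.waveform_record <- function(x, ...) {
  cat("<waveform_record ", x$patient_id, "> span ",
      round(record_duration(x), 1), " s; channels: ",
      paste(sprintf("%s@%gHz", names(x$channels),
                    vapply(x$channels, `[[`, 0, "fs")), collapse = ", "),
      "; ", nrow(x$labs), " lactate lab(s)\n", sep = "")
  invisible(x)
}

#' @export
record_duration <- function(record) {
  if (!length(record$channels)) return(0)
  max(vapply(record$channels,
             function(ch) length(ch$samples) / ch$fs, 0))
}

#' @export
has_channel <- function(record, channel) channel %in% names(record$channels)

#' Extract one channel over a half-open interval
#'
#' @param record A `waveform_record`.
#' @param channel One of `ABP`, `ECG`, `RESP`, `SPO2`.
#' @param interval Numeric length-2 `[start, end)` in seconds from record
#'   start, or `NULL` for the full channel.
#' @return List with `fs`, `t0` (time of the first returned sample),
#'   `samples` and `valid`.
#' @export
channel_slice <- function(record, channel, interval = NULL) {
  if (!has_channel(record, channel)) stop("channel absent: ", channel)
  ch <- record$channels[[channel]]
  if (is.null(interval))
    return(list(fs = ch$fs, t0 = 0, samples = ch$samples, valid = ch$valid))
  stopifnot(length(interval) == 2L, interval[2] > interval[1])
  i0 <- ceiling(interval[1] * ch$fs - 1e-9)        # first sample with i/fs >= start
  i1 <- ceiling(interval[2] * ch$fs - 1e-9) - 1    # last sample with i/fs < end
  i0 <- max(i0, 0L); i1 <- min(i1, length(ch$samples) - 1L)
  if (i1 < i0) stop("interval outside channel span")
  idx <- seq.int(i0 + 1L, i1 + 1L)
  list(fs = ch$fs, t0 = i0 / ch$fs,
       samples = ch$samples[idx], valid = ch$valid[idx])
}

#' Per-channel fraction of invalid samples over an interval
#'
#' Cohort rule: patients with more than 50% missing values in any used
#' window/channel are excluded.
#'
#' @inheritParams channel_slice
#' @param channels Channel names to report (default: all present).
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
missing_fraction <- function(record, interval = NULL,
                             channels = names(record$channels)) {
  if (!is.null(interval) && interval[2] <= interval[1])
    stop("empty interval")
  vapply(channels, function(nm) {
    sl <- channel_slice(record, nm, interval)
    mean(!sl$valid)
  }, 0)
}

# ---- CSV I/O (long format: one file per patient) -------------------------

#' Write a waveform record
#'
#' CSV layout (the portable fixture format): `<prefix>.csv` in long format
#' `(time_s, channel, value)` with `NA` for invalid samples, labs in
#' `<prefix>_labs.csv` `(time_s, lactate_mmol_per_L)` and a JSON sidecar
#' `<prefix>_meta.json` carrying patient id, record start, per-channel
#' sampling rates and covariates. WFDB layout: text header `<prefix>.hea`
#' plus one 16-bit little-endian `.dat` per signal (invalid sentinel
#' -32768), with the same labs/meta sidecars.
#'
#' @param record A `waveform_record`.
#' @param prefix Path prefix (no extension).
#' @param format `"csv"` or `"wfdb"`.
#' @return `prefix`, invisibly.
#' @export
write_waveform_record <- function(record, prefix, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  meta <- list(patient_id = record$patient_id,
               record_start = record$record_start,
               format = format,
               fs = lapply(record$channels, `[[`, "fs"),
               covariates = record$covariates)
  jsonlite::write_json(meta, paste0(prefix, "_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  labs <- record$labs
  names(labs) <- c("time_s", "lactate_mmol_per_L")
  write.csv(labs, paste0(prefix, "_labs.csv"), row.names = FALSE)
  if (format == "csv") {
    long <- do.call(rbind, lapply(names(record$channels), function(nm) {
      ch <- record$channels[[nm]]
      data.frame(time_s = (seq_along(ch$samples) - 1) / ch$fs,
                 channel = nm, value = ch$samples)
    }))
    write.csv(long, paste0(prefix, ".csv"), row.names = FALSE)
  } else {
    .write_wfdb(record, prefix)
  }
  invisible(prefix)
}

#' Read a waveform record
#'
#' @param prefix Path prefix as used by [write_waveform_record()].
#' @param format `"csv"` or `"wfdb"`.
#' @return A `waveform_record`. Channels absent from the file are absent
#'   from the returned record (flagged via `has_channel()`), never
#'   zero-filled.
#' @export
read_waveform_record <- function(prefix, format = c("csv", "wfdb")) {
  format <- match.arg(format)
  meta_path <- paste0(prefix, "_meta.json")
  if (!file.exists(meta_path)) stop("missing sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  labs_path <- paste0(prefix, "_labs.csv")
  labs <- if (file.exists(labs_path)) {
    lb <- read.csv(labs_path)
    data.frame(time_s = lb$time_s, lactate = lb$lactate_mmol_per_L)
  } else NULL
  channels <- if (format == "csv") {
    path <- paste0(prefix, ".csv")
    if (!file.exists(path)) stop("missing data file: ", path)
    long <- read.csv(path)
    if (anyDuplicated(paste(long$channel, long$time_s)))
      stop("corrupt record: duplicate (channel, index) rows")
    sapply(intersect(.modalities, unique(long$channel)), function(nm) {
      sub <- long[long$channel == nm, ]
      sub <- sub[order(sub$time_s), ]
      list(fs = meta$fs[[nm]], samples = sub$value)
    }, simplify = FALSE)
  } else {
    .read_wfdb(prefix)
  }
  waveform_record(meta$patient_id, channels,
                  record_start = meta$record_start, labs = labs,
                  covariates = meta$covariates)
}

# ---- minimal WFDB-compatible subset --------------------------------------
# One .dat per signal, format 16 (int16 little-endian), physical value
# = (adc - baseline) / gain, invalid sentinel -32768. Header: record line
# "<name> <nsig> <fs> <nsamp>" then one line per signal
# "<file> 16 <gain>(<baseline>)/<units> 16 0 0 0 0 <description>".
# Per-signal sampling rates are carried as an extra trailing field.

.wfdb_gain <- c(ABP = 100, ECG = 1000, RESP = 1000, SPO2 = 100)

.write_wfdb <- function(record, prefix) {
  base <- basename(prefix)
  lines <- sprintf("%s %d %g %d", base, length(record$channels), 1,
                   max(vapply(record$channels,
                              function(ch) length(ch$samples), 0L)))
  for (nm in names(record$channels)) {
    ch <- record$channels[[nm]]
    gain <- .wfdb_gain[[nm]]
    adc <- as.integer(round(ch$samples * gain))
    adc[!ch$valid | is.na(adc)] <- -32768L
    writeBin(adc, paste0(prefix, "_", nm, ".dat"), size = 2,
             endian = "little")
    lines <- c(lines, sprintf("%s_%s.dat 16 %g(0)/%s 16 0 0 0 0 %s fs=%g",
                              base, nm, gain, nm, nm, ch$fs))
  }
  writeLines(lines, paste0(prefix, ".hea"))
}

.read_wfdb <- function(prefix) {
  hea <- paste0(prefix, ".hea")
  if (!file.exists(hea)) stop("missing data file: ", hea)
  lines <- readLines(hea)
  if (length(lines) < 2) stop("corrupt header: ", hea)
  nsig <- as.integer(strsplit(lines[1], " +")[[1]][2])
  if (is.na(nsig) || length(lines) < nsig + 1) stop("corrupt header: ", hea)
  chans <- list()
  for (i in seq_len(nsig)) {
    f <- strsplit(lines[i + 1], " +")[[1]]
    file <- f[1]
    if (f[2] != "16") stop("unsupported WFDB format: ", f[2])
    gain <- as.numeric(sub("\\(.*", "", f[3]))
    nm <- f[9]
    fs <- as.numeric(sub("fs=", "", f[10]))
    adc <- readBin(file.path(dirname(prefix), file), integer(), size = 2,
                   n = file.size(file.path(dirname(prefix), file)) / 2,
                   endian = "little")
    x <- adc / gain
    x[adc == -32768L] <- NA_real_
    chans[[nm]] <- list(fs = fs, samples = x)
  }
  chans
}
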