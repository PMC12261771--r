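# Shock-event labeling: beat-averaged mean arterial pressure, hypotensive
# episode detection (MAP <= 65 mmHg sustained > 1 min), lactate
# qualification (>= 2 mmol/L within 12 h), self-controlled window
# construction and cohort exclusions.

#' Beat-wise mean arterial pressure series
#'
#' Detects beat onsets on the arterial-pressure waveform and computes one
#' MAP value per beat as the time-average pressure over the beat interval,
#' then interpolates to a regular 1 Hz series for episode logic. Spans
#' without detectable beats carry `NA` in the 1 Hz series.
#'
#' @param record A [waveform_record()] with an `ABP` channel, or a channel
#'   list as returned by [channel_slice()].
#' @param interval Optional `[start, end)` restriction (seconds).
#' @return List with `beats` (data frame `t`, `map`) and `map_1hz` (data
#'   frame `t`, `map`, regular 1 Hz grid).
#' @export
beatwise_map_series <- function(record, interval = NULL) {
  sl <- if (inherits(record, "waveform_record"))
    channel_slice(record, "ABP", interval) else record
  x <- sl$samples
  fs <- sl$fs
  ok <- !is.na(x)
  if (!any(ok)) stop("no detectable beats: no valid ABP samples")
  # archived records are segmented: work per contiguous valid run so the
  # arithmetic scales with recorded data, not record span
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- which(r$values & r$lengths >= 5 * fs)
  bt <- numeric(0); map <- numeric(0)
  for (ri in runs) {
    xa <- x[starts[ri]:ends[ri]]
    dx <- diff(xa)
    if (length(dx) > 1e5) dx <- dx[seq(1, length(dx), length.out = 1e5)]
    slope_thr <- 0.25 * quantile(dx, 0.98, na.rm = TRUE, names = FALSE) * fs
    if (!is.finite(slope_thr) || slope_thr <= 0) next
    on <- cpp_pulse_onsets(xa, fs, slope_thr, 0.3) + 1L
    if (length(on) < 3) next
    bs <- cpp_beat_stats(xa, on - 1L)
    bt <- c(bt, sl$t0 + (starts[ri] + on[-length(on)] - 2) / fs)
    map <- c(map, bs$mean)
  }
  if (length(bt) < 3) stop("no detectable beats in the requested span")
  beats <- data.frame(t = bt, map = map)
  t_grid <- seq(floor(min(bt)), ceiling(max(bt)))
  m <- approx(bt, map, xout = t_grid)$y
  # blank grid points far from any beat (gap spans stay NA)
  nearest <- findInterval(t_grid, bt)
  gap_ok <- rep(FALSE, length(t_grid))
  inside <- nearest >= 1 & nearest < length(bt)
  gap_ok[inside] <- (bt[pmin(nearest + 1, length(bt))] -
                       bt[pmax(nearest, 1)])[inside] < 5
  m[!gap_ok] <- NA_real_
  list(beats = beats, map_1hz = data.frame(t = t_grid, map = m))
}

#' Detect hypotensive episodes
#'
#' Maximal runs of the 1 Hz MAP series at or below the threshold lasting
#' strictly more than `min_duration` seconds, in time order. `NA` samples
#' break runs.
#'
#' @param map_1hz Data frame `t`, `map` on a regular 1 Hz grid.
#' @param threshold MAP threshold (mmHg), default 65.
#' @param min_duration Minimum sustained duration (s), strict, default 60.
#' @return Data frame with `start`, `end` (half-open, seconds); zero rows
#'   when no episode qualifies.
#' @export
detect_hypotension_episodes <- function(map_1hz, threshold = 65,
                                        min_duration = 60) {
  below <- !is.na(map_1hz$map) & map_1hz$map <= threshold
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths > min_duration
  data.frame(start = map_1hz$t[starts[keep]],
             end = map_1hz$t[ends[keep]] + 1)
}

#' Qualify the first shock event
#'
#' Returns the earliest hypotensive episode that has a serum-lactate
#' measurement meeting the threshold within 12 hours of the episode onset;
#' only the first such event per patient is used.
#'
#' @param episodes Data frame from [detect_hypotension_episodes()].
#' @param labs Data frame `time_s`, `lactate` (mmol/L).
#' @param lactate_threshold mmol/L, default 2.
#' @param lactate_op `">="` (default, the headline definition) or `">"`;
#'   the boundary is exposed for sensitivity analysis.
#' @param max_lag_h Association window half-width (hours), default 12.
#' @return A list of class `shock_event` (`episode_start`, `episode_end`,
#'   `onset`, `lactate_time`, `lactate_value`) or `NULL`.
#' @export
qualify_shock_event <- function(episodes, labs, lactate_threshold = 2,
                                lactate_op = c(">=", ">"), max_lag_h = 12) {
  lactate_op <- match.arg(lactate_op)
  cmp <- match.fun(lactate_op)
  if (!nrow(episodes) || !nrow(labs)) return(NULL)
  for (i in seq_len(nrow(episodes))) {
    onset <- episodes$start[i]
    ok <- cmp(labs$lactate, lactate_threshold) &
      abs(labs$time_s - onset) <= max_lag_h * 3600
    if (any(ok)) {
      j <- which(ok)[1]
      return(structure(list(episode_start = onset,
                            episode_end = episodes$end[i], onset = onset,
                            lactate_time = labs$time_s[j],
                            lactate_value = labs$lactate[j]),
                       class = "shock_event"))
    }
  }
  NULL
}

#' @export
print.shock_event <- function(x, ...) {
  cat(sprintf(
    "<shock_event> onset %.0f s; episode [%.0f, %.0f); lactate %.1f @ %+.1f h\n",
    x$onset, x$episode_start, x$episode_end, x$lactate_value,
    (x$lactate_time - x$onset) / 3600))
  invisible(x)
}

#' Build self-controlled analysis windows
#'
#' One 30-minute observation window ending one hour before the event onset
#' (label 1), and one 30-minute within-patient control window (label 0):
#' scenario 1 places it flush against a 24-hour washout before the onset;
#' when that is not inside the record, scenario 2 places it after a 7-day
#' washout following the event. Only windows fully inside the record are
#' returned; windows never overlap the 1-hour pre-onset blackout.
#'
#' @param event A `shock_event`.
#' @param record The patient's [waveform_record()].
#' @param scenario_preference `"1"` (default) or `"2"`: which control
#'   placement to try first when both are in-record.
#' @return Data frame with `patient_id`, `role`, `scenario`, `start`,
#'   `end`, `label`; the control row is absent when neither scenario fits.
#' @export
build_windows <- function(event, record, scenario_preference = c("1", "2")) {
  scenario_preference <- match.arg(scenario_preference)
  stopifnot(inherits(event, "shock_event"))
  onset <- event$onset
  dur <- record_duration(record)
  win <- data.frame(patient_id = record$patient_id, role = "observation",
                    scenario = "none", start = onset - 90 * 60,
                    end = onset - 60 * 60, label = 1L)
  s1 <- c(onset - 24 * 3600 - 1800, onset - 24 * 3600)
  s2 <- c(onset + 7 * 86400, onset + 7 * 86400 + 1800)
  fits <- function(iv) iv[1] >= 0 && iv[2] <= dur
  order_try <- if (scenario_preference == "1") list(c("1", s1), c("2", s2))
               else list(c("2", s2), c("1", s1))
  for (cand in order_try) {
    iv <- as.numeric(cand[2:3])
    if (fits(iv)) {
      win <- rbind(win, data.frame(patient_id = record$patient_id,
                                   role = "control", scenario = cand[1],
                                   start = iv[1], end = iv[2], label = 0L))
      break
    }
  }
  if (win$start[1] < 0 || win$end[1] > dur)
    win <- win[win$role != "observation", , drop = FALSE]
  win
}

#' Label one record
#'
#' Full labeling chain: beat-wise MAP, episode detection, lactate
#' qualification and window construction.
#'
#' @inheritParams build_windows
#' @inheritParams qualify_shock_event
#' @return List with `event` (or `NULL`) and `windows` (possibly empty).
#' @export
label_record <- function(record, lactate_threshold = 2,
                         lactate_op = ">=", scenario_preference = "1") {
  ms <- tryCatch(beatwise_map_series(record), error = function(e) NULL)
  if (is.null(ms))
    return(list(event = NULL,
                windows = build_windows_empty(record$patient_id)))
  eps <- detect_hypotension_episodes(ms$map_1hz)
  ev <- qualify_shock_event(eps, record$labs, lactate_threshold,
                            lactate_op)
  if (is.null(ev))
    return(list(event = NULL,
                windows = build_windows_empty(record$patient_id)))
  list(event = ev,
       windows = build_windows(ev, record, scenario_preference))
}

build_windows_empty <- function(patient_id) {
  data.frame(patient_id = character(0), role = character(0),
             scenario = character(0), start = numeric(0), end = numeric(0),
             label = integer(0))
}

#' Apply cohort exclusions
#'
#' Exclusion rules, applied in order with the first triggered reason
#' logged per patient: any of the four waveform channels missing; no
#' qualifying shock event; less than 90 minutes of pre-onset data; more
#' than `max_missing` invalid samples in any channel of any used window;
#' no feasible control window.
#'
#' @param cohort List of per-patient lists with `record`, `event`,
#'   `windows` (as from [label_record()]).
#' @param max_missing Missing-fraction threshold (default 0.5).
#' @param min_pre_onset_min Required pre-onset data span (minutes).
#' @return List with `included` (subset of `cohort`) and `log` (data frame
#'   `patient_id`, `status`, `reason`).
#' @export
apply_exclusions <- function(cohort, max_missing = 0.5,
                             min_pre_onset_min = 90) {
  logs <- list(); keep <- logical(length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    id <- p$record$patient_id
    reason <- NA_character_
    missing_ch <- setdiff(.modalities, names(p$record$channels))
    if (length(missing_ch)) {
      reason <- paste0("missing channel: ", paste(missing_ch, collapse = ","))
    } else if (is.null(p$event)) {
      reason <- "no qualifying shock event"
    } else if (p$event$onset < min_pre_onset_min * 60) {
      reason <- sprintf("pre-onset data shorter than %d min",
                        min_pre_onset_min)
    } else {
      used <- p$windows
      for (w in seq_len(nrow(used))) {
        mf <- missing_fraction(p$record,
                               c(used$start[w], used$end[w]))
        if (any(mf > max_missing)) {
          reason <- sprintf("more than %d%% missing in %s window (%s)",
                            round(max_missing * 100), used$role[w],
                            names(mf)[which.max(mf)])
          break
        }
      }
      if (is.na(reason) && !any(used$role == "control"))
        reason <- "no feasible control window"
      if (is.na(reason) && !any(used$role == "observation"))
        reason <- "observation window outside record"
    }
    keep[i] <- is.na(reason)
    logs[[i]] <- data.frame(patient_id = id,
                            status = if (keep[i]) "included" else "excluded",
                            reason = if (keep[i]) "" else reason)
  }
  list(included = cohort[keep], log = do.call(rbind, logs))
}
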