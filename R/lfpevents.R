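#' Local field potential recording
#'
#' @param samples_mv voltage samples, mV.
#' @param sampling_interval_s sampling interval, s (> 0).
#' @return An `lfp_recording`: list with `mv`, `sampling_interval_s`,
#'   `duration_s`, `filtered` flag.
#' @export
lfp_recording <- function(samples_mv, sampling_interval_s) {
  if (sampling_interval_s <= 0) stop("`sampling_interval_s` must be > 0")
  structure(list(mv = as.numeric(samples_mv),
                 sampling_interval_s = sampling_interval_s,
                 duration_s = length(samples_mv) * sampling_interval_s,
                 filtered = FALSE),
            class = "lfp_recording")
}

#' Band-pass filter an LFP recording
#'
#' Zero-phase (forward-backward) second-order Butterworth high-pass and
#' low-pass in cascade. The high-pass removes any DC offset, so detections
#' are invariant to constant shifts of the raw trace.
#'
#' @param rec an [lfp_recording()].
#' @param hp_hz high-pass corner, Hz.
#' @param lp_hz low-pass corner, Hz; must be below Nyquist.
#' @return The filtered recording.
#' @export
bandpass <- function(rec, hp_hz = 0.1, lp_hz = 1000) {
  stopifnot(inherits(rec, "lfp_recording"))
  fs <- 1 / rec$sampling_interval_s
  nyq <- fs / 2
  if (lp_hz >= nyq)
    stop("low-pass corner (", lp_hz, " Hz) must be below Nyquist (", nyq,
         " Hz); resample the recording or lower `lp_hz`")
  if (hp_hz <= 0 || hp_hz >= lp_hz) stop("need 0 < hp_hz < lp_hz")
  hp <- signal::butter(2, hp_hz / nyq, type = "high")
  lp <- signal::butter(2, lp_hz / nyq, type = "low")
  x <- signal::filtfilt(hp, rec$mv)
  rec$mv <- signal::filtfilt(lp, x)
  rec$filtered <- TRUE
  rec
}

#' Detect seizure-like LFP events
#'
#' An event is a maximal contiguous segment with the filtered signal
#' strictly below `amp_mv`, lasting strictly more than `min_dur_ms`; its
#' amplitude is the segment minimum. Segments closer than `merge_gap_ms`
#' are merged before the duration test.
#'
#' @param rec a band-pass filtered [lfp_recording()].
#' @param amp_mv threshold level, mV (negative).
#' @param min_dur_ms minimum duration, ms (strict).
#' @param merge_gap_ms merge gap, ms (default 0: no merging).
#' @return data.frame `(start_s, duration_ms, amplitude_mv)`.
#' @export
detect_lfp_events <- function(rec, amp_mv = -0.3, min_dur_ms = 100,
                              merge_gap_ms = 0) {
  stopifnot(inherits(rec, "lfp_recording"))
  dt <- rec$sampling_interval_s
  below <- rec$mv < amp_mv
  gap <- max(1L, as.integer(round(merge_gap_ms / 1000 / dt)))
  runs <- run_bounds(below, min_gap = gap)
  if (nrow(runs) == 0L)
    return(data.frame(start_s = numeric(0), duration_ms = numeric(0),
                      amplitude_mv = numeric(0)))
  dur_ms <- (runs$end - runs$start + 1L) * dt * 1000
  keep <- dur_ms > min_dur_ms
  runs <- runs[keep, , drop = FALSE]
  dur_ms <- dur_ms[keep]
  amp <- mapply(function(a, b) min(rec$mv[a:b]), runs$start, runs$end)
  data.frame(start_s = (runs$start - 1L) * dt,
             duration_ms = dur_ms,
             amplitude_mv = as.numeric(amp))
}

#' Summary statistics of detected LFP events
#'
#' @param events data.frame from [detect_lfp_events()].
#' @param duration_s recording length, s (> 0).
#' @return list `(count, rate_per_min, mean_abs_amplitude_mv)`; the mean
#'   amplitude is `NA` when there are no events.
#' @export
lfp_stats <- function(events, duration_s) {
  if (duration_s <= 0) stop("duration must be > 0")
  n <- nrow(events)
  list(count = n,
       rate_per_min = n / (duration_s / 60),
       mean_abs_amplitude_mv = if (n > 0) mean(abs(events$amplitude_mv))
       else NA_real_)
}
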