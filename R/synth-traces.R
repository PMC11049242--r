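#' Ground truth for a synthetic calcium trace
#'
#' @param event_onsets strictly increasing frame indices (1-based).
#' @param event_peak_dff peak dF/F0 of each transient (> 0), expressed
#'   relative to the local (pre-event) baseline.
#' @param baseline baseline fluorescence, intensity units.
#' @param drift_slope linear drift, intensity units per frame.
#' @param noise_sigma Gaussian noise SD, intensity units.
#' @param decay_tau transient decay constant, frames (instant rise,
#'   exponential decay).
#' @return A `calcium_truth` object.
#' @export
calcium_truth <- function(event_onsets = integer(0),
                          event_peak_dff = numeric(0),
                          baseline = 100, drift_slope = 0, noise_sigma = 0,
                          decay_tau = 10) {
  if (length(event_onsets) != length(event_peak_dff))
    stop("onsets and peak amplitudes must have equal length")
  if (length(event_onsets) > 1 && any(diff(event_onsets) <= 0))
    stop("`event_onsets` must be strictly increasing")
  if (any(event_peak_dff <= 0)) stop("`event_peak_dff` must be > 0")
  if (baseline <= 0) stop("`baseline` must be > 0")
  structure(list(event_onsets = as.integer(event_onsets),
                 event_peak_dff = as.numeric(event_peak_dff),
                 baseline = baseline, drift_slope = drift_slope,
                 noise_sigma = noise_sigma, decay_tau = decay_tau),
            class = "calcium_truth")
}

#' Generate a synthetic whole-field fluorescence trace
#'
#' Baseline + linear drift + Gaussian noise + calcium transients (instant
#' rise, exponential decay) at the truth onsets. Each transient's peak
#' equals `peak_dff` times the local noiseless baseline at its onset;
#' overlapping transients sum. Negative intensities are clipped at 0 with a
#' warning.
#'
#' @param n_frames number of frames (> 0).
#' @param truth a [calcium_truth()].
#' @param seed integer seed.
#' @param frame_interval_s seconds per frame (default 1).
#' @return A `fluor_trace` (see [fluor_trace()]) with the realized truth in
#'   attribute `"truth"`.
#' @export
gen_calcium_trace <- function(n_frames, truth = calcium_truth(), seed = 1L,
                              frame_interval_s = 1) {
  if (n_frames <= 0) stop("`n_frames` must be > 0")
  if (length(truth$event_onsets) && max(truth$event_onsets) > n_frames)
    stop("event onsets exceed `n_frames`")
  set.seed(seed)
  t_frames <- seq_len(n_frames)
  base <- truth$baseline + truth$drift_slope * (t_frames - 1)
  raw <- base + rnorm(n_frames, 0, truth$noise_sigma)
  for (k in seq_along(truth$event_onsets)) {
    on <- truth$event_onsets[k]
    amp <- truth$event_peak_dff[k] * base[on]
    idx <- on:n_frames
    raw[idx] <- raw[idx] + amp * exp(-(idx - on) / truth$decay_tau)
  }
  if (any(raw < 0)) {
    warning("negative intensities clipped at 0")
    raw[raw < 0] <- 0
  }
  structure(fluor_trace(raw, frame_interval_s = frame_interval_s),
            truth = truth)
}

#' Ground truth for a synthetic LFP trace
#'
#' @param event_starts event start times, s.
#' @param event_durations event durations, ms (> 0).
#' @param event_amplitudes event depths, mV (negative).
#' @param noise_sigma Gaussian noise SD, mV.
#' @return An `lfp_truth` object; specified events must not overlap.
#' @export
lfp_truth <- function(event_starts = numeric(0), event_durations = numeric(0),
                      event_amplitudes = numeric(0), noise_sigma = 0) {
  n <- length(event_starts)
  if (length(event_durations) != n || length(event_amplitudes) != n)
    stop("event fields must have equal length")
  if (any(event_durations <= 0)) stop("durations must be > 0")
  if (any(event_amplitudes >= 0)) stop("amplitudes must be negative (mV)")
  if (n > 1) {
    o <- order(event_starts)
    ends <- event_starts[o] + event_durations[o] / 1000
    if (any(event_starts[o][-1] < ends[-n]))
      stop("specified events overlap")
  }
  structure(list(event_starts = event_starts,
                 event_durations = event_durations,
                 event_amplitudes = event_amplitudes,
                 noise_sigma = noise_sigma),
            class = "lfp_truth")
}

#' Generate a synthetic LFP voltage trace
#'
#' Zero-mean Gaussian noise plus smooth-edged downward deflections
#' (half-cosine onset/offset ramps) of the specified depth and duration.
#'
#' @param duration_s recording duration, s; must cover all events.
#' @param sampling_interval_s sampling interval, s (default 1 ms; detectors
#'   are sampling-rate-agnostic).
#' @param truth an [lfp_truth()].
#' @param seed integer seed.
#' @param edge_ms half-cosine ramp duration at each event edge, ms.
#' @return An `lfp_recording` (see [lfp_recording()]) with the truth in
#'   attribute `"truth"`.
#' @export
gen_lfp <- function(duration_s, sampling_interval_s = 1e-3,
                    truth = lfp_truth(), seed = 1L, edge_ms = 5) {
  if (length(truth$event_starts) &&
      any(truth$event_starts + truth$event_durations / 1000 > duration_s))
    stop("`duration_s` must cover all events")
  set.seed(seed)
  n <- round(duration_s / sampling_interval_s)
  t <- (seq_len(n) - 1) * sampling_interval_s
  v <- rnorm(n, 0, truth$noise_sigma)
  edge <- edge_ms / 1000
  for (k in seq_along(truth$event_starts)) {
    s0 <- truth$event_starts[k]
    dur <- truth$event_durations[k] / 1000
    e <- min(edge, dur / 2)
    idx <- which(t >= s0 & t < s0 + dur)
    tt <- t[idx] - s0
    w <- rep(1, length(idx))
    w[tt < e] <- 0.5 * (1 - cos(pi * tt[tt < e] / e))
    tail_t <- dur - tt
    w[tail_t < e] <- 0.5 * (1 - cos(pi * tail_t[tail_t < e] / e))
    v[idx] <- v[idx] + truth$event_amplitudes[k] * w
  }
  structure(lfp_recording(v, sampling_interval_s), truth = truth)
}

#' Generate a piecewise-constant-speed 2D trajectory
#'
#' A random-heading walk whose per-step displacement is exactly
#' `speed * dt` within each segment, emulating larva centroid tracking.
#'
#' @param segments list of `c(duration_s, speed_mm_s)` pairs (or a 2-column
#'   matrix); speeds must be >= 0.
#' @param dt_s sampling interval, s (> 0).
#' @param seed integer seed.
#' @param turn_sd SD of the per-step heading change, radians.
#' @return data.frame `(t_s, x_mm, y_mm)` starting at the origin, with the
#'   per-segment plan in attribute `"truth"`.
#' @export
gen_trajectory <- function(segments, dt_s = 1, seed = 1L, turn_sd = 0.4) {
  if (is.matrix(segments)) segments <- asplit(segments, 1)
  if (length(segments) == 0) stop("`segments` must be non-empty")
  if (dt_s <= 0) stop("`dt_s` must be > 0")
  seg <- do.call(rbind, lapply(segments, function(s) {
    if (length(s) != 2) stop("each segment is c(duration_s, speed_mm_s)")
    s
  }))
  if (any(seg[, 2] < 0)) stop("speeds must be >= 0")
  set.seed(seed)
  n_steps <- round(seg[, 1] / dt_s)
  speed <- rep(seg[, 2], n_steps)
  n <- length(speed)
  heading <- cumsum(c(runif(1, 0, 2 * pi), rnorm(n - 1, 0, turn_sd)))
  dx <- speed * dt_s * cos(heading)
  dy <- speed * dt_s * sin(heading)
  out <- data.frame(t_s = seq(0, by = dt_s, length.out = n + 1),
                    x_mm = c(0, cumsum(dx)), y_mm = c(0, cumsum(dy)))
  structure(out, truth = data.frame(duration_s = seg[, 1],
                                    speed_mm_s = seg[, 2]))
}
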