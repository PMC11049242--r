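test_that("band-pass rejects DC and preserves the passband", {
  fs <- 250
  n <- 600 * fs
  const <- lfp_recording(rep(5, n), 1 / fs)
  f <- bandpass(const, 0.1, 100)
  mid <- f$mv[(60 * fs):(540 * fs)]
  expect_lt(max(abs(mid)), 1e-6 * 5)
  t <- (0:(n - 1)) / fs
  sine10 <- bandpass(lfp_recording(sin(2 * pi * 10 * t), 1 / fs), 0.1, 100)
  amp10 <- max(abs(sine10$mv[(60 * fs):(540 * fs)]))
  expect_gte(amp10, 0.95)
  expect_lte(amp10, 1.0 + 1e-6)
  slow <- bandpass(lfp_recording(sin(2 * pi * 0.01 * t), 1 / fs), 0.1, 100)
  expect_lt(max(abs(slow$mv[(100 * fs):(500 * fs)])), 0.2)
  expect_error(bandpass(const, 0.1, 200), "Nyquist")
  expect_error(bandpass(const, -1, 100), "hp_hz")
})

test_that("detection respects the amplitude and duration boundaries", {
  fs <- 1250
  mk <- function(amp, dur_ms)
    bandpass(gen_lfp(60, 1 / fs, lfp_truth(30, dur_ms, amp), seed = 1),
             0.1, 500)
  ok <- detect_lfp_events(mk(-0.5, 200))
  expect_equal(nrow(ok), 1)
  expect_equal(ok$amplitude_mv, -0.5, tolerance = 0.1)
  expect_gt(ok$duration_ms, 100)
  expect_equal(ok$start_s, 30, tolerance = 0.05)
  expect_equal(nrow(detect_lfp_events(mk(-0.5, 50))), 0)
  expect_equal(nrow(detect_lfp_events(mk(-0.2, 200))), 0)
  flat <- bandpass(lfp_recording(rep(0, 10 * fs), 1 / fs), 0.1, 500)
  expect_equal(nrow(detect_lfp_events(flat)), 0)
})

test_that("detections are invariant to a DC offset of the raw trace", {
  fs <- 1250
  truth <- lfp_truth(c(30, 90, 150), c(200, 300, 150), c(-0.5, -0.8, -0.4),
                     noise_sigma = 0.05)
  rec <- gen_lfp(200, 1 / fs, truth, seed = 12)
  ev0 <- detect_lfp_events(bandpass(rec, 0.1, 500))
  shifted <- rec
  shifted$mv <- shifted$mv + 7
  ev7 <- detect_lfp_events(bandpass(shifted, 0.1, 500))
  expect_equal(nrow(ev7), nrow(ev0))
  expect_equal(ev7$start_s, ev0$start_s, tolerance = 1e-6)
  # amplitudes agree up to the high-pass edge transient of the DC step
  expect_equal(ev7$amplitude_mv, ev0$amplitude_mv, tolerance = 1e-3)
})

test_that("stricter thresholds never increase the event count", {
  # on noiseless unimodal deflections the rule is exactly monotone in both
  # the amplitude and the duration threshold
  fs <- 1250
  set.seed(3)
  truth <- lfp_truth(seq(20, 560, by = 60),
                     runif(10, 120, 500), runif(10, -0.9, -0.35))
  rec <- bandpass(gen_lfp(600, 1 / fs, truth, seed = 3), 0.1, 500)
  amps <- c(-0.25, -0.3, -0.4, -0.6)
  counts_a <- vapply(amps, function(a)
    nrow(detect_lfp_events(rec, amp_mv = a)), numeric(1))
  expect_true(all(diff(counts_a) <= 0))
  durs <- c(50, 100, 200, 400)
  counts_d <- vapply(durs, function(d)
    nrow(detect_lfp_events(rec, min_dur_ms = d)), numeric(1))
  expect_true(all(diff(counts_d) <= 0))
})

test_that("qualifying deflections are recalled in noise", {
  fs <- 1250
  hits <- 0; total <- 0; fp <- 0; minutes <- 0
  for (i in 1:4) {
    set.seed(i)
    starts <- sort(runif(15, 10, 560))
    while (any(diff(starts) < 2))
      starts <- sort(runif(15, 10, 560))
    truth <- lfp_truth(starts, runif(15, 150, 600), runif(15, -1, -0.4),
                       noise_sigma = 0.05)
    rec <- bandpass(gen_lfp(600, 1 / fs, truth, seed = 40 + i), 0.1, 500)
    # 20 ms merge gap: debounce for noise dips above threshold mid-event
    ev <- detect_lfp_events(rec, merge_gap_ms = 20)
    ends <- starts + truth$event_durations / 1000
    matched <- vapply(seq_along(starts), function(k)
      any(ev$start_s < ends[k] &
            ev$start_s + ev$duration_ms / 1000 > starts[k]), logical(1))
    is_fp <- !vapply(seq_len(nrow(ev)), function(j)
      any(ev$start_s[j] < ends & ev$start_s[j] +
            ev$duration_ms[j] / 1000 > starts), logical(1))
    hits <- hits + sum(matched); total <- total + 15
    fp <- fp + sum(is_fp); minutes <- minutes + 10
  }
  expect_gte(hits / total, 0.95)
  expect_lte(fp / (minutes / 10), 1)
})

test_that("lfp summary statistics are plain arithmetic", {
  s0 <- lfp_stats(data.frame(start_s = numeric(0), duration_ms = numeric(0),
                             amplitude_mv = numeric(0)), 3600)
  expect_equal(s0$count, 0)
  expect_equal(s0$rate_per_min, 0)
  expect_true(is.na(s0$mean_abs_amplitude_mv))
  ev <- data.frame(start_s = 1:28, duration_ms = 200,
                   amplitude_mv = rep(c(-0.4, -0.6), 14))
  s <- lfp_stats(ev, 3600)
  expect_equal(s$rate_per_min, 28 / 60, tolerance = 1e-12)
  expect_equal(s$mean_abs_amplitude_mv, 0.5)
  expect_error(lfp_stats(ev, 0), "duration")
})
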