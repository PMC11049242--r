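test_that("dF/F0 follows the global-mean formula", {
  d <- compute_dff(fluor_trace(c(90, 110)))
  expect_equal(d$dff, c(-0.1, 0.1))
  const <- compute_dff(fluor_trace(rep(37, 50)))
  expect_true(all(const$dff == 0))
  set.seed(1)
  raw <- runif(500, 50, 150)
  tr <- compute_dff(fluor_trace(raw))
  expect_lt(abs(sum(tr$dff)), 1e-9)
  # multiplicative gain invariance is exact up to float round-off
  tr2 <- compute_dff(fluor_trace(3.7 * raw))
  expect_equal(tr$dff, tr2$dff, tolerance = 1e-12)
  expect_error(compute_dff(fluor_trace(rep(0, 10))), "zero")
})

test_that("drift correction flattens a linear ramp", {
  ramp <- fluor_trace(100 + 0.01 * (0:2399))
  rc <- correct_drift(ramp)
  expect_lt(max(abs(rc$dff)), 0.005)
  expect_warning(correct_drift(fluor_trace(rep(100, 20)), window_s = 500),
                 "window")
})

test_that("drift correction leaves drift-free event calls unchanged", {
  tr0 <- calcium_truth(event_onsets = c(200, 600, 1000, 1400, 1800),
                       event_peak_dff = rep(0.1, 5))
  g <- gen_calcium_trace(2400, tr0, seed = 6)
  ev_plain <- detect_events(compute_dff(g))
  ev_corr <- detect_events(correct_drift(g))
  expect_equal(nrow(ev_plain), 5)
  expect_equal(ev_corr$onset_frame, ev_plain$onset_frame, tolerance = 0)
})

test_that("events are maximal threshold runs with run-max amplitudes", {
  tr <- fluor_trace(c(rep(100, 95), rep(115, 5)))
  ev <- detect_events(compute_dff(tr))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_frame, 96)
  expect_equal(ev$duration_frames, 5)
  expect_equal(ev$amplitude, max(compute_dff(tr)$dff))
  none <- detect_events(compute_dff(fluor_trace(rep(5, 60))))
  expect_equal(nrow(none), 0)
  # runs separated by less than min_separation merge
  raw <- rep(100, 60)
  raw[c(20:23, 26:29)] <- 115
  t2 <- compute_dff(fluor_trace(raw))
  expect_equal(nrow(detect_events(t2)), 2)
  expect_equal(nrow(detect_events(t2, min_separation_frames = 4)), 1)
  expect_error(detect_events(fluor_trace(raw)), "dff")
})

test_that("raising the threshold never increases the event count", {
  # strict monotonicity is a property of unimodal excursions: each noiseless
  # transient crosses any threshold at most once on the way up, so a higher
  # threshold can only drop events, never split them
  set.seed(9)
  for (i in 1:10) {
    g <- gen_calcium_trace(
      1200,
      calcium_truth(event_onsets = sort(sample(seq(30, 1100, by = 40), 8)),
                    event_peak_dff = runif(8, 0.05, 0.15)),
      seed = 70 + i)
    tr <- compute_dff(g)
    counts <- vapply(c(0.02, 0.04, 0.06, 0.1),
                     function(th) nrow(detect_events(tr, th)), numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("detector recovers injected transients on noisy drifting traces", {
  hits <- 0; total <- 0; fp <- 0
  for (i in 1:6) {
    set.seed(i)
    onsets <- sort(sample(seq(50, 2300, by = 60), 20))
    tr0 <- calcium_truth(event_onsets = onsets,
                         event_peak_dff = rep(0.08, 20),
                         noise_sigma = 0.5, drift_slope = 0.004)
    g <- gen_calcium_trace(2400, tr0, seed = 300 + i)
    ev <- detect_events(correct_drift(g), 0.04, min_separation_frames = 5)
    matched <- vapply(onsets, function(o)
      any(ev$peak_frame >= o & ev$peak_frame <= o + 40), logical(1))
    hits <- hits + sum(matched); total <- total + 20
    fp <- fp + sum(!vapply(ev$peak_frame, function(p)
      any(p >= onsets & p <= onsets + 40), logical(1)))
  }
  expect_gte(hits / total, 0.95)
  expect_lte(fp / 6, 1)
})

test_that("event statistics handle empty and simple cases", {
  none <- detect_events(compute_dff(fluor_trace(rep(5, 10))))
  s0 <- event_stats(none, 3600)
  expect_equal(s0$count, 0)
  expect_equal(s0$rate_per_min, 0)
  expect_true(is.na(s0$mean_amplitude))
  ev <- data.frame(amplitude = c(0.05, 0.15))
  s <- event_stats(ev, 3600)
  expect_equal(s$rate_per_min, 2 / 60)
  expect_equal(s$mean_amplitude, 0.10)
  s30 <- event_stats(ev[rep(1, 30), , drop = FALSE], 3600)
  expect_equal(s30$rate_per_min, 0.5)
  expect_error(event_stats(ev, 0), "duration")
})
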