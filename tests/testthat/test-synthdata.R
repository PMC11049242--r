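test_that("microglia generator is deterministic and honours its truth", {
  tr <- shape_truth(6, c(20, 25, 30))
  a <- gen_microglia(tr, seed = 42)
  b <- gen_microglia(tr, seed = 42)
  expect_identical(a$volume$voxels, b$volume$voxels)
  expect_identical(a$truth$realized_lengths, b$truth$realized_lengths)
  expect_false(identical(a$volume$voxels,
                         gen_microglia(tr, seed = 43)$volume$voxels))
  # realized lengths equal polyline arc lengths (unclipped case)
  expect_equal(a$truth$realized_lengths, c(20, 25, 30), tolerance = 1e-12)
  expect_equal(a$truth$total_length, 75)
})

test_that("degenerate amoeboid truth gives a single ball component", {
  g <- gen_microglia(shape_truth(6), seed = 1)
  expect_equal(g$truth$n_processes, 0L)
  lab <- gliaquant:::cc_label_3d(as.vector(g$volume$voxels > 0),
                                 dim(g$volume$voxels))
  expect_equal(max(lab), 1L)
  # voxel count close to the continuum ball volume
  expect_equal(sum(g$volume$voxels > 0), 4 / 3 * pi * 6^3, tolerance = 0.05)
})

test_that("a branched cell stays 26-connected and rejects too-small grids", {
  set.seed(7)
  tr <- shape_truth(6, runif(8, 18, 28), has_secondary_branches = TRUE)
  g <- gen_microglia(tr, seed = 7)
  lab <- gliaquant:::cc_label_3d(as.vector(g$volume$voxels > 0),
                                 dim(g$volume$voxels))
  expect_equal(max(lab), 1L)
  expect_error(gen_microglia(tr, seed = 7, dims = c(20L, 20L, 20L)),
               "grid too small")
  expect_error(gen_microglia(tr, voxel_size = c(1, -1, 1)), "voxel sizes")
})

test_that("shape truth validates its invariants", {
  expect_error(shape_truth(0, c(10)), "soma_radius")
  expect_error(shape_truth(5, c(10, -2)), "> 0")
  expect_error(shape_truth(5, c(10), n_processes = 3), "n_processes")
})

test_that("population generator validates the mix and reproduces it", {
  expect_error(gen_population(c(branched = 0.4, amoeboid = 0.5), 10),
               "sum to 1")
  expect_error(gen_population(
    c(branched = 0.1, amoeboid = 0.3, transitional = 0.6), 0), "n")
  mix <- c(branched = 0.1, amoeboid = 0.3, transitional = 0.6)
  p1 <- gen_population(mix, 25, seed = 3)
  p2 <- gen_population(mix, 25, seed = 3)
  expect_identical(attr(p1, "class_counts"), attr(p2, "class_counts"))
  expect_identical(p1[[5]]$volume$voxels, p2[[5]]$volume$voxels)
  expect_equal(sum(attr(p1, "class_counts")), 25)
})

test_that("class-conditional truths satisfy their intended criteria", {
  # applying the classifier to analytic truth morphologies recovers the
  # intended class for (at least) 99% of draws
  mix <- c(branched = 1 / 3, amoeboid = 1 / 3, transitional = 1 / 3)
  set.seed(11)
  ok <- replicate(300, {
    cls <- sample(names(mix), 1)
    tr <- gliaquant:::draw_class_truth(cls)
    tr$tube_radius <- 1.5
    classify_cell(expected_morphology(tr))$label == cls
  })
  expect_gte(mean(ok), 0.99)
})

test_that("calcium trace generator matches its analytic skeleton", {
  flat <- gen_calcium_trace(100, calcium_truth(baseline = 80), seed = 1)
  expect_true(all(flat$raw == 80))
  tr <- calcium_truth(event_onsets = c(10, 30, 50, 70, 90),
                      event_peak_dff = rep(0.1, 5))
  g <- gen_calcium_trace(100, tr, seed = 2)
  # five local maxima above baseline, at the onsets (instant rise)
  peaks <- which(diff(sign(diff(g$raw))) < 0) + 1L
  expect_equal(sum(g$raw[peaks] > 100 + 1e-9), 5)
  expect_equal(g$raw[10], 100 * 1.1, tolerance = 1e-12)
  expect_identical(gen_calcium_trace(100, tr, seed = 2)$raw, g$raw)
  expect_warning(
    gen_calcium_trace(50, calcium_truth(baseline = 1, noise_sigma = 10),
                      seed = 1), "clipped")
  expect_error(gen_calcium_trace(0, tr), "n_frames")
})

test_that("lfp generator produces calibrated deflections", {
  z <- gen_lfp(10, 1e-3, lfp_truth(), seed = 1)
  expect_true(all(z$mv == 0))
  one <- gen_lfp(10, 1e-3,
                 lfp_truth(2, 200, -0.5), seed = 1)
  expect_equal(min(one$mv), -0.5, tolerance = 1e-9)
  expect_true(all(one$mv <= 0))
  expect_identical(gen_lfp(10, 1e-3, lfp_truth(2, 200, -0.5), seed = 1)$mv,
                   one$mv)
  expect_error(lfp_truth(c(1, 1.05), c(100, 100), c(-0.5, -0.5)), "overlap")
  expect_error(gen_lfp(1, 1e-3, lfp_truth(0.9, 200, -0.5)), "cover")
})

test_that("trajectory generator walks at exactly the segment speeds", {
  tj <- gen_trajectory(list(c(60, 10)), dt_s = 1, seed = 4)
  steps <- sqrt(diff(tj$x_mm)^2 + diff(tj$y_mm)^2)
  expect_length(steps, 60)
  expect_equal(steps, rep(10, 60), tolerance = 1e-12)
  still <- gen_trajectory(list(c(10, 0)), dt_s = 1, seed = 4)
  expect_true(all(diff(still$x_mm) == 0) && all(diff(still$y_mm) == 0))
  mixed <- gen_trajectory(list(c(30, 2), c(45, 5)), dt_s = 0.5, seed = 9)
  path <- sum(sqrt(diff(mixed$x_mm)^2 + diff(mixed$y_mm)^2))
  expect_equal(path, 30 * 2 + 45 * 5, tolerance = 1e-9)
  expect_error(gen_trajectory(list()), "non-empty")
  expect_error(gen_trajectory(list(c(10, -1))), "speeds")
})

test_that("synthetic objects round-trip through their file formats", {
  td <- withr::local_tempdir()
  g <- gen_microglia(shape_truth(5, c(15, 20)), seed = 2)
  skip_if_not_installed("tiff")
  p <- file.path(td, "cell.tif")
  write_volume_tiff(g$volume, p)
  back <- read_volume_tiff(p)
  expect_identical(back$voxels, g$volume$voxels)
  expect_equal(back$voxel_size, g$volume$voxel_size)
  write_truth_json(g$truth, file.path(td, "cell.json"))
  j <- jsonlite::read_json(file.path(td, "cell.json"))
  expect_equal(j$soma_radius, 5)
  tr <- gen_calcium_trace(50, calcium_truth(), seed = 1)
  write_trace_csv(tr, file.path(td, "tr.csv"))
  rt <- read_fluor_csv(file.path(td, "tr.csv"))
  expect_equal(rt$raw, tr$raw)
  rec <- gen_lfp(2, 1e-3, lfp_truth(0.5, 100, -0.4), seed = 1)
  write_trace_csv(rec, file.path(td, "lfp.csv"))
  rl <- read_lfp_csv(file.path(td, "lfp.csv"))
  expect_equal(rl$mv, rec$mv)
  expect_equal(rl$sampling_interval_s, 1e-3)
})
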