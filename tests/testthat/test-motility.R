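test_that("track summaries follow their definitions", {
  sq <- data.frame(t_s = seq(0, 160, by = 40),
                   x = c(0, 10, 10, 0, 0), y = c(0, 0, 10, 10, 0))
  s <- summarize_track(sq)
  expect_equal(s$displacement_um, 0)
  expect_equal(s$path_length_um, 40)
  expect_equal(s$mean_speed_um_min, 15)

  line <- data.frame(t_s = c(0, 30, 60), x = c(0, 15, 30), y = 0)
  sl <- summarize_track(line)
  expect_equal(sl$displacement_um, 30)
  expect_equal(sl$path_length_um, 30)
  expect_error(summarize_track(data.frame(t_s = 0, x = 0, y = 0)),
               "2 samples")
  expect_error(summarize_track(data.frame(t_s = c(0, 0), x = 0:1, y = 0)),
               "increasing")
})

test_that("path length dominates displacement on random walks", {
  set.seed(4)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    tr <- data.frame(t_s = seq_len(n) * 40,
                     x = cumsum(rnorm(n, 0, 3)),
                     y = cumsum(rnorm(n, 0, 3)),
                     z = cumsum(rnorm(n, 0, 1)))
    s <- summarize_track(tr)
    expect_gte(s$path_length_um + 1e-12, s$displacement_um)
  }
})

test_that("halving dt doubles mean speed but not displacement", {
  tr1 <- data.frame(t_s = (0:10) * 40, x = 0:10, y = 0)
  tr2 <- data.frame(t_s = (0:10) * 20, x = 0:10, y = 0)
  s1 <- summarize_track(tr1)
  s2 <- summarize_track(tr2)
  expect_equal(s2$displacement_um, s1$displacement_um)
  expect_equal(s2$mean_speed_um_min, 2 * s1$mean_speed_um_min)
})

test_that("linking keeps stationary and steadily moving cells intact", {
  pts <- matrix(c(0, 0, 50, 80, 100, 10), 3, 2, byrow = TRUE)
  frames <- rep(list(pts), 90)
  tracks <- link_centroids(frames, max_step = 20, dt = 40)
  expect_length(tracks, 3)
  expect_true(all(vapply(tracks, function(tr) attr(tr, "complete"),
                         logical(1))))
  expect_true(all(vapply(tracks, function(tr)
    summarize_track(tr)$displacement_um, numeric(1)) == 0))

  mover <- lapply(0:19, function(i) matrix(c(5 * i, 0), 1, 2))
  mt <- link_centroids(mover, max_step = 20, dt = 40)
  expect_length(mt, 1)
  expect_equal(summarize_track(mt[[1]])$path_length_um, 5 * 19)
})

test_that("links longer than max_step terminate tracks instead of jumping", {
  # both centroids would need 30 um steps; only the 0-length link survives
  frames <- list(matrix(c(0, 0, 30, 0), 2, 2, byrow = TRUE),
                 matrix(c(30, 0, 60, 0), 2, 2, byrow = TRUE))
  tracks <- link_centroids(frames, max_step = 20, dt = 40)
  lens <- vapply(tracks, nrow, integer(1))
  expect_equal(sort(lens), c(1L, 1L, 2L))
  two <- tracks[[which(lens == 2)]]
  expect_equal(summarize_track(two)$path_length_um, 0)
  # empty frames end tracks without error
  fr2 <- list(matrix(c(0, 0), 1, 2), matrix(numeric(0), 0, 2),
              matrix(c(0, 0), 1, 2))
  t2 <- link_centroids(fr2, max_step = 20, dt = 40)
  expect_length(t2, 2)
  expect_error(link_centroids(frames[1]), "2 frames")
})

test_that("fragments below the span filter are excluded from summaries", {
  frames <- c(lapply(1:10, function(i) matrix(c(i, 0), 1, 2)),
              lapply(1:10, function(i)
                matrix(c(10 + i, 0, 200, 200), 2, 2, byrow = TRUE)))
  tracks <- link_centroids(frames, max_step = 5, dt = 40)
  tab_all <- summarize_tracks(tracks, min_span_frac = 0)
  tab_strict <- summarize_tracks(tracks, min_span_frac = 0.8)
  expect_gt(nrow(tab_all), nrow(tab_strict))
})

test_that("labeled-volume centroids land at the cell centres", {
  two <- array(0L, c(30, 12, 12))
  two[2:9, 3:10, 3:10] <- 1L     # centre (5.5, 6.5, 6.5) voxel index
  two[20:27, 3:10, 3:10] <- 2L   # centre (23.5, 6.5, 6.5)
  cen <- centroids_of(labeled_volume(two, 2))
  expect_equal(unname(cen[1, ]), c(5.0, 6.0, 6.0) * 2)
  expect_equal(unname(cen[2, ]), c(23.0, 6.0, 6.0) * 2)
})

test_that("generator speeds are recovered from centroid streams", {
  for (sp in c(2, 5, 9)) {
    tj <- gen_trajectory(list(c(120, sp)), dt_s = 1, seed = 20 + sp)
    tr <- data.frame(t_s = tj$t_s, x = tj$x_mm, y = tj$y_mm)
    s <- summarize_track(tr)
    expect_equal(s$mean_speed_um_min, sp * 60, tolerance = 0.01)
  }
})
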