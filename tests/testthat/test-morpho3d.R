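test_that("sphericity hits its closed-form limits", {
  ball <- digital_ball(20)
  m <- measure_cell(ball)
  expect_gt(m$sphericity, 0.97)
  expect_lt(m$sphericity, 1.03)
  expect_equal(m$volume, 4 / 3 * pi * 20^3, tolerance = 0.01)
  expect_equal(m$surface_area, 4 * pi * 20^2, tolerance = 0.03)
  expect_equal(m$n_processes, 0L)
  expect_equal(m$total_length, 0)
  expect_equal(m$ramification_index, 0)

  cube <- digital_cube(30)
  mc <- measure_cell(cube)
  expect_equal(mc$volume, 27000)
  expect_equal(mc$sphericity, (pi / 6)^(1 / 3), tolerance = 0.05)
})

test_that("segmentation thresholds, labels and filters components", {
  expect_warning(z <- segment_cells(array(0, c(10, 10, 10)), 1), "empty")
  expect_length(z$cell_ids, 0)

  two <- array(0, c(40, 20, 20))
  g <- expand.grid(x = 1:40, y = 1:20, z = 1:20)
  d1 <- sqrt((g$x - 10)^2 + (g$y - 10)^2 + (g$z - 10)^2)
  d2 <- sqrt((g$x - 30)^2 + (g$y - 10)^2 + (g$z - 10)^2)
  two[d1 <= 5 | d2 <= 5] <- 100
  seg <- segment_cells(two, 1)
  expect_length(seg$cell_ids, 2)

  small <- array(0, c(12, 12, 12))
  small[5:8, 5:8, 5:7] <- 100  # 48 voxels < default min_voxels = 50
  expect_warning(s2 <- segment_cells(small, 1), "min_voxels")
  expect_length(s2$cell_ids, 0)
  expect_length(segment_cells(small, 1, min_voxels = 10)$cell_ids, 1)
})

test_that("skeleton recovers a straight process and a Y-shaped one", {
  straight <- tube_cell(5, list(rbind(c(5, 0, 0), c(35, 0, 0))))
  sk <- skeletonize_cell(straight$voxels > 0, 1)
  st <- process_stats(sk)
  expect_equal(st$n_processes, 1L)
  expect_equal(st$total_length, 30, tolerance = 2 / 30)
  expect_equal(st$ramification_index, 1)
  expect_equal(sk$soma_radius_um, 5, tolerance = 0.15)

  yfork <- tube_cell(5, list(
    rbind(c(5, 0, 0), c(25, 0, 0)),
    rbind(c(25, 0, 0), c(25 + 12 * cos(pi / 4), 12 * sin(pi / 4), 0)),
    rbind(c(25, 0, 0), c(25 + 12 * cos(pi / 4), -12 * sin(pi / 4), 0))))
  sky <- skeletonize_cell(yfork$voxels > 0, 1)
  sty <- process_stats(sky)
  expect_equal(sty$n_processes, 1L)
  expect_length(sky$terminal_nodes, 2)
  expect_equal(sty$ramification_index, 2)
  # bifurcation: Sholl count rises from 1 to 2 across the branch point
  sh <- sholl_profile(sky, r_step = 5, r_max = 50)
  expect_equal(sh$intersections[sh$radius_um == 20], 1L)
  expect_equal(sh$intersections[sh$radius_um == 30], 2L)
})

test_that("process stats follow their definitions on radial cells", {
  g <- radial_cell(5, 4, 25, seed = 3)
  m <- measure_cell(g$volume)
  expect_equal(m$n_processes, 4L)
  expect_equal(m$total_length, 100, tolerance = 0.1)
  expect_equal(m$mean_length, m$total_length / 4)
  expect_equal(m$ramification_index, 1)
  sk <- attr(m, "skeleton")
  # Sholl equals NP just above the soma radius, 0 beyond the reach
  sh <- sholl_profile(sk, r_step = 5, r_max = 60)
  expect_equal(sh$intersections[sh$radius_um == 10], 4L)
  expect_equal(sh$intersections[sh$radius_um == 25], 4L)
  expect_true(all(sh$intersections[sh$radius_um >= 40] == 0L))
  # empty skeleton: all zeros
  ball <- digital_ball(8)
  sh0 <- sholl_profile(skeletonize_cell(ball$voxels > 0, 1))
  expect_true(all(sh0$intersections == 0L))
})

test_that("measured morphology is scale-equivariant and rotation-robust", {
  set.seed(5)
  g <- gen_microglia(shape_truth(5.5, runif(6, 15, 22)), seed = 5)
  m1 <- measure_cell(g$volume)
  v2 <- labeled_volume(g$volume$voxels, 2)
  m2 <- measure_cell(v2)
  expect_equal(m2$volume, 8 * m1$volume, tolerance = 1e-12)
  expect_equal(m2$surface_area, 4 * m1$surface_area, tolerance = 0.02)
  expect_equal(m2$total_length, 2 * m1$total_length, tolerance = 0.02)
  expect_equal(m2$sphericity, m1$sphericity, tolerance = 0.02)
  expect_equal(m2$n_processes, m1$n_processes)

  rot <- labeled_volume(aperm(g$volume$voxels, c(2, 3, 1)), 1)
  mr <- measure_cell(rot)
  expect_equal(mr$volume, m1$volume)
  expect_equal(mr$sphericity, m1$sphericity, tolerance = 0.01)
  expect_lte(abs(mr$n_processes - m1$n_processes), 1)

  ball <- digital_ball(12)
  mb <- measure_cell(ball)
  mbr <- measure_cell(labeled_volume(aperm(ball$voxels, c(3, 1, 2)), 1))
  expect_identical(mbr$volume, mb$volume)
  expect_equal(mbr$sphericity, mb$sphericity, tolerance = 1e-9)
})

test_that("generator truth is recovered by the measurement chain", {
  set.seed(21)
  res <- lapply(1:15, function(i) {
    np <- sample(0:10, 1)
    tr <- shape_truth(runif(1, 5, 6.5),
                      if (np > 0) runif(np, 12, 30) else numeric(0))
    g <- gen_microglia(tr, seed = 400 + i)
    m <- measure_cell(g$volume)
    c(np_err = m$n_processes - np,
      tl_err = if (np > 0) abs(m$total_length - g$truth$total_length) /
        g$truth$total_length else abs(m$total_length) / 5)
  })
  res <- do.call(rbind, res)
  expect_gte(mean(abs(res[, "np_err"]) <= 1), 0.9)
  expect_gte(mean(res[, "tl_err"] <= 0.15), 0.9)
})

test_that("coexpression fraction counts reporter-positive cells", {
  three <- array(0L, c(36, 12, 12))
  three[2:9, 3:10, 3:10] <- 1L
  three[14:21, 3:10, 3:10] <- 2L
  three[26:33, 3:10, 3:10] <- 3L
  cells <- labeled_volume(three, 1)
  rep0 <- array(0, dim(three))
  expect_equal(as.numeric(coexpression_fraction(cells, rep0)), 0)
  rep1 <- rep0
  rep1[three == 2L] <- 100
  expect_equal(as.numeric(coexpression_fraction(cells, rep1)), 100 / 3,
               tolerance = 1e-9)
  repall <- rep0 + 50
  repall[three > 0L] <- 200
  expect_equal(as.numeric(coexpression_fraction(cells, repall)), 100)
  expect_error(coexpression_fraction(
    labeled_volume(array(0L, c(5, 5, 5)), 1), array(0, c(5, 5, 5))),
    "no cells")
  expect_error(coexpression_fraction(cells, array(0, c(2, 2, 2))), "shape")
})

test_that("measure_cell validates its cell id", {
  ball <- digital_ball(8)
  expect_error(measure_cell(ball, cell_id = 4), "not present")
  two <- ball$voxels
  two[1:2, 1:2, 1:2] <- 2L
  expect_error(measure_cell(labeled_volume(two, 1)), "supply")
})
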