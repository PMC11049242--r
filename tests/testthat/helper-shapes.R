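# Programmatic voxel fixtures: digital primitives with closed-form geometry
# and hand-built tube cells for skeleton oracles.

digital_ball <- function(radius_vox, vox = 1) {
  d <- 2L * ceiling(radius_vox) + 7L
  c0 <- (d + 1) / 2
  g <- expand.grid(x = 1:d, y = 1:d, z = 1:d)
  m <- array(sqrt((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2) <= radius_vox,
             c(d, d, d))
  labeled_volume(m, vox)
}

digital_cube <- function(side_vox, vox = 1) {
  d <- side_vox + 6L
  m <- array(FALSE, c(d, d, d))
  m[4:(3 + side_vox), 4:(3 + side_vox), 4:(3 + side_vox)] <- TRUE
  labeled_volume(m, vox)
}

# soma ball plus explicit tube polylines (vertex matrices in um, relative to
# the soma centre), rasterized like the synthetic generator
tube_cell <- function(soma_radius, polylines, tube_radius = 1.5,
                      half_extent = 40, vox = 1) {
  dims <- rep(2L * ceiling(half_extent / vox) + 1L, 3L)
  center <- dims / 2 * vox
  mask <- array(FALSE, dims)
  mask <- gliaquant:::stamp_points(mask, matrix(center, 1), soma_radius,
                                   rep(vox, 3))
  for (p in polylines) {
    pts <- gliaquant:::densify_polyline(sweep(p, 2, center, "+"), 0.45 * vox)
    mask <- gliaquant:::stamp_points(mask, pts, tube_radius, rep(vox, 3))
  }
  labeled_volume(mask, vox)
}

# perfectly radial unbranched cell via the generator with zero heading noise
radial_cell <- function(soma_radius, n_processes, length_um, seed = 1) {
  gen_microglia(shape_truth(soma_radius, rep(length_um, n_processes)),
                seed = seed, turn_sd = 0)
}

# literal predicate counting, independent of the classifier implementation
brute_force_label <- function(S, NP, TL, A, min_criteria = 3) {
  nb <- sum(c(S < 0.5, NP > 7, TL > 140, A > 2400))
  na_ <- sum(c(S > 0.7, NP < 3, TL < 60, A < 1500))
  if (nb >= min_criteria) "branched"
  else if (na_ >= min_criteria) "amoeboid"
  else "transitional"
}

random_morph_vectors <- function(n) {
  data.frame(S = runif(n, 0, 1.05),
             NP = sample(0:15, n, replace = TRUE),
             TL = runif(n, 0, 400),
             A = runif(n, 100, 5000))
}
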