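#' Ground-truth description of a synthetic microglial cell
#'
#' @param soma_radius soma radius, um (> 0).
#' @param process_lengths primary process lengths, um (all > 0).
#' @param n_processes number of primary processes; must equal
#'   `length(process_lengths)`.
#' @param has_secondary_branches whether primaries may carry one secondary
#'   branch each.
#' @param intended_class optional activation-state label the cell is built to
#'   satisfy (`"branched"`, `"amoeboid"`, `"transitional"`).
#' @return A `shape_truth` object.
#' @export
shape_truth <- function(soma_radius, process_lengths = numeric(0),
                        n_processes = length(process_lengths),
                        has_secondary_branches = FALSE,
                        intended_class = NULL) {
  if (!is.numeric(soma_radius) || length(soma_radius) != 1L || soma_radius <= 0)
    stop("`soma_radius` must be a positive scalar (um)")
  if (n_processes != length(process_lengths))
    stop("`n_processes` must equal length(process_lengths)")
  if (any(process_lengths <= 0)) stop("all process lengths must be > 0")
  if (!is.null(intended_class))
    intended_class <- match.arg(intended_class, morph_class_levels())
  structure(list(soma_radius = soma_radius,
                 n_processes = as.integer(n_processes),
                 process_lengths = as.numeric(process_lengths),
                 has_secondary_branches = isTRUE(has_secondary_branches),
                 intended_class = intended_class),
            class = "shape_truth")
}

unit3 <- function(v) v / sqrt(sum(v^2))

# n roughly equidistant unit vectors (Fibonacci sphere)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}

random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# rotate `v` by `angle` around a random axis perpendicular to it
rotate_off_axis <- function(v, angle) {
  v <- unit3(v)
  a <- rnorm(3)
  perp <- unit3(a - sum(a * v) * v)
  unit3(cos(angle) * v + sin(angle) * perp)
}

# persistent random-walk polyline from `start` with initial direction `dir`,
# total arc length `len`, clipped to stay within `lim` (physical box half
# width around `center`). Returns vertices and the realized arc length.
walk_polyline <- function(start, dir, len, center, lim,
                          step_um = 1, turn_sd = 0.12, outward_bias = 0.08) {
  n_full <- floor(len / step_um)
  steps <- rep(step_um, n_full)
  if (len - n_full * step_um > 1e-9) steps <- c(steps, len - n_full * step_um)
  pts <- matrix(NA_real_, length(steps) + 1L, 3L)
  pts[1L, ] <- start
  p <- start
  d <- unit3(dir)
  realized <- 0
  k <- 1L
  for (s in steps) {
    d <- unit3(d + turn_sd * rnorm(3) + outward_bias * unit3(p - center))
    q <- p + s * d
    if (any(abs(q - center) > lim)) break  # would leave the grid: clip here
    k <- k + 1L
    pts[k, ] <- q
    realized <- realized + s
    p <- q
  }
  list(vertices = pts[seq_len(k), , drop = FALSE], length = realized)
}

# resample a polyline at ~`by` um spacing (includes both endpoints)
densify_polyline <- function(v, by) {
  if (nrow(v) < 2L) return(v)
  seg <- sqrt(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  t <- unique(c(seq(0, s[length(s)], by = by), s[length(s)]))
  cbind(approx(s, v[, 1], t)$y, approx(s, v[, 2], t)$y, approx(s, v[, 3], t)$y)
}

# stamp balls of physical radius `radius` (um) at each point into `mask`
stamp_points <- function(mask, points, radius, voxel_size) {
  dm <- dim(mask)
  nr <- ceiling(radius / voxel_size)
  off <- as.matrix(expand.grid(x = -nr[1]:nr[1], y = -nr[2]:nr[2],
                               z = -nr[3]:nr[3]))
  keep <- sqrt((off[, 1] * voxel_size[1])^2 + (off[, 2] * voxel_size[2])^2 +
               (off[, 3] * voxel_size[3])^2) <= radius + 1e-9
  off <- off[keep, , drop = FALSE]
  idx <- cbind(round(points[, 1] / voxel_size[1] + 0.5),
               round(points[, 2] / voxel_size[2] + 0.5),
               round(points[, 3] / voxel_size[3] + 0.5))
  ix <- outer(idx[, 1], off[, 1], "+")
  iy <- outer(idx[, 2], off[, 2], "+")
  iz <- outer(idx[, 3], off[, 3], "+")
  ok <- ix >= 1L & ix <= dm[1] & iy >= 1L & iy <= dm[2] & iz >= 1L & iz <= dm[3]
  mask[cbind(ix[ok], iy[ok], iz[ok])] <- TRUE
  mask
}

#' Generate one synthetic 3D microglial cell
#'
#' Rasterizes a soma ball plus `n_processes` tube-like processes (persistent
#' random walks attached at well-separated points on the soma surface) into a
#' binary voxel volume, and returns the realized ground truth with lengths
#' measured on the generated polylines. Processes that would leave the grid
#' are clipped and their realized length updated.
#'
#' @param truth a [shape_truth()].
#' @param voxel_size voxel pitch, um (scalar or length 3).
#' @param seed integer seed; the generator is a pure function of
#'   `(truth, voxel_size, seed)`.
#' @param tube_radius process tube radius in um; default 1.5 x the smallest
#'   voxel dimension (thinner tubes fragment the voxelization).
#' @param dims optional grid dimensions; error if too small to contain the
#'   soma plus the longest process.
#' @param step_um,turn_sd polyline step length and per-step heading noise.
#' @return A list with `volume` (a [labeled_volume()]) and `truth`, the
#'   realized truth: primary `realized_lengths`, `secondary_lengths`,
#'   `total_length`, `n_terminals`, `tube_radius`, `soma_center` (um).
#' @export
gen_microglia <- function(truth, voxel_size = c(1, 1, 1), seed = 1L,
                          tube_radius = NULL, dims = NULL,
                          step_um = 1, turn_sd = 0.12) {
  stopifnot(inherits(truth, "shape_truth"))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (any(voxel_size <= 0)) stop("voxel sizes must be > 0")
  if (is.null(tube_radius)) tube_radius <- 1.5 * min(voxel_size)
  set.seed(seed)

  reach_f <- if (truth$has_secondary_branches) 1.35 else 1.05
  max_len <- if (truth$n_processes > 0) max(truth$process_lengths) else 0
  half_extent <- truth$soma_radius + reach_f * max_len + tube_radius + 3
  need <- 2L * ceiling(half_extent / voxel_size) + 1L
  if (is.null(dims)) dims <- need
  else if (any(dims < need))
    stop("grid too small: need at least ", paste(need, collapse = "x"),
         " voxels for this truth")
  center <- (dims / 2) * voxel_size
  lim <- dims / 2 * voxel_size - tube_radius - min(voxel_size)

  dirs <- if (truth$n_processes > 0) {
    d <- fibonacci_sphere(truth$n_processes) %*% t(random_rotation())
    t(apply(d, 1, function(v) unit3(v + 0.08 * rnorm(3))))
  } else matrix(0, 0, 3)

  spacing <- 0.45 * min(voxel_size)
  realized <- numeric(truth$n_processes)
  secondary <- numeric(0)
  n_secondary <- 0L
  tube_pts <- vector("list", 2L * truth$n_processes)
  for (i in seq_len(truth$n_processes)) {
    w <- walk_polyline(center + truth$soma_radius * dirs[i, ], dirs[i, ],
                       truth$process_lengths[i], center, lim,
                       step_um = step_um, turn_sd = turn_sd)
    realized[i] <- w$length
    if (nrow(w$vertices) >= 2L)
      tube_pts[[2L * i - 1L]] <- densify_polyline(w$vertices, spacing)
    if (truth$has_secondary_branches && w$length > 4 * step_um &&
        runif(1) < 0.6) {
      at <- max(2L, round(runif(1, 0.4, 0.8) * nrow(w$vertices)))
      pdir <- unit3(w$vertices[at, ] - w$vertices[at - 1L, ])
      bdir <- rotate_off_axis(pdir, runif(1, 40, 70) * pi / 180)
      blen <- runif(1, 0.3, 0.6) * w$length
      wb <- walk_polyline(w$vertices[at, ], bdir, blen, center, lim,
                          step_um = step_um, turn_sd = turn_sd)
      if (wb$length > 0) {
        secondary <- c(secondary, wb$length)
        n_secondary <- n_secondary + 1L
        tube_pts[[2L * i]] <- densify_polyline(wb$vertices, spacing)
      }
    }
  }

  mask <- array(FALSE, dims)
  mask <- stamp_points(mask, matrix(center, 1), truth$soma_radius, voxel_size)
  tube_pts <- tube_pts[!vapply(tube_pts, is.null, logical(1))]
  if (length(tube_pts))
    mask <- stamp_points(mask, do.call(rbind, tube_pts), tube_radius,
                         voxel_size)

  out <- truth
  out$realized_lengths <- realized
  out$process_lengths <- realized
  out$secondary_lengths <- secondary
  out$total_length <- sum(realized) + sum(secondary)
  out$n_terminals <- sum(realized > 0) + n_secondary
  out$tube_radius <- tube_radius
  out$soma_center <- center
  list(volume = labeled_volume(mask, voxel_size), truth = out)
}

#' Analytic morphology expected from a shape truth
#'
#' Ball-plus-cylinder closed forms for volume, surface area, sphericity and
#' the process statistics, used to check that class-conditional truths
#' satisfy their intended classification criteria.
#'
#' @param truth a (realized) [shape_truth()].
#' @param tube_radius tube radius um; taken from the realized truth if absent.
#' @return A [cell_morphology()].
#' @export
expected_morphology <- function(truth, tube_radius = NULL) {
  r <- tube_radius %||% truth$tube_radius %||% 1.5
  tl <- truth$total_length %||% sum(truth$process_lengths)
  R <- truth$soma_radius
  V <- 4 / 3 * pi * R^3 + pi * r^2 * tl
  A <- 4 * pi * R^2 + 2 * pi * r * tl
  np <- truth$n_processes
  terms <- truth$n_terminals %||% np
  cell_morphology(
    sphericity = pi^(1 / 3) * (6 * V)^(2 / 3) / A,
    n_processes = np,
    total_length = tl,
    mean_length = if (np > 0) tl / np else 0,
    surface_area = A,
    volume = V,
    ramification_index = if (np > 0) terms / np else 0,
    sholl = data.frame(radius_um = numeric(0), intersections = integer(0)))
}

# class-conditional truth parameters: each intended class satisfies its
# classification criteria by construction (amoeboid: <=2 short processes;
# branched: >=8 processes totalling > 140 um; transitional in between)
draw_class_truth <- function(class) {
  switch(class,
    amoeboid = {
      np <- sample(0:2, 1)
      shape_truth(runif(1, 5, 7),
                  if (np > 0) runif(np, 8, 18) else numeric(0),
                  intended_class = "amoeboid")
    },
    transitional = {
      np <- sample(4:6, 1)
      raw <- runif(np, 18, 26)
      shape_truth(runif(1, 4.5, 6), raw * runif(1, 75, 130) / sum(raw),
                  intended_class = "transitional")
    },
    branched = {
      np <- sample(8:10, 1)
      shape_truth(runif(1, 5.5, 6.5), runif(np, 18, 28),
                  has_secondary_branches = TRUE,
                  intended_class = "branched")
    },
    stop("unknown class: ", class))
}

#' Generate a synthetic microglia population with a given class mix
#'
#' Draws cell class labels from a multinomial over
#' `(branched, amoeboid, transitional)` and generates each cell with
#' class-conditional parameter ranges chosen so the intended class satisfies
#' its classification criteria by construction.
#'
#' @param mix named proportions over `branched`, `amoeboid`, `transitional`;
#'   must be non-negative and sum to 1.
#' @param n number of cells (> 0).
#' @param seed integer seed.
#' @param voxel_size voxel pitch um.
#' @return List of `list(volume, truth)` pairs; the drawn class counts are in
#'   attribute `"class_counts"`.
#' @export
gen_population <- function(mix, n, seed = 1L, voxel_size = c(1, 1, 1)) {
  if (n <= 0) stop("`n` must be > 0")
  if (is.null(names(mix)) || !all(names(mix) %in% morph_class_levels()))
    stop("`mix` must be named with classes ",
         paste(morph_class_levels(), collapse = ", "))
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-6)
    stop("`mix` proportions must be >= 0 and sum to 1")
  set.seed(seed)
  classes <- sample(names(mix), n, replace = TRUE, prob = mix)
  cells <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(derive_seed(seed, i))
    truth <- draw_class_truth(classes[i])
    cells[[i]] <- gen_microglia(truth, voxel_size = voxel_size,
                                seed = derive_seed(seed, n + i))
  }
  structure(cells, class_counts = table(factor(classes, morph_class_levels())))
}
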