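# Centerline extraction for tube-like 3D cells.
#
# The skeleton is traced as a shortest-path tree on the foreground voxel
# graph (26-connectivity, physical edge weights): the soma is the deepest
# voxel by distance-to-background, and branch tips are found by iterative
# farthest-point search, accepting a new tip only where the geodesic
# distance to the current skeleton exceeds the local depth plus a margin
# (so voxels inside an already-traced tube or the soma never seed tips).
# This yields the rooted tree (soma, junctions, terminals, arc lengths)
# that the process statistics and Sholl analysis consume, and works
# directly on anisotropic grids because all edge weights are in um.

# arc length of a voxel chain, resampled at every 3rd point: chords over
# three voxel steps cancel the staircase zigzag of a discrete path while
# following any curvature the generator's walks produce
chord_length <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  idx <- unique(c(seq(1L, n, by = 3L), n))
  Q <- P[idx, , drop = FALSE]
  sum(sqrt(rowSums((Q[-1, , drop = FALSE] - Q[-nrow(Q), , drop = FALSE])^2)))
}

crop_mask <- function(mask, pad = 3L) {
  w <- which(mask, arr.ind = TRUE)
  lo <- pmax(apply(w, 2, min) - pad, 1L)
  hi <- pmin(apply(w, 2, max) + pad, dim(mask))
  list(mask = mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE],
       offset_vox = lo - 1L)
}

#' Skeletonize one cell mask into a rooted process graph
#'
#' @param mask 3D logical (or 0/1) array containing one connected cell.
#' @param voxel_size voxel pitch, um (scalar or length 3).
#' @param prune_len terminal (spur) branches shorter than this are removed,
#'   um.
#' @param tip_margin a voxel can seed a new branch tip only if its geodesic
#'   distance to the current skeleton exceeds its depth plus this margin
#'   (um); bounds the shortest detectable process.
#' @param max_tips safety cap on traced branches.
#' @return A `skeleton_graph`: condensed `nodes` (soma / junction /
#'   terminal, physical um coordinates) and `edges` with arc lengths,
#'   `soma_node`, `terminal_nodes`, `soma_radius_um`, `soma_center_um`; the
#'   full voxel tree is kept in attribute `"voxel_tree"` for Sholl profiles.
#' @export
skeletonize_cell <- function(mask, voxel_size, prune_len = 2,
                             tip_margin = 4, max_tips = 200L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  cr <- crop_mask(mask)
  sub <- cr$mask
  g <- mask_csr(as.vector(sub), dim(sub), voxel_size)
  m <- length(g$fg)

  # physical voxel-center coordinates in the original frame
  v0 <- g$fg - 1L
  dm <- dim(sub)
  vx <- v0 %% dm[1]
  vy <- (v0 %/% dm[1]) %% dm[2]
  vz <- v0 %/% (dm[1] * dm[2])
  pos <- cbind((vx + 0.5 + cr$offset_vox[1]) * voxel_size[1],
               (vy + 0.5 + cr$offset_vox[2]) * voxel_size[2],
               (vz + 0.5 + cr$offset_vox[3]) * voxel_size[3])

  depth <- csr_dijkstra(g, g$boundary)$dist + 0.5 * min(voxel_size)
  soma_fg <- which.max(depth)
  r_soma <- depth[soma_fg]
  soma_center <- pos[soma_fg, ]
  euclid <- sqrt(colSums((t(pos) - soma_center)^2))

  # route paths through deep (central) voxels: 26-connected shortest paths
  # tie on length and otherwise hug the tube wall, inflating arc lengths;
  # the depth penalty breaks ties toward the centreline while tip selection
  # and all reported lengths stay in physical um
  row_idx <- rep(seq_len(m), diff(g$ptr))
  depth_mid <- (depth[row_idx] + depth[g$nbr]) / 2
  g_pen <- g
  g_pen$wt <- g$wt * (1 + 1 / (0.5 + depth_mid))

  in_skel <- logical(m)
  in_skel[soma_fg] <- TRUE
  skel_parent <- integer(m)
  min_tip_euclid <- r_soma + min(voxel_size)
  # a voxel inside an already-traced tube sits within (tube radius + one
  # voxel diagonal) of the centreline while its own depth is at least a
  # fraction of the tube radius, so gating tips at twice the local depth
  # plus two voxel diagonals rejects tube-wall artifacts at any voxel size;
  # tip_margin (um) is the absolute floor
  diag3 <- sqrt(sum(voxel_size^2))
  for (it in seq_len(max_tips)) {
    src <- which(in_skel)
    d <- csr_dijkstra(g, src)
    score <- d$dist
    score[in_skel |
            score <= pmax(tip_margin, 2 * depth + 2 * diag3) |
            euclid <= min_tip_euclid] <- -Inf
    v <- which.max(score)
    if (!is.finite(score[v])) break
    dp <- csr_dijkstra(g_pen, src)
    u <- v
    while (!in_skel[u]) {
      skel_parent[u] <- dp$parent[u]
      in_skel[u] <- TRUE
      u <- dp$parent[u]
    }
  }

  skel <- which(in_skel)
  step_len <- numeric(m)
  has_par <- skel[skel_parent[skel] > 0L]
  step_len[has_par] <- sqrt(rowSums(
    (pos[has_par, , drop = FALSE] -
       pos[skel_parent[has_par], , drop = FALSE])^2))

  # spur pruning: drop terminal chains shorter than prune_len
  repeat {
    skel <- which(in_skel)
    p <- skel_parent[skel]
    n_child <- tabulate(p[p > 0L], m)
    leaves <- skel[n_child[skel] == 0L & skel != soma_fg]
    removed <- FALSE
    for (leaf in leaves) {
      chain <- integer(0)
      u <- leaf
      len <- 0
      while (u != soma_fg && n_child[u] <= 1L && euclid[u] > r_soma &&
             skel_parent[u] > 0L) {
        chain <- c(chain, u)
        len <- len + step_len[u]
        u <- skel_parent[u]
        if (len >= prune_len) break
      }
      if (len < prune_len && length(chain) > 0L) {
        in_skel[chain] <- FALSE
        removed <- TRUE
      }
    }
    if (!removed) break
  }

  # centreline smoothing: a voxel-resolution shortest path zigzags along the
  # tube wall, inflating arc lengths; two passes of 3-point averaging on
  # chain-interior voxels recover near-true lengths without moving
  # junctions, tips or the root
  skel <- which(in_skel)
  pp <- skel_parent[skel]
  n_child_all <- tabulate(pp[pp > 0L], m)
  child <- integer(m)
  child[pp[pp > 0L]] <- skel[pp > 0L]  # unique where n_child == 1
  interior <- skel[skel_parent[skel] > 0L & n_child_all[skel] == 1L &
                     child[skel] > 0L]
  for (pass in 1:2) {
    if (length(interior) == 0L) break
    pos[interior, ] <- 0.25 * pos[skel_parent[interior], , drop = FALSE] +
      0.5 * pos[interior, , drop = FALSE] +
      0.25 * pos[child[interior], , drop = FALSE]
  }
  has_par <- skel[skel_parent[skel] > 0L]
  step_len[has_par] <- sqrt(rowSums(
    (pos[has_par, , drop = FALSE] -
       pos[skel_parent[has_par], , drop = FALSE])^2))
  euclid <- sqrt(colSums((t(pos) - soma_center)^2))

  outside <- in_skel & euclid > r_soma
  # children counted within the outside sub-forest
  n_child <- integer(m)
  op <- skel_parent[which(outside)]
  op <- op[op > 0L & outside[pmax(op, 1L)]]
  if (length(op)) n_child <- tabulate(op, m)

  is_leaf <- outside & n_child == 0L
  is_junction <- outside & n_child >= 2L
  special <- which(is_leaf | is_junction)

  node_pos <- matrix(soma_center, 1, 3)
  node_type <- "soma"
  node_of <- integer(m)  # voxel -> condensed node id
  for (s in special) {
    node_pos <- rbind(node_pos, pos[s, ])
    node_type <- c(node_type, if (is_junction[s]) "junction" else "terminal")
    node_of[s] <- nrow(node_pos)
  }
  edges <- data.frame(from = integer(0), to = integer(0),
                      length_um = numeric(0))
  for (s in special) {
    chain <- s
    u <- skel_parent[s]
    while (u > 0L && outside[u] && node_of[u] == 0L) {
      chain <- c(chain, u)
      u <- skel_parent[u]
    }
    if (u > 0L) chain <- c(chain, u)
    from <- if (u > 0L && outside[u]) node_of[u] else 1L
    edges <- rbind(edges, data.frame(
      from = from, to = node_of[s],
      length_um = chord_length(pos[chain, , drop = FALSE])))
  }

  # the farthest-point tip lies on the end-cap surface, ~one tube radius
  # beyond the true process end; trim terminal edges by the tube radius
  # estimated as the median centreline depth outside the soma
  if (nrow(edges) > 0L && any(outside)) {
    trim <- median(depth[which(outside)])
    term_edge <- edges$to %in% which(node_type == "terminal")
    edges$length_um[term_edge] <-
      pmax(edges$length_um[term_edge] - trim, 0.25 * min(voxel_size))
  }

  nodes <- data.frame(id = seq_len(nrow(node_pos)),
                      x_um = node_pos[, 1], y_um = node_pos[, 2],
                      z_um = node_pos[, 3], type = node_type)
  tree <- list(pos = pos[skel, , drop = FALSE],
               parent_pos = {
                 pp <- skel_parent[skel]
                 ok <- pp > 0L
                 out <- matrix(NA_real_, length(skel), 3)
                 out[ok, ] <- pos[pp[ok], , drop = FALSE]
                 out
               },
               outside = outside[skel])
  structure(list(nodes = nodes, edges = edges, soma_node = 1L,
                 terminal_nodes = nodes$id[nodes$type == "terminal"],
                 soma_radius_um = r_soma, soma_center_um = soma_center),
            voxel_tree = tree, class = "skeleton_graph")
}

#' @export
print.skeleton_graph <- function(x, ...) {
  st <- process_stats(x)
  cat("skeleton_graph: soma radius", round(x$soma_radius_um, 2), "um,",
      st$n_processes, "primary process(es),", nrow(x$edges), "edge(s),",
      length(x$terminal_nodes), "terminal(s), total length",
      round(st$total_length, 1), "um\n")
  invisible(x)
}

#' Process statistics from a skeleton
#'
#' Primary processes (NP) are the skeleton edges incident to the soma node;
#' total length (TL) sums all process arc lengths outside the soma; the
#' ramification index is terminals per primary process (1 for unbranched
#' cells, larger with branching, 0 when there are no processes).
#'
#' @param skeleton a `skeleton_graph`.
#' @return list `(n_processes, total_length, mean_length,
#'   ramification_index)`.
#' @export
process_stats <- function(skeleton) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  np <- sum(skeleton$edges$from == skeleton$soma_node)
  tl <- sum(skeleton$edges$length_um)
  nt <- length(skeleton$terminal_nodes)
  list(n_processes = np,
       total_length = tl,
       mean_length = if (np > 0) tl / np else 0,
       ramification_index = if (np > 0) nt / np else 0)
}

#' Sholl profile of a skeleton
#'
#' Counts skeleton segments crossing concentric spheres centred on the soma;
#' a segment crossing a sphere k times contributes k.
#'
#' @param skeleton a `skeleton_graph`.
#' @param center sphere centre, um; default the soma centroid.
#' @param r_step,r_max radius step and maximum, um.
#' @return data.frame `(radius_um, intersections)`.
#' @export
sholl_profile <- function(skeleton, center = NULL, r_step = 5, r_max = 100) {
  stopifnot(inherits(skeleton, "skeleton_graph"))
  if (r_step <= 0) stop("`r_step` must be > 0")
  center <- center %||% skeleton$soma_center_um
  radii <- seq(r_step, r_max, by = r_step)
  tree <- attr(skeleton, "voxel_tree")
  ok <- !is.na(tree$parent_pos[, 1])
  if (!any(ok))
    return(data.frame(radius_um = radii, intersections = 0L))
  d1 <- sqrt(colSums((t(tree$pos[ok, , drop = FALSE]) - center)^2))
  d2 <- sqrt(colSums((t(tree$parent_pos[ok, , drop = FALSE]) - center)^2))
  lo <- pmin(d1, d2)
  hi <- pmax(d1, d2)
  # half-open interval so a crossing that lands exactly on a shared segment
  # endpoint is counted once, not zero or twice
  counts <- vapply(radii, function(r) sum(lo < r & r <= hi), integer(1))
  data.frame(radius_um = radii, intersections = counts)
}
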