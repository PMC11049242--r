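#' Physical centroids of every cell in a labeled volume
#'
#' @param volume a [labeled_volume()].
#' @return Matrix (cells x 3) of centroid coordinates in um, rownames the
#'   cell ids; suitable as one frame for [link_centroids()].
#' @export
centroids_of <- function(volume) {
  stopifnot(inherits(volume, "labeled_volume"))
  ids <- volume$cell_ids
  out <- matrix(NA_real_, length(ids), 3,
                dimnames = list(ids, c("x", "y", "z")))
  for (i in seq_along(ids)) {
    w <- which(volume$voxels == ids[i], arr.ind = TRUE)
    out[i, ] <- (colMeans(w) - 0.5) * volume$voxel_size
  }
  out
}

#' Link per-frame centroids into cell tracks
#'
#' Greedy mutual-nearest-neighbour linking between consecutive frames:
#' the globally closest centroid pair is linked first, then the next, and
#' so on; candidate links longer than `max_step` are rejected. Unmatched
#' centroids end their track or start a new one; empty frames simply end
#' all open tracks (no gap closing).
#'
#' @param frames list of per-frame centroid matrices (n_i x 2 or n_i x 3,
#'   um), at least 2 frames.
#' @param max_step maximum link length, um.
#' @param dt frame interval, s (used when `frame_times` is absent).
#' @param frame_times optional frame times, s.
#' @return List of `cell_track` objects: data.frames `(t_s, x, y[, z])`
#'   with attributes `complete` (spans first and last frame) and `cell_id`.
#' @export
link_centroids <- function(frames, max_step = 20, dt = 40,
                           frame_times = NULL) {
  if (length(frames) < 2L) stop("need at least 2 frames")
  frames <- lapply(frames, function(f) {
    f <- as.matrix(f)
    if (nrow(f) > 0 && !ncol(f) %in% 2:3)
      stop("centroids must be 2D or 3D")
    f
  })
  t_s <- frame_times %||% (seq_along(frames) - 1) * dt
  nd <- max(c(2L, vapply(frames, ncol, integer(1))))

  open <- list()   # list of list(rows = matrix, times, last_frame)
  done <- list()
  for (fi in seq_along(frames)) {
    f <- frames[[fi]]
    n_new <- nrow(f)
    prev_idx <- which(vapply(open, function(tr) tr$last_frame == fi - 1L,
                             logical(1)))
    assigned_new <- integer(0)
    if (length(prev_idx) > 0 && n_new > 0) {
      prev_pos <- do.call(rbind, lapply(open[prev_idx], function(tr)
        tr$rows[nrow(tr$rows), , drop = FALSE]))
      D <- as.matrix(dist(rbind(prev_pos, f)))[seq_along(prev_idx),
                                               length(prev_idx) + seq_len(n_new),
                                               drop = FALSE]
      D[D > max_step] <- Inf
      while (any(is.finite(D))) {
        k <- arrayInd(which.min(D), dim(D))
        ti <- prev_idx[k[1]]
        open[[ti]]$rows <- rbind(open[[ti]]$rows, f[k[2], ])
        open[[ti]]$times <- c(open[[ti]]$times, t_s[fi])
        open[[ti]]$last_frame <- fi
        assigned_new <- c(assigned_new, k[2])
        D[k[1], ] <- Inf
        D[, k[2]] <- Inf
      }
    }
    # close tracks not extended into this frame
    stale <- which(vapply(open, function(tr) tr$last_frame < fi, logical(1)))
    if (length(stale)) {
      done <- c(done, open[stale])
      open <- open[-stale]
    }
    # unmatched centroids start new tracks
    for (j in setdiff(seq_len(n_new), assigned_new))
      open <- c(open, list(list(rows = f[j, , drop = FALSE],
                                times = t_s[fi], last_frame = fi)))
  }
  done <- c(done, open)
  n_frames <- length(frames)
  lapply(seq_along(done), function(i) {
    tr <- done[[i]]
    df <- as.data.frame(tr$rows)
    names(df) <- c("x", "y", "z")[seq_len(ncol(df))]
    df <- cbind(t_s = tr$times, df)
    structure(df, complete = tr$times[1] == t_s[1] &&
                tr$times[length(tr$times)] == t_s[n_frames],
              cell_id = i, class = c("cell_track", "data.frame"))
  })
}

#' Motility summary of one cell track
#'
#' Displacement is the straight-line distance between the first and last
#' centroid; path length sums the inter-frame steps; mean speed is path
#' length over elapsed time (from timestamps), in um/min.
#'
#' @param track a `cell_track` or data.frame `(t_s, x, y[, z])` with at
#'   least 2 samples and strictly increasing times.
#' @return list `(displacement_um, path_length_um, mean_speed_um_min,
#'   elapsed_s)`.
#' @export
summarize_track <- function(track) {
  if (nrow(track) < 2L) stop("track needs at least 2 samples")
  if (any(diff(track$t_s) <= 0)) stop("times must be strictly increasing")
  xyz <- as.matrix(track[, intersect(c("x", "y", "z"), names(track)),
                         drop = FALSE])
  steps <- sqrt(rowSums((xyz[-1, , drop = FALSE] -
                           xyz[-nrow(xyz), , drop = FALSE])^2))
  path <- sum(steps)
  disp <- sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  elapsed <- track$t_s[nrow(track)] - track$t_s[1]
  list(displacement_um = disp, path_length_um = path,
       mean_speed_um_min = path / (elapsed / 60), elapsed_s = elapsed)
}

#' Motility summary table for a set of tracks
#'
#' @param tracks list from [link_centroids()].
#' @param min_span_frac only tracks spanning at least this fraction of the
#'   recording enter the table (avoids speed bias from short fragments).
#' @return data.frame with one row per retained track.
#' @export
summarize_tracks <- function(tracks, min_span_frac = 0.8) {
  total <- max(vapply(tracks, function(tr) max(tr$t_s), numeric(1))) -
    min(vapply(tracks, function(tr) min(tr$t_s), numeric(1)))
  rows <- lapply(tracks, function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    span <- tr$t_s[nrow(tr)] - tr$t_s[1]
    if (total > 0 && span < min_span_frac * total) return(NULL)
    s <- summarize_track(tr)
    data.frame(cell_id = attr(tr, "cell_id"),
               n_samples = nrow(tr),
               displacement_um = s$displacement_um,
               path_length_um = s$path_length_um,
               mean_speed_um_min = s$mean_speed_um_min)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(cell_id = integer(0), n_samples = integer(0),
                      displacement_um = numeric(0),
                      path_length_um = numeric(0),
                      mean_speed_um_min = numeric(0))
  out
}
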