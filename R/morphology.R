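#' Per-cell morphology vector
#'
#' The measured parameter set for one microglial cell: Wadell sphericity S,
#' number of primary processes NP, total process length TL (um), mean
#' process length (um), surface area A (um^2), volume V (um^3),
#' ramification index RI (terminals per primary process), and the Sholl
#' profile.
#'
#' @param sphericity,n_processes,total_length,mean_length,surface_area,volume,ramification_index
#'   scalar measurements (see description).
#' @param sholl data.frame `(radius_um, intersections)`.
#' @return A `cell_morphology` object.
#' @export
cell_morphology <- function(sphericity, n_processes, total_length,
                            mean_length, surface_area, volume,
                            ramification_index, sholl) {
  stopifnot(volume > 0, surface_area > 0, total_length >= 0,
            n_processes >= 0, sphericity > 0)
  structure(list(sphericity = sphericity,
                 n_processes = as.integer(n_processes),
                 total_length = total_length,
                 mean_length = mean_length,
                 surface_area = surface_area,
                 volume = volume,
                 ramification_index = ramification_index,
                 sholl = sholl),
            class = "cell_morphology")
}

#' @export
print.cell_morphology <- function(x, ...) {
  cat(sprintf(paste0("cell_morphology: S=%.3f NP=%d TL=%.1f um ",
                     "mean=%.1f um A=%.0f um^2 V=%.0f um^3 RI=%.2f\n"),
              x$sphericity, x$n_processes, x$total_length, x$mean_length,
              x$surface_area, x$volume, x$ramification_index))
  invisible(x)
}

#' Wadell sphericity
#'
#' `pi^(1/3) * (6V)^(2/3) / A`: 1 for a perfect sphere, smaller for any
#' other shape.
#'
#' @param volume volume, um^3.
#' @param area surface area, um^2.
#' @return Dimensionless sphericity.
#' @export
wadell_sphericity <- function(volume, area) {
  pi^(1 / 3) * (6 * volume)^(2 / 3) / area
}

#' Measure the 3D morphology of one cell
#'
#' Volume is voxel count times voxel volume; surface area is the
#' normal-corrected exposed-face estimate of the 0.5 isosurface (see
#' the methods vignette); sphericity is Wadell's; process statistics and the
#' Sholl profile come from [skeletonize_cell()].
#'
#' @param volume a [labeled_volume()].
#' @param cell_id which label to measure (defaults to the only cell).
#' @param r_step,r_max Sholl radius step and maximum, um.
#' @param prune_len,tip_margin skeletonization parameters, um; see
#'   [skeletonize_cell()].
#' @return A [cell_morphology()], with the `skeleton_graph` in attribute
#'   `"skeleton"`.
#' @export
measure_cell <- function(volume, cell_id = NULL, r_step = 5, r_max = 100,
                         prune_len = 2, tip_margin = 4) {
  stopifnot(inherits(volume, "labeled_volume"))
  if (is.null(cell_id)) {
    if (length(volume$cell_ids) != 1L)
      stop("volume has ", length(volume$cell_ids),
           " cells; supply `cell_id`")
    cell_id <- volume$cell_ids[1]
  }
  if (!cell_id %in% volume$cell_ids)
    stop("cell_id ", cell_id, " not present in volume")
  vox <- volume$voxel_size
  mask <- volume$voxels == cell_id
  cr <- crop_mask(mask)
  sub <- cr$mask
  V <- sum(sub) * prod(vox)
  A <- surface_area_mask(as.vector(sub), dim(sub), vox, 0.45 * min(vox))
  skel <- skeletonize_cell(mask, vox, prune_len = prune_len,
                           tip_margin = tip_margin)
  st <- process_stats(skel)
  sholl <- sholl_profile(skel, r_step = r_step, r_max = r_max)
  structure(cell_morphology(
    sphericity = wadell_sphericity(V, A),
    n_processes = st$n_processes,
    total_length = st$total_length,
    mean_length = st$mean_length,
    surface_area = A,
    volume = V,
    ramification_index = st$ramification_index,
    sholl = sholl), skeleton = skel)
}

#' Morphology table for a labelled volume or a synthetic population
#'
#' @param x a [labeled_volume()] (all cells measured) or a list of
#'   `list(volume, truth)` pairs as returned by [gen_population()].
#' @param ... passed to [measure_cell()].
#' @return data.frame with one row per cell: `cell_id`, `sphericity`,
#'   `n_processes`, `total_length`, `mean_length`, `surface_area`,
#'   `volume`, `ramification_index` (+ `intended_class` for populations).
#' @export
morphology_table <- function(x, ...) {
  row_of <- function(m, id) {
    data.frame(cell_id = id, sphericity = m$sphericity,
               n_processes = m$n_processes, total_length = m$total_length,
               mean_length = m$mean_length, surface_area = m$surface_area,
               volume = m$volume, ramification_index = m$ramification_index)
  }
  if (inherits(x, "labeled_volume")) {
    do.call(rbind, lapply(x$cell_ids, function(k)
      row_of(measure_cell(x, k, ...), k)))
  } else {
    out <- do.call(rbind, lapply(seq_along(x), function(i)
      row_of(measure_cell(x[[i]]$volume, ...), i)))
    cls <- vapply(x, function(c)
      c$truth$intended_class %||% NA_character_, character(1))
    out$intended_class <- cls
    out
  }
}
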