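#' Labeled 3D volume
#'
#' Container for a voxel grid carrying cell labels. `voxels` is a 3D integer
#' array (0 = background, k > 0 = cell id); `voxel_size` gives the physical
#' voxel pitch in micrometres along each array dimension.
#'
#' @param voxels 3D integer or logical array. Logical input is converted to
#'   a single label (1 = foreground).
#' @param voxel_size numeric length-3, micrometres per voxel along
#'   `dim(voxels)[1:3]`. A scalar is recycled (isotropic voxels).
#' @return An object of class `labeled_volume` with elements `voxels`
#'   (integer array) and `voxel_size`.
#' @export
labeled_volume <- function(voxels, voxel_size) {
  if (length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3D array")
  if (is.logical(voxels)) voxels <- array(as.integer(voxels), dim(voxels))
  if (!is.numeric(voxels)) stop("`voxels` must be integer or logical")
  storage.mode(voxels) <- "integer"
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stop("`voxel_size` must be 3 positive finite numbers (um)")
  ids <- cell_ids_from(voxels)
  structure(list(voxels = voxels, voxel_size = voxel_size, cell_ids = ids),
            class = "labeled_volume")
}

cell_ids_from <- function(voxels) {
  mx <- max(voxels)
  if (mx <= 0L) return(integer(0))
  which(tabulate(voxels, mx) > 0L)  # tabulate skips zeros in one C pass
}

#' @export
print.labeled_volume <- function(x, ...) {
  cat("labeled_volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels,", length(x$cell_ids), "cell(s),\n  voxel size (um):",
      paste(signif(x$voxel_size, 4), collapse = " x "), "\n")
  invisible(x)
}

#' Otsu threshold of an intensity sample
#'
#' Histogram-based Otsu threshold (maximum between-class variance), used for
#' global foreground segmentation and reporter-positivity calls.
#'
#' @param x numeric vector of intensities.
#' @param n_bins number of histogram bins.
#' @return Scalar threshold; voxels with intensity strictly above it are
#'   foreground.
#' @export
otsu_threshold <- function(x, n_bins = 256L) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), n_bins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sb2 <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  sb2[!is.finite(sb2)] <- -Inf
  mids[which.max(sb2)]
}

#' Segment cells from an intensity volume
#'
#' Global threshold (Otsu by default) followed by 26-connected component
#' labelling; components smaller than `min_voxels` are discarded and labels
#' are renumbered 1..k in order of appearance.
#'
#' @param intensity_volume 3D numeric array.
#' @param voxel_size voxel pitch in um (length 3 or scalar).
#' @param method `"otsu"` or a numeric threshold.
#' @param min_voxels minimum component size kept (voxels).
#' @return A [labeled_volume()].
#' @export
segment_cells <- function(intensity_volume, voxel_size, method = "otsu",
                          min_voxels = 50L) {
  if (length(dim(intensity_volume)) != 3L)
    stop("`intensity_volume` must be a 3D array")
  thr <- if (is.numeric(method)) method else
    switch(match.arg(method, "otsu"), otsu = otsu_threshold(intensity_volume))
  mask <- intensity_volume > thr
  if (!any(mask)) {
    warning("empty foreground: no voxels above threshold")
    return(labeled_volume(array(0L, dim(intensity_volume)), voxel_size))
  }
  lab <- cc_label_3d(as.vector(mask), dim(intensity_volume))
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_voxels)
  if (length(keep) == 0L) {
    warning("all components smaller than min_voxels")
    return(labeled_volume(array(0L, dim(intensity_volume)), voxel_size))
  }
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- array(0L, dim(intensity_volume))
  nz <- lab > 0L
  out[nz] <- remap[lab[nz]]
  labeled_volume(out, voxel_size)
}

#' Fraction of cells positive for a reporter channel
#'
#' A cell is reporter-positive when its mean reporter intensity exceeds an
#' Otsu threshold computed over all cell voxels (`rule = "mean"`), or when at
#' least `threshold` of its voxels individually exceed that Otsu cut
#' (`rule = "fraction"`).
#'
#' @param cells a [labeled_volume()].
#' @param reporter_volume 3D numeric array, same shape as `cells$voxels`.
#' @param rule `"mean"` (default) or `"fraction"`.
#' @param threshold voxel fraction for `rule = "fraction"`.
#' @return Percentage of positive cells (0-100), with per-cell calls in
#'   attribute `"calls"`.
#' @export
coexpression_fraction <- function(cells, reporter_volume,
                                  rule = c("mean", "fraction"),
                                  threshold = 0.5) {
  rule <- match.arg(rule)
  stopifnot(inherits(cells, "labeled_volume"))
  if (!identical(dim(reporter_volume), dim(cells$voxels)))
    stop("`reporter_volume` must match the cell grid shape")
  ids <- cells$cell_ids
  if (length(ids) == 0L) stop("no cells in `cells`")
  inside <- cells$voxels > 0L
  rv <- reporter_volume[inside]
  if (diff(range(rv)) == 0) {
    # uniform reporter across all cell voxels: no contrast to threshold,
    # so every cell is positive iff the common level is nonzero
    pos <- rep(rv[1] > 0, length(ids))
  } else {
    cut <- otsu_threshold(rv)
    pos <- vapply(ids, function(k) {
      v <- reporter_volume[cells$voxels == k]
      if (rule == "mean") mean(v) > cut else mean(v > cut) >= threshold
    }, logical(1))
  }
  structure(100 * mean(pos),
            calls = data.frame(cell_id = ids, positive = pos))
}

#' Write / read a labeled volume as a multi-page TIFF
#'
#' One z-slice per 16-bit page, labels scaled to the full range. The voxel
#' size and label scale travel in a JSON sidecar (`<path>.meta.json`).
#' Requires the `tiff` package.
#'
#' @param volume a [labeled_volume()].
#' @param path output file.
#' @return `write_volume_tiff`: `path`, invisibly. `read_volume_tiff`: a
#'   [labeled_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  v <- volume$voxels
  mx <- max(1L, max(v))
  slices <- lapply(seq_len(dim(v)[3]), function(z) v[, , z] / mx)
  tiff::writeTIFF(slices, path, bits.per.sample = 16L, reduce = FALSE)
  jsonlite::write_json(list(voxel_size_um = volume$voxel_size,
                            max_label = mx),
                       paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @param voxel_size override for the voxel size when no sidecar is present.
#' @export
read_volume_tiff <- function(path, voxel_size = NULL) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  slices <- tiff::readTIFF(path, all = TRUE)
  mx <- 1L
  sidecar <- paste0(path, ".meta.json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(voxel_size)) voxel_size <- meta$voxel_size_um
    mx <- as.integer(meta$max_label)
  }
  if (is.null(voxel_size))
    stop("no voxel size sidecar found; supply `voxel_size`")
  arr <- array(0L, c(dim(slices[[1]])[1:2], length(slices)))
  for (z in seq_along(slices))
    arr[, , z] <- as.integer(round(slices[[z]] * mx))
  labeled_volume(arr, voxel_size)
}
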