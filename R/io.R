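#' Read and write the pipeline's CSV trace formats
#'
#' Three small plain-text formats tie the pipeline to acquisition software:
#' fluorescence traces (`frame,t_s,intensity`), LFP traces (`t_s,mV`) and
#' larva trajectories (`t_s,x_mm,y_mm`).
#'
#' @param path CSV file path.
#' @return `read_fluor_csv`: a [fluor_trace()]; `read_lfp_csv`: an
#'   [lfp_recording()]; `read_trajectory_csv`: a data.frame
#'   `(t_s, x_mm, y_mm)`.
#' @export
read_fluor_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!"intensity" %in% names(d))
    stop("fluorescence CSV needs an `intensity` column")
  fluor_trace(d$intensity,
              frame_times = if ("t_s" %in% names(d)) d$t_s else NULL)
}

#' @rdname read_fluor_csv
#' @export
read_lfp_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "mV") %in% names(d)))
    stop("LFP CSV needs `t_s` and `mV` columns")
  dt <- median(diff(d$t_s))
  lfp_recording(d$mV, dt)
}

#' @rdname read_fluor_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("t_s", "x_mm", "y_mm") %in% names(d)))
    stop("trajectory CSV needs `t_s`, `x_mm`, `y_mm` columns")
  d[c("t_s", "x_mm", "y_mm")]
}

#' Whole-field fluorescence trace from a TIFF time series
#'
#' Reads a multi-page TIFF (one frame per page) and reduces each frame to
#' its mean gray value. Requires the `tiff` package.
#'
#' @param path multi-page TIFF file.
#' @param frame_interval_s seconds per frame.
#' @return A [fluor_trace()].
#' @export
fluor_trace_from_tiff <- function(path, frame_interval_s = 1) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("package 'tiff' is required for TIFF I/O")
  frames <- tiff::readTIFF(path, all = TRUE)
  fluor_trace(vapply(frames, mean, numeric(1)),
              frame_interval_s = frame_interval_s)
}

#' Write a trace or trajectory in its standard CSV format
#'
#' @param x a [fluor_trace()], [lfp_recording()] or trajectory data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path) {
  d <- if (inherits(x, "fluor_trace")) {
    data.frame(frame = seq_along(x$raw), t_s = x$t_s, intensity = x$raw)
  } else if (inherits(x, "lfp_recording")) {
    data.frame(t_s = (seq_along(x$mv) - 1) * x$sampling_interval_s,
               mV = x$mv)
  } else as.data.frame(x)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Write the ground truth of a synthetic object as a JSON sidecar
#'
#' @param truth a `shape_truth`, `calcium_truth` or `lfp_truth`.
#' @param path output `.json` file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(c(list(truth_class = class(truth)[1]),
                         unclass(truth)),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
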