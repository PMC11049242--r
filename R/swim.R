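#' Locomotor scoring configuration
#'
#' Speed thresholds for the four locomotor states: a step counts as
#' immobile below `motion_floor`, low-speed below `inactive_threshold`,
#' medium-speed in `[inactive_threshold, high_threshold)` and high-speed at
#' or above `high_threshold`. Thresholds are in mm/s (distance per second
#' at 1 s re-integration).
#'
#' @param integration_s reporting bin length, s.
#' @param inactive_threshold low/medium boundary, mm/s.
#' @param high_threshold medium/high boundary, mm/s.
#' @param motion_floor immobility floor, mm/s.
#' @return A `swim_config` object.
#' @export
swim_config <- function(integration_s = 60, inactive_threshold = 4,
                        high_threshold = 8, motion_floor = 0.1) {
  if (!(0 < inactive_threshold && inactive_threshold < high_threshold))
    stop("need 0 < inactive_threshold < high_threshold")
  if (motion_floor < 0 || motion_floor >= inactive_threshold)
    stop("`motion_floor` must be in [0, inactive_threshold)")
  structure(list(integration_s = integration_s,
                 inactive_threshold = inactive_threshold,
                 high_threshold = high_threshold,
                 motion_floor = motion_floor),
            class = "swim_config")
}

#' Score one larva trajectory into distance and speed-state times
#'
#' Per-step speed is step length over the step interval; each inter-sample
#' interval is assigned to one of the four states (see [swim_config()]) and
#' state times and total distance are accumulated, overall and per
#' integration bin.
#'
#' @param positions data.frame `(t_s, x_mm, y_mm)` with strictly increasing
#'   times and at least 2 samples.
#' @param cfg a [swim_config()].
#' @return list `(total_distance_mm, time_immobile_s, time_low_s,
#'   time_medium_s, time_high_s, duration_s, bins)` where `bins` is a
#'   per-integration-bin data.frame of the same quantities.
#' @export
summarize_trajectory <- function(positions, cfg = swim_config()) {
  stopifnot(inherits(cfg, "swim_config"))
  if (nrow(positions) < 2L) stop("need at least 2 samples")
  dt <- diff(positions$t_s)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  step <- sqrt(diff(positions$x_mm)^2 + diff(positions$y_mm)^2)
  speed <- step / dt
  state <- cut(speed,
               c(-Inf, cfg$motion_floor, cfg$inactive_threshold,
                 cfg$high_threshold, Inf),
               labels = c("immobile", "low", "medium", "high"),
               right = FALSE)
  state[speed == 0] <- "immobile"
  bin <- floor(positions$t_s[-nrow(positions)] / cfg$integration_s)
  per_bin <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b,
               t_start_s = b * cfg$integration_s,
               distance_mm = sum(step[i]),
               time_immobile_s = sum(dt[i][state[i] == "immobile"]),
               time_low_s = sum(dt[i][state[i] == "low"]),
               time_medium_s = sum(dt[i][state[i] == "medium"]),
               time_high_s = sum(dt[i][state[i] == "high"]))
  }))
  list(total_distance_mm = sum(step),
       time_immobile_s = sum(dt[state == "immobile"]),
       time_low_s = sum(dt[state == "low"]),
       time_medium_s = sum(dt[state == "medium"]),
       time_high_s = sum(dt[state == "high"]),
       duration_s = positions$t_s[nrow(positions)] - positions$t_s[1],
       bins = per_bin)
}

#' Score a plate of larva trajectories
#'
#' @param plate non-empty list of trajectories (see
#'   [summarize_trajectory()]), optionally named by larva id.
#' @param cfg a [swim_config()].
#' @return list with `per_larva` (one row each) and `group` (mean and sem
#'   of each metric).
#' @export
batch_summarize <- function(plate, cfg = swim_config()) {
  if (length(plate) == 0L) stop("empty plate")
  ids <- names(plate) %||% as.character(seq_along(plate))
  per <- do.call(rbind, lapply(seq_along(plate), function(i) {
    s <- summarize_trajectory(plate[[i]], cfg)
    data.frame(larva = ids[i], total_distance_mm = s$total_distance_mm,
               time_immobile_s = s$time_immobile_s,
               time_low_s = s$time_low_s, time_medium_s = s$time_medium_s,
               time_high_s = s$time_high_s, duration_s = s$duration_s)
  }))
  num <- per[, -1]
  sem <- function(x) if (length(x) > 1) sd(x) / sqrt(length(x)) else 0
  group <- data.frame(metric = names(num),
                      n = nrow(per),
                      mean = vapply(num, mean, numeric(1)),
                      sem = vapply(num, sem, numeric(1)),
                      row.names = NULL)
  list(per_larva = per, group = group)
}
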