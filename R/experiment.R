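#' Default configuration for the end-to-end synthetic experiment
#'
#' Two genotypes (wild-type `wt` and `scn1lab` knockdown `kd`) crossed with
#' microglia status (`present` / `depleted`). Per-condition targets default
#' to the group means of the study system: amoeboid microglia fraction
#' 0.104 vs 0.291, calcium events per hour 16.5 vs 32.2, LFP events per
#' hour 4.8 vs 28.2, and 30-min swim distance 212 vs 355 mm, with further
#' increases in the microglia-depleted epileptic condition. Problem sizes
#' (cells per genotype, larvae per condition, trace lengths) are chosen for
#' desk-scale runs; see the methods vignette.
#'
#' @param zero_effect when `TRUE`, every condition uses the wild-type
#'   parameters (for type-I error checks).
#' @return Nested configuration list.
#' @export
default_experiment_config <- function(zero_effect = FALSE) {
  cfg <- list(
    morpho = list(
      n_cells = 200, voxel_size = 1.25,
      mix = list(
        wt = c(branched = 0.278, amoeboid = 0.104, transitional = 0.618),
        kd = c(branched = 0.102, amoeboid = 0.291, transitional = 0.607))),
    calcium = list(
      n_larvae = 8, duration_min = 40, frame_interval_s = 1,
      events_per_hour = c(wt = 16.5, kd = 32.2,
                          wt_depleted = 22, kd_depleted = 45),
      peak_dff = c(0.06, 0.12), noise_sigma_dff = 0.005,
      drift_frac_per_hour = 0.1, decay_tau = 10,
      threshold = 0.04, min_separation_frames = 5),
    lfp = list(
      n_larvae = 5, duration_min = 30, sampling_interval_s = 4e-3,
      events_per_hour = c(wt = 4.8, kd = 28.2,
                          wt_depleted = 9, kd_depleted = 45),
      amplitude_mv = c(-1.0, -0.4), duration_ms = c(150, 600),
      noise_sigma_mv = 0.05, hp_hz = 0.1, lp_hz = 100,
      amp_threshold_mv = -0.3, min_dur_ms = 100, merge_gap_ms = 20),
    swim = list(
      n_larvae = 16, duration_min = 30, dt_s = 1,
      distance_mm = c(wt = 212, kd = 355,
                      wt_depleted = 240, kd_depleted = 423),
      distance_sd_mm = 44),
    alpha = 0.05)
  if (zero_effect) {
    cfg$morpho$mix$kd <- cfg$morpho$mix$wt
    for (blk in c("calcium", "lfp"))
      cfg[[blk]]$events_per_hour[] <- cfg[[blk]]$events_per_hour[["wt"]]
    cfg$swim$distance_mm[] <- cfg$swim$distance_mm[["wt"]]
  }
  cfg
}

validate_experiment_config <- function(config) {
  need <- list(
    morpho = c("n_cells", "voxel_size", "mix"),
    calcium = c("n_larvae", "duration_min", "frame_interval_s",
                "events_per_hour", "peak_dff", "noise_sigma_dff",
                "drift_frac_per_hour", "decay_tau", "threshold",
                "min_separation_frames"),
    lfp = c("n_larvae", "duration_min", "sampling_interval_s",
            "events_per_hour", "amplitude_mv", "duration_ms",
            "noise_sigma_mv", "hp_hz", "lp_hz", "amp_threshold_mv",
            "min_dur_ms", "merge_gap_ms"),
    swim = c("n_larvae", "duration_min", "dt_s", "distance_mm",
             "distance_sd_mm"))
  missing <- character(0)
  for (blk in names(need)) {
    if (is.null(config[[blk]])) { missing <- c(missing, blk); next }
    gone <- setdiff(need[[blk]], names(config[[blk]]))
    if (length(gone)) missing <- c(missing, paste(blk, gone, sep = "$"))
  }
  conds <- c("wt", "kd", "wt_depleted", "kd_depleted")
  for (blk in c("calcium", "lfp"))
    if (!is.null(config[[blk]]$events_per_hour) &&
        !all(conds %in% names(config[[blk]]$events_per_hour)))
      missing <- c(missing, paste0(blk, "$events_per_hour[", conds, "]"))
  if (length(missing))
    stop("invalid experiment config; missing keys: ",
         paste(unique(missing), collapse = ", "))
  invisible(config)
}

# sorted event times with a minimum separation, by rejection (falls back to
# jittered even spacing when the draw is too dense to place randomly)
spaced_times <- function(n, t_max, min_gap) {
  if (n == 0) return(numeric(0))
  for (try in 1:50) {
    t <- sort(runif(n, 0, t_max - min_gap))
    if (n == 1 || all(diff(t) >= min_gap)) return(t)
  }
  sort((seq_len(n) - runif(n, 0.2, 0.8)) * (t_max / (n + 1)))
}

experiment_conditions <- function() {
  data.frame(condition = c("wt", "kd", "wt_depleted", "kd_depleted"),
             genotype = c("wt", "kd", "wt", "kd"),
             microglia = c("present", "present", "depleted", "depleted"))
}

#' Run the full synthetic experiment
#'
#' Generates synthetic microglia populations, calcium traces, LFP traces
#' and larva trajectories for the 2 x 2 genotype x microglia design of the
#' configuration, runs every analysis stage of the package on them, and
#' returns per-figure-analog tables plus the group statistics. Fully
#' deterministic for a given `(config, seed)`.
#'
#' @param config configuration list, see [default_experiment_config()].
#' @param seed integer seed.
#' @param out_dir optional directory; when given, all tables are written as
#'   CSV and a run summary as JSON.
#' @return List with elements `morphology`, `classification`, `calcium`,
#'   `lfp`, `swim`, `comparisons`, `factorial`, `thresholds`, `seed`.
#' @export
run_synthetic_experiment <- function(config = default_experiment_config(),
                                     seed = 1L, out_dir = NULL) {
  validate_experiment_config(config)
  conds <- experiment_conditions()

  ## -- microglia morphology + classification (microglia-present genotypes)
  morpho <- list()
  class_counts <- list()
  for (g in c("wt", "kd")) {
    pop <- gen_population(config$morpho$mix[[g]], config$morpho$n_cells,
                          seed = derive_seed(seed, match(g, c("wt", "kd"))),
                          voxel_size = config$morpho$voxel_size)
    tab <- morphology_table(pop)
    cls <- classify_population(tab)
    tab <- cls$table
    tab$genotype <- g
    morpho[[g]] <- list(table = tab, proportions = cls$proportions)
    class_counts[[g]] <- table(factor(tab$label, morph_class_levels()))
  }

  ## -- calcium imaging
  ca_cfg <- config$calcium
  n_frames <- round(ca_cfg$duration_min * 60 / ca_cfg$frame_interval_s)
  calcium <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
    cond <- conds$condition[ci]
    rate_h <- ca_cfg$events_per_hour[[cond]]
    do.call(rbind, lapply(seq_len(ca_cfg$n_larvae), function(li) {
      sd <- derive_seed(seed, 100 + 10 * ci + li)
      set.seed(sd)
      n_ev <- rpois(1, rate_h * ca_cfg$duration_min / 60)
      onsets <- sort(unique(pmax(1, round(
        spaced_times(n_ev, n_frames - 3 * ca_cfg$decay_tau,
                     3 * ca_cfg$decay_tau)))))
      truth <- calcium_truth(
        event_onsets = onsets,
        event_peak_dff = runif(length(onsets), ca_cfg$peak_dff[1],
                               ca_cfg$peak_dff[2]),
        baseline = 100,
        drift_slope = runif(1, -1, 1) * ca_cfg$drift_frac_per_hour * 100 /
          (3600 / ca_cfg$frame_interval_s),
        noise_sigma = ca_cfg$noise_sigma_dff * 100,
        decay_tau = ca_cfg$decay_tau)
      tr <- gen_calcium_trace(n_frames, truth, seed = derive_seed(sd, 1),
                              frame_interval_s = ca_cfg$frame_interval_s)
      ev <- detect_events(correct_drift(tr),
                          threshold = ca_cfg$threshold,
                          min_separation_frames = ca_cfg$min_separation_frames)
      st <- event_stats(ev, ca_cfg$duration_min * 60)
      data.frame(condition = cond, genotype = conds$genotype[ci],
                 microglia = conds$microglia[ci], larva = li,
                 n_true = length(onsets), n_events = st$count,
                 rate_per_min = st$rate_per_min,
                 mean_amplitude = st$mean_amplitude)
    }))
  }))

  ## -- LFP
  lf_cfg <- config$lfp
  dur_s <- lf_cfg$duration_min * 60
  lfp <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
    cond <- conds$condition[ci]
    rate_h <- lf_cfg$events_per_hour[[cond]]
    do.call(rbind, lapply(seq_len(lf_cfg$n_larvae), function(li) {
      sd <- derive_seed(seed, 500 + 10 * ci + li)
      set.seed(sd)
      n_ev <- rpois(1, rate_h * lf_cfg$duration_min / 60)
      starts <- spaced_times(n_ev, dur_s - 1,
                             lf_cfg$duration_ms[2] / 1000 + 1)
      truth <- lfp_truth(
        event_starts = starts,
        event_durations = runif(length(starts), lf_cfg$duration_ms[1],
                                lf_cfg$duration_ms[2]),
        event_amplitudes = runif(length(starts), lf_cfg$amplitude_mv[1],
                                 lf_cfg$amplitude_mv[2]),
        noise_sigma = lf_cfg$noise_sigma_mv)
      rec <- gen_lfp(dur_s, lf_cfg$sampling_interval_s, truth,
                     seed = derive_seed(sd, 1))
      ev <- detect_lfp_events(bandpass(rec, lf_cfg$hp_hz, lf_cfg$lp_hz),
                              amp_mv = lf_cfg$amp_threshold_mv,
                              min_dur_ms = lf_cfg$min_dur_ms,
                              merge_gap_ms = lf_cfg$merge_gap_ms)
      st <- lfp_stats(ev, dur_s)
      data.frame(condition = cond, genotype = conds$genotype[ci],
                 microglia = conds$microglia[ci], larva = li,
                 n_true = length(starts), n_events = st$count,
                 rate_per_min = st$rate_per_min,
                 mean_abs_amplitude_mv = st$mean_abs_amplitude_mv)
    }))
  }))

  ## -- locomotion
  sw_cfg <- config$swim
  n_min <- sw_cfg$duration_min
  swim <- do.call(rbind, lapply(seq_len(nrow(conds)), function(ci) {
    cond <- conds$condition[ci]
    do.call(rbind, lapply(seq_len(sw_cfg$n_larvae), function(li) {
      sd <- derive_seed(seed, 900 + 20 * ci + li)
      set.seed(sd)
      D <- max(10, rnorm(1, sw_cfg$distance_mm[[cond]],
                         sw_cfg$distance_sd_mm))
      w <- rexp(n_min)
      segs <- cbind(60, (D * w / sum(w)) / 60)
      traj <- gen_trajectory(asplit(segs, 1), dt_s = sw_cfg$dt_s,
                             seed = derive_seed(sd, 1))
      s <- summarize_trajectory(traj)
      data.frame(condition = cond, genotype = conds$genotype[ci],
                 microglia = conds$microglia[ci], larva = li,
                 total_distance_mm = s$total_distance_mm,
                 time_immobile_s = s$time_immobile_s,
                 time_low_s = s$time_low_s, time_medium_s = s$time_medium_s,
                 time_high_s = s$time_high_s)
    }))
  }))

  ## -- statistics (wt vs kd, microglia present)
  n_cells <- config$morpho$n_cells
  amo <- vapply(class_counts, function(ct) ct[["amoeboid"]], numeric(1))
  bra <- vapply(class_counts, function(ct) ct[["branched"]], numeric(1))
  prop_cmp <- function(x, metric) {
    pt <- suppressWarnings(prop.test(x, c(n_cells, n_cells)))
    list(metric = metric, test = "two-proportion",
         groups = data.frame(group = c("wt", "kd"), n = n_cells,
                             mean = 100 * x / n_cells, sem = NA),
         statistic = unname(pt$statistic), p_value = pt$p.value)
  }
  pick <- function(df, cond) df[df$condition == cond, ]
  comparisons <- list(
    amoeboid_fraction = prop_cmp(amo, "amoeboid cell fraction (%)"),
    branched_fraction = prop_cmp(bra, "branched cell fraction (%)"),
    calcium_events = compare_two_groups(
      pick(calcium, "wt")$n_events, pick(calcium, "kd")$n_events,
      labels = c("wt", "kd"), metric = "calcium events per recording"),
    lfp_events = compare_two_groups(
      pick(lfp, "wt")$n_events, pick(lfp, "kd")$n_events,
      labels = c("wt", "kd"), metric = "LFP events per recording"),
    swim_distance = compare_two_groups(
      pick(swim, "wt")$total_distance_mm,
      pick(swim, "kd")$total_distance_mm,
      labels = c("wt", "kd"), metric = "total distance (mm)"))

  factorial <- list(
    calcium_events = compare_factorial(calcium, "n_events", "genotype",
                                       "microglia"),
    lfp_events = compare_factorial(lfp, "n_events", "genotype", "microglia"),
    swim_distance = compare_factorial(swim, "total_distance_mm", "genotype",
                                      "microglia"))

  thresholds <- list(
    classifier = unclass(classifier_rule()),
    calcium_dff_threshold = ca_cfg$threshold,
    lfp_amplitude_mv = lf_cfg$amp_threshold_mv,
    lfp_min_duration_ms = lf_cfg$min_dur_ms,
    swim_inactive_mm_s = swim_config()$inactive_threshold,
    swim_high_mm_s = swim_config()$high_threshold,
    n_comparisons = length(comparisons))

  out <- list(seed = seed, config = config,
              morphology = rbind(morpho$wt$table, morpho$kd$table),
              classification = list(wt = morpho$wt$proportions,
                                    kd = morpho$kd$proportions),
              calcium = calcium, lfp = lfp, swim = swim,
              comparisons = comparisons, factorial = factorial,
              thresholds = thresholds)
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(df, name)
    write.csv(df, file.path(out_dir, paste0(name, ".csv")),
              row.names = FALSE)
  wr(result$morphology, "morphology")
  wr(result$calcium, "calcium_events")
  wr(result$lfp, "lfp_events")
  wr(result$swim, "swim_summary")
  cmp <- do.call(rbind, lapply(names(result$comparisons), function(nm) {
    c <- result$comparisons[[nm]]
    data.frame(comparison = nm, metric = c$metric %||% nm, test = c$test,
               mean_wt = c$groups$mean[1], mean_kd = c$groups$mean[2],
               p_value = c$p_value)
  }))
  wr(cmp, "comparisons")
  jsonlite::write_json(
    list(seed = result$seed, classification = result$classification,
         thresholds = result$thresholds),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(out_dir)
}
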