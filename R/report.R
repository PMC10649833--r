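# Session serialization and analysis-ready exports: spider-plot tables,
# hand-path 2-D histograms, normalized joint-path tables, and the
# simulate/analyze drivers the analysis scripts wrap.

session_stem <- function(session) {
  paste(session$participant_id, session$side, session$timepoint, sep = "_")
}

#' Write one session to disk
#'
#' One JSON header (participant, side, timepoint, arm, FMA-UE, seed), one
#' delimited per-millisecond samples table and one per-trial events table.
#'
#' @param session A `participant_session`.
#' @param dir Output directory (created if needed).
#' @return The header path, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- session_stem(session)
  header <- list(participant = session$participant_id,
                 side = session$side,
                 timepoint = session$timepoint,
                 recorded_arm = session$recorded_arm,
                 fma_ue = session$fma_ue,
                 seed = session$seed,
                 n_trials = length(session$trials))
  hp <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(header, hp, auto_unbox = TRUE, digits = NA)
  samples <- data.table::rbindlist(lapply(session$trials, function(tr) {
    data.table::data.table(trial = tr$trial_index, t_ms = tr$t,
                           x_cm = tr$x, y_cm = tr$y,
                           shoulder_deg = tr$shoulder_deg,
                           elbow_deg = tr$elbow_deg)
  }))
  data.table::fwrite(samples, file.path(dir, paste0(stem, "_samples.csv")))
  events <- data.table::rbindlist(lapply(session$trials, function(tr) {
    data.table::data.table(
      trial = tr$trial_index,
      scheduled_target = tr$scheduled_target,
      target = tr$target,
      target_onset_ms = tr$target_onset_time,
      left_center = tr$left_center,
      reached_target = tr$reached_target,
      reach_duration_ms = tr$reach_duration,
      outcome = tr$outcome
    )
  }))
  data.table::fwrite(events, file.path(dir, paste0(stem, "_events.csv")))
  invisible(hp)
}

#' Read one session back from disk
#'
#' @param header_path Path to the session's JSON header.
#' @param config A [task_config()] (used for target positions).
#' @return A `participant_session`.
#' @export
read_session <- function(header_path, config = task_config()) {
  h <- jsonlite::read_json(header_path, simplifyVector = TRUE)
  stem <- sub("\\.json$", "", header_path)
  samples <- data.table::fread(paste0(stem, "_samples.csv"), data.table = FALSE)
  events <- data.table::fread(paste0(stem, "_events.csv"), data.table = FALSE,
                              na.strings = c("NA", ""))
  trials <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    s <- samples[samples$trial == ev$trial, ]
    # labels in the events table are already in the recorded frame
    tgt <- if (is.na(ev$target)) {
      target_xy(ev$scheduled_target, config)
    } else target_xy(ev$target, config)
    structure(list(
      trial_index = as.integer(ev$trial),
      scheduled_target = ev$scheduled_target,
      target = if (is.na(ev$target)) NA_character_ else ev$target,
      t = as.integer(s$t_ms),
      # coordinates are quantized by construction; snap parsed values back
      # onto the grid so reloaded sessions are bit-identical
      x = quantize(s$x_cm, config$spatial_resolution),
      y = quantize(s$y_cm, config$spatial_resolution),
      shoulder_deg = s$shoulder_deg, elbow_deg = s$elbow_deg,
      start_xy = c(0, 0),
      target_xy = tgt,
      target_onset_time = if (is.na(ev$target_onset_ms)) NA_integer_ else
        as.integer(ev$target_onset_ms),
      left_center = isTRUE(ev$left_center),
      reached_target = isTRUE(ev$reached_target),
      reach_duration = if (is.na(ev$reach_duration_ms)) NA_integer_ else
        as.integer(ev$reach_duration_ms),
      outcome = ev$outcome,
      recorded_arm = h$recorded_arm
    ), class = "reach_trial")
  })
  structure(list(participant_id = h$participant, side = h$side,
                 timepoint = h$timepoint, recorded_arm = h$recorded_arm,
                 fma_ue = as.integer(h$fma_ue), seed = as.integer(h$seed),
                 trials = trials),
            class = "participant_session")
}

#' Simulate a cohort and write it to disk
#'
#' Writes all session files plus a cohort manifest CSV (one row per
#' session: participant, group, side, timepoint, arm, FMA-UE, session seed,
#' header file).
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory.
#' @param config A [task_config()].
#' @param geometry An [arm_geometry()].
#' @return The cohort, invisibly; the manifest is
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
run_simulate <- function(spec = cohort_spec(), out_dir,
                         config = task_config(), geometry = arm_geometry()) {
  cohort <- simulate_cohort(spec, config, geometry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- data.table::rbindlist(lapply(cohort$sessions, function(s) {
    hp <- write_session(s, out_dir)
    data.table::data.table(
      participant = s$participant_id,
      group = cohort$roster$group[match(s$participant_id,
                                        cohort$roster$participant)],
      side = s$side, timepoint = s$timepoint,
      recorded_arm = s$recorded_arm, fma_ue = s$fma_ue,
      seed = s$seed, header = basename(hp))
  }))
  data.table::fwrite(manifest, file.path(out_dir, "manifest.csv"))
  data.table::fwrite(cohort$roster, file.path(out_dir, "roster.csv"))
  message("wrote ", length(cohort$sessions), " sessions (",
          nrow(cohort$roster), " participants) to ", out_dir)
  invisible(cohort)
}

#' Read a cohort written by [run_simulate()]
#'
#' @param dir Cohort directory containing `manifest.csv` and `roster.csv`.
#' @param config A [task_config()].
#' @return A `reach_cohort`.
#' @export
read_cohort <- function(dir, config = task_config()) {
  manifest <- data.table::fread(file.path(dir, "manifest.csv"),
                                data.table = FALSE)
  roster <- data.table::fread(file.path(dir, "roster.csv"), data.table = FALSE)
  sessions <- lapply(manifest$header, function(h) {
    read_session(file.path(dir, h), config)
  })
  structure(list(spec = NULL, config = config, geometry = arm_geometry(),
                 roster = roster, sessions = sessions),
            class = "reach_cohort")
}

#' Direction x side x time summary for spider plots
#'
#' Group means and standard errors of the mean across participants for
#' each quality metric and direction, the table behind the spider plots.
#'
#' @param cohort_table An [aggregate_quality()] table.
#' @return A data.frame: metric, direction, side, timepoint, n, mean, sem.
#' @export
spider_table <- function(cohort_table) {
  key <- interaction(cohort_table$metric, cohort_table$direction,
                     cohort_table$side, cohort_table$timepoint, drop = TRUE)
  rows <- lapply(split(cohort_table, key), function(s) {
    data.frame(metric = s$metric[1], direction = s$direction[1],
               side = s$side[1], timepoint = s$timepoint[1],
               n = nrow(s), mean = mean(s$value),
               sem = stats::sd(s$value) / sqrt(nrow(s)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$metric, out$side, out$timepoint,
            match(out$direction, direction_labels())), ]
}

#' Hand-path 2-D histogram counts
#'
#' Bins the post-illumination hand positions of quantity-qualified trials
#' into square bins centred on the start position, pooled by side and
#' timepoint — the data behind hand-path colormap displays.
#'
#' @param cohort A `reach_cohort`.
#' @param group Participant group retained.
#' @param bin_cm Bin side, cm.
#' @param half_width_cm Window half-width, cm.
#' @param config A [task_config()].
#' @return A data.frame of non-empty bins: side, timepoint, x_bin, y_bin
#'   (bin centres, cm), count; total retained samples in
#'   `attr(, "n_samples")`.
#' @export
hand_path_histogram <- function(cohort, group = "moderate_to_severe",
                                bin_cm = 0.25, half_width_cm = 14,
                                config = cohort$config) {
  breaks <- seq(-half_width_cm, half_width_cm, by = bin_cm)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  keep <- cohort$roster$participant[cohort$roster$group %in% group]
  out <- list(); n_samples <- 0L
  for (s in cohort$sessions) {
    if (!(s$participant_id %in% keep)) next
    s <- mirror_session_to_left(s)
    qn <- qualify_quantity(s, config)
    for (i in qn$included) {
      tr <- s$trials[[i]]
      idx <- (tr$target_onset_time + 1):length(tr$x)
      x <- tr$x[idx]; y <- tr$y[idx]
      ok <- abs(x) < half_width_cm & abs(y) < half_width_cm
      x <- x[ok]; y <- y[ok]
      n_samples <- n_samples + length(x)
      ix <- findInterval(x, breaks, rightmost.closed = TRUE)
      iy <- findInterval(y, breaks, rightmost.closed = TRUE)
      key <- paste(s$side, s$timepoint, ix, iy)
      tb <- table(key)
      out[[length(out) + 1L]] <- data.frame(key = names(tb),
                                            count = as.integer(tb),
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) stop("no quantity-qualified trials to bin")
  all <- do.call(rbind, out)
  ag <- stats::aggregate(count ~ key, data = all, FUN = sum)
  parts <- do.call(rbind, strsplit(ag$key, " ", fixed = TRUE))
  res <- data.frame(side = parts[, 1], timepoint = parts[, 2],
                    x_bin = mids[as.integer(parts[, 3])],
                    y_bin = mids[as.integer(parts[, 4])],
                    count = ag$count, stringsAsFactors = FALSE)
  attr(res, "n_samples") <- n_samples
  res[order(res$side, res$timepoint, res$x_bin, res$y_bin), ]
}

#' Mean normalized joint paths per direction, side and timepoint
#'
#' Resamples each quality-qualified trial's shoulder/elbow delta angles to
#' a 0--100% grid and averages across trials and participants of the mild
#' group — the data behind interjoint-coordination displays.
#'
#' @param cohort A `reach_cohort`.
#' @param group Participant group retained.
#' @param config A [task_config()].
#' @param grid_size Grid length.
#' @return A data.frame: side, timepoint, direction, percent,
#'   shoulder_delta, elbow_delta, n_trials.
#' @export
joint_path_table <- function(cohort, group = "mild", config = cohort$config,
                             grid_size = 101) {
  keep <- cohort$roster$participant[cohort$roster$group %in% group]
  acc <- list()
  for (s in cohort$sessions) {
    if (!(s$participant_id %in% keep)) next
    s <- mirror_session_to_left(s)
    qq <- qualify_quality(s, config)
    if (!length(qq$included)) next
    thr <- compute_thresholds(s, config)
    for (i in qq$included) {
      tr <- s$trials[[i]]
      onset <- as.integer(detect_onset(tr, thr, config))
      offset <- detect_offset(tr, config)
      if (offset <= onset) next
      nj <- resample_joint_angles(tr, onset, offset, grid_size)
      nj$side <- s$side; nj$timepoint <- s$timepoint; nj$direction <- tr$target
      acc[[length(acc) + 1L]] <- nj
    }
  }
  if (!length(acc)) stop("no quality-qualified trials for joint paths")
  all <- as.data.frame(data.table::rbindlist(acc))
  ag <- stats::aggregate(cbind(shoulder_delta, elbow_delta) ~
                           side + timepoint + direction + percent,
                         data = all, FUN = mean)
  cnt <- stats::aggregate(shoulder_delta ~ side + timepoint + direction,
                          data = all[all$percent == 0, ], FUN = length)
  names(cnt)[4] <- "n_trials"
  out <- merge(ag, cnt, by = c("side", "timepoint", "direction"))
  out[order(out$side, out$timepoint,
            match(out$direction, direction_labels()), out$percent), ]
}

#' Run the full analysis over a cohort
#'
#' Computes per-trial metrics, qualification reports, the aggregated
#' quality and quantity tables, the three repeated-measures ANOVAs, the
#' mixed model of the mediolateral proportion, the FMA-UE paired t tests,
#' and the figure-data tables; optionally writes everything as CSV (plus a
#' JSON sidecar with ANOVA/LMM diagnostics) under `out_dir`.
#'
#' @param cohort A `reach_cohort`.
#' @param out_dir Optional output directory.
#' @param config A [task_config()].
#' @return A list of all result objects.
#' @export
run_analyze <- function(cohort, out_dir = NULL, config = cohort$config) {
  metrics <- cohort_metrics(cohort, config)
  qual_reports <- do.call(rbind, lapply(cohort$sessions, function(s) {
    rbind(qualification_row(qualify_quality(s, config)$report),
          qualification_row(qualify_quantity(s, config)$report))
  }))
  qual_reports$group <- cohort$roster$group[match(qual_reports$participant,
                                                 cohort$roster$participant)]
  quality_tab <- aggregate_quality(metrics)
  quantity_tab <- aggregate_quantity(metrics)
  anovas <- lapply(stats::setNames(nm = c("path_length", "movement_time",
                                          "n_velocity_peaks")),
                   function(m) rm_anova_3way(quality_tab, m))
  lmm <- fit_lmm_proportion(quantity_tab)
  fma <- fma_paired_tests(cohort$roster)
  spider <- spider_table(quality_tab)
  hist2d <- hand_path_histogram(cohort, config = config)
  joint_paths <- joint_path_table(cohort, config = config)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(x, f) data.table::fwrite(as.data.frame(x),
                                            file.path(out_dir, f))
    wr(qual_reports, "qualification_reports.csv")
    wr(quality_tab, "quality_cell_means.csv")
    wr(quantity_tab, "quantity_ml_proportions.csv")
    for (m in names(anovas)) wr(anovas[[m]], paste0("anova_", m, ".csv"))
    wr(lmm$anova, "lmm_ml_proportion.csv")
    wr(lmm$fixed, "lmm_ml_proportion_fixed.csv")
    wr(fma, "fma_paired_t.csv")
    wr(spider, "spider_table.csv")
    wr(hist2d, "hand_path_histogram.csv")
    wr(joint_paths, "joint_path_table.csv")
    diag <- list(
      anova = lapply(anovas, function(a) {
        list(metric = attr(a, "metric"),
             alpha = attr(a, "alpha"),
             effects = as.data.frame(a))
      }),
      lmm = list(varcor = as.list(lmm$varcor), logLik = lmm$logLik,
                 singular = lmm$singular, df_method = lmm$df_method)
    )
    jsonlite::write_json(diag, file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message("analysis tables written to ", out_dir)
  }
  invisible(list(metrics = metrics, qualification = qual_reports,
                 quality_table = quality_tab, quantity_table = quantity_tab,
                 anovas = anovas, lmm = lmm, fma = fma, spider = spider,
                 hand_path_histogram = hist2d, joint_paths = joint_paths))
}
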