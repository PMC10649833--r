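# Per-trial movement parameters: hand speed, session speed thresholds,
# dual-threshold backward-search onset detection, target-entry offset,
# path length, zero-phase Butterworth filtering, velocity-peak counting,
# AP/ML displacement decomposition and joint-angle time normalization.

#' Hand speed from a position series
#'
#' Magnitude of the central-difference velocity (forward/backward
#' differences at the series ends); same length as the input.
#'
#' @param x,y Position series, cm.
#' @param rate Sampling rate, Hz.
#' @return Speed series, cm/s.
#' @export
compute_speed <- function(x, y, rate = 1000) {
  n <- length(x)
  if (n < 3) stop("compute_speed needs at least 3 samples")
  vx <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) * rate
  vy <- c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) * rate
  sqrt(vx^2 + vy^2)
}

trial_speed <- function(trial, rate) compute_speed(trial$x, trial$y, rate)

#' Session speed thresholds for movement-onset detection
#'
#' Pools the per-millisecond hand speed from the 500-ms windows immediately
#' preceding each target illumination, across all trials of the session in
#' which a target appeared. The lower threshold is the pooled median and
#' the upper threshold the pooled 95th percentile (linear-interpolation
#' percentile). `method = "per_trial_median"` instead takes the median of
#' per-trial medians / 95th percentiles.
#'
#' @param session A `participant_session`.
#' @param config A [task_config()].
#' @param window_ms Pre-illumination window length, ms.
#' @param method Pooling rule.
#' @return A list with `lower` and `upper`, cm/s (class `speed_thresholds`).
#' @export
compute_thresholds <- function(session, config = task_config(),
                               window_ms = 500,
                               method = c("pooled", "per_trial_median")) {
  method <- match.arg(method)
  rate <- config$sample_rate
  win <- lapply(session$trials, function(tr) {
    if (is.na(tr$target) || is.na(tr$target_onset_time)) return(NULL)
    illum <- tr$target_onset_time
    if (illum < window_ms) return(NULL)
    sp <- trial_speed(tr, rate)
    sp[(illum - window_ms + 1):illum]
  })
  win <- Filter(Negate(is.null), win)
  if (!length(win)) stop("no trial with a target and a full pre-illumination window")
  if (method == "pooled") {
    pool <- unlist(win)
    lower <- unname(stats::quantile(pool, 0.5, type = 7))
    upper <- unname(stats::quantile(pool, 0.95, type = 7))
  } else {
    lower <- stats::median(vapply(win, stats::median, numeric(1)))
    upper <- stats::median(vapply(win, function(w)
      unname(stats::quantile(w, 0.95, type = 7)), numeric(1)))
  }
  if (lower > upper) stop("invalid thresholds: lower exceeds upper")
  structure(list(lower = lower, upper = upper), class = "speed_thresholds")
}

#' Time at which the hand leaves the central target
#'
#' First post-illumination sample whose distance from the start exceeds the
#' configured leave threshold.
#'
#' @param trial A `reach_trial`.
#' @param config A [task_config()].
#' @return Time, ms, or `NA` if the hand never leaves.
#' @export
detect_t_leave <- function(trial, config = task_config()) {
  if (is.na(trial$target_onset_time)) return(NA_integer_)
  illum <- trial$target_onset_time
  thr <- left_center_threshold(config)
  idx <- (illum + 1):length(trial$x)
  d <- sqrt((trial$x[idx] - trial$start_xy[1])^2 +
              (trial$y[idx] - trial$start_xy[2])^2)
  i <- which(d > thr)[1]
  if (is.na(i)) NA_integer_ else as.integer(illum + i - 1)
}

#' Movement onset by dual-threshold backward search
#'
#' Starting from the sample at which the hand leaves the central target,
#' the speed trace is reviewed in reverse toward the illumination time; the
#' onset is the first sample encountered that is either a strict local
#' minimum of (unfiltered) speed below the upper threshold, or a sample
#' with speed below the lower threshold. If the scan reaches the
#' illumination time without meeting either criterion the illumination
#' time is returned (fallback, recorded in the `fallback` attribute).
#'
#' @param trial A `reach_trial` in which a target appeared and the hand
#'   left the centre.
#' @param thresholds A [compute_thresholds()] result.
#' @param config A [task_config()].
#' @return Onset time, ms.
#' @export
detect_onset <- function(trial, thresholds, config = task_config()) {
  if (is.na(trial$target)) {
    stop("trial ", trial$trial_index, ": no target appeared; onset undefined")
  }
  t_leave <- detect_t_leave(trial, config)
  if (is.na(t_leave)) {
    stop("trial ", trial$trial_index, ": hand never left the centre; onset undefined")
  }
  sp <- trial_speed(trial, config$sample_rate)
  illum <- trial$target_onset_time
  i_lo <- illum + 1L          # index of the illumination sample
  i_hi <- t_leave + 1L        # index of the leave sample
  j <- i_lo:i_hi
  n <- length(sp)
  jm <- pmax(j - 1L, 1L); jp <- pmin(j + 1L, n)
  local_min <- sp[j] < sp[jm] & sp[j] < sp[jp]
  hit <- (local_min & sp[j] < thresholds$upper) | (sp[j] < thresholds$lower)
  if (any(hit)) {
    onset <- as.integer(j[max(which(hit))] - 1L)
    attr(onset, "fallback") <- FALSE
  } else {
    onset <- as.integer(illum)
    attr(onset, "fallback") <- TRUE
  }
  onset
}

#' Movement offset at target entry
#'
#' First post-illumination sample at which the cursor is inside the
#' peripheral target under the configured entry rule.
#'
#' @param trial A `reach_trial` with `reached_target` set.
#' @param config A [task_config()].
#' @return Offset time, ms.
#' @export
detect_offset <- function(trial, config = task_config()) {
  if (!isTRUE(trial$reached_target)) {
    stop("trial ", trial$trial_index,
         ": target never entered; offset undefined (trial should have been excluded)")
  }
  illum <- trial$target_onset_time
  idx <- (illum + 1):length(trial$x)
  d <- sqrt((trial$x[idx] - trial$target_xy[1])^2 +
              (trial$y[idx] - trial$target_xy[2])^2)
  i <- which(d <= target_entry_radius(config))[1]
  if (is.na(i)) stop("trial ", trial$trial_index, ": no entry sample found")
  as.integer(illum + i - 1)
}

#' Hand path length between onset and offset
#'
#' Sum of Euclidean norms of successive sample displacements over
#' `[onset, offset]`.
#'
#' @param trial A `reach_trial` (or any list with `t`, `x`, `y`).
#' @param onset,offset Window bounds, ms.
#' @return Length, cm.
#' @export
path_length <- function(trial, onset, offset) {
  stopifnot(onset <= offset)
  i0 <- match(onset, trial$t); i1 <- match(offset, trial$t)
  if (is.na(i0) || is.na(i1)) stop("onset/offset outside the recorded series")
  if (i1 == i0) return(0)
  idx <- i0:i1
  sum(sqrt(diff(trial$x[idx])^2 + diff(trial$y[idx])^2))
}

#' Zero-phase low-pass filtering of a speed series
#'
#' Butterworth design applied forward and backward (`signal::filtfilt`),
#' giving a zero-phase response whose magnitude is the square of the
#' single-pass filter — an order-3 design double-passed yields the
#' sixth-order magnitude response used for velocity-peak counting
#' (10-Hz cutoff by default).
#'
#' @param speed Speed series, cm/s.
#' @param rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz.
#' @param order Single-pass filter order.
#' @return Filtered series, same length.
#' @export
filter_speed <- function(speed, rate = 1000, cutoff = 10, order = 3) {
  n <- length(speed)
  if (n < 24) {
    stop("series too short to filter (need at least 24 samples)")
  }
  key <- paste0("lp", rate, "_", cutoff, "_", order)
  if (is.null(.reachkin_cache[[key]])) {
    .reachkin_cache[[key]] <- signal::butter(order, cutoff / (rate / 2))
  }
  # de-mean (exact unit DC gain) and odd-reflection pad so start/end
  # transients are confined to the pads
  mu <- mean(speed)
  sp <- speed - mu
  npad <- min(n - 1, 500)
  padded <- c(2 * sp[1] - sp[(npad + 1):2],
              sp,
              2 * sp[n] - sp[(n - 1):(n - npad)])
  out <- as.numeric(signal::filtfilt(.reachkin_cache[[key]], padded))
  out[(npad + 1):(npad + n)] + mu
}

#' Count positive velocity peaks
#'
#' Number of samples within `[onset, offset]` strictly greater than both
#' immediate neighbours; no amplitude or spacing thresholds; window
#' endpoints are never peaks and plateaus are not extrema.
#'
#' @param fspeed Filtered speed series.
#' @param onset,offset Window bounds, ms.
#' @param t Time stamps of `fspeed` (defaults to 0-based ms).
#' @return Peak count.
#' @export
count_velocity_peaks <- function(fspeed, onset, offset,
                                 t = seq_along(fspeed) - 1) {
  stopifnot(onset < offset)
  i0 <- match(onset, t); i1 <- match(offset, t)
  if (is.na(i0) || is.na(i1)) stop("onset/offset outside the series")
  w <- fspeed[i0:i1]
  m <- length(w)
  if (m < 3) return(0L)
  j <- 2:(m - 1)
  sum(w[j] > w[j - 1] & w[j] > w[j + 1])
}

#' Anteroposterior and mediolateral total displacement
#'
#' Breaks per-millisecond movements into anteroposterior (y) and
#' mediolateral (x) components and sums the unsigned displacement of each
#' over the analysis span: from target illumination to the end of the
#' outbound reach phase (target entry, the reach limit, or the end of the
#' recorded excursion), or the whole recording with `span = "full"`.
#'
#' @param trial A `reach_trial` in which a target appeared and the hand
#'   left the centre.
#' @param config A [task_config()].
#' @param span `"outbound"` (default) or `"full"`.
#' @return Named vector `c(ap_total, ml_total)`, cm.
#' @export
displacement_components <- function(trial, config = task_config(),
                                    span = c("outbound", "full")) {
  span <- match.arg(span)
  if (is.na(trial$target)) {
    stop("trial ", trial$trial_index, ": no target appeared")
  }
  if (!isTRUE(trial$left_center)) {
    stop("trial ", trial$trial_index, ": hand never left the centre")
  }
  n <- length(trial$x)
  illum <- trial$target_onset_time
  i0 <- illum + 1L
  if (span == "full") {
    i1 <- n
  } else {
    idx <- i0:n
    d <- sqrt((trial$x[idx] - trial$target_xy[1])^2 +
                (trial$y[idx] - trial$target_xy[2])^2)
    i_entry <- which(d <= target_entry_radius(config))[1]
    i1 <- if (!is.na(i_entry)) i0 + i_entry - 1L else
      min(i0 + config$reach_limit, n)
  }
  idx <- i0:i1
  c(ap_total = sum(abs(diff(trial$y[idx]))),
    ml_total = sum(abs(diff(trial$x[idx]))))
}

#' Pooled mediolateral displacement proportion of one session
#'
#' Sums AP and ML displacement across a participant's qualified trials and
#' returns the mediolateral share as a percentage. Undefined (NA) when the
#' pooled total is zero, mirroring missing participants who could not
#' perform a single qualified trial.
#'
#' @param ap_totals,ml_totals Per-trial displacement sums, cm.
#' @return ML percentage of `AP + ML`, or `NA` if the total is zero.
#' @export
participant_ml_proportion <- function(ap_totals, ml_totals) {
  ap <- sum(ap_totals); ml <- sum(ml_totals)
  if (!length(ap_totals) || (ap + ml) <= 0) return(NA_real_)
  100 * ml / (ap + ml)
}

#' Time-normalized joint-angle path of a trial
#'
#' Shoulder and elbow angle changes relative to the onset posture, linearly
#' resampled onto a fixed 0--100% grid of the movement, so trials of
#' different duration are comparable. The first grid point is exactly
#' (0, 0).
#'
#' @param trial A `reach_trial`.
#' @param onset,offset Movement window, ms.
#' @param grid_size Number of grid points (101 gives 1% steps).
#' @return A data.frame with `percent`, `shoulder_delta`, `elbow_delta`.
#' @export
resample_joint_angles <- function(trial, onset, offset, grid_size = 101) {
  stopifnot(onset < offset)
  i0 <- match(onset, trial$t); i1 <- match(offset, trial$t)
  if (is.na(i0) || is.na(i1)) stop("onset/offset outside the recorded series")
  idx <- i0:i1
  tt <- trial$t[idx]
  sd0 <- trial$shoulder_deg[idx] - trial$shoulder_deg[i0]
  ed0 <- trial$elbow_deg[idx] - trial$elbow_deg[i0]
  pct <- seq(0, 100, length.out = grid_size)
  xout <- onset + pct / 100 * (offset - onset)
  sh <- stats::approx(tt, sd0, xout = xout)$y
  el <- stats::approx(tt, ed0, xout = xout)$y
  sh[1] <- 0; el[1] <- 0
  data.frame(percent = pct, shoulder_delta = sh, elbow_delta = el)
}

#' Quality-arm movement parameters of one qualified trial
#'
#' @param trial A quality-qualified `reach_trial`.
#' @param thresholds Session [compute_thresholds()].
#' @param config A [task_config()].
#' @return A list: onset, offset, movement_time (ms), path_length (cm),
#'   n_velocity_peaks, onset_fallback flag.
#' @export
quality_metrics <- function(trial, thresholds, config = task_config()) {
  onset <- detect_onset(trial, thresholds, config)
  offset <- detect_offset(trial, config)
  fallback <- isTRUE(attr(onset, "fallback"))
  onset <- as.integer(onset)
  sp <- trial_speed(trial, config$sample_rate)
  fsp <- filter_speed(sp, config$sample_rate)
  list(
    onset = onset, offset = offset,
    movement_time = offset - onset,
    path_length = path_length(trial, onset, offset),
    n_velocity_peaks = if (offset > onset)
      count_velocity_peaks(fsp, onset, offset, trial$t) else 0L,
    onset_fallback = fallback
  )
}

#' Per-trial metric table of one session
#'
#' Mirrors the session to the left-arm frame, computes the session speed
#' thresholds, applies both qualification arms and assembles a long-format
#' row per trial with quality metrics (where quality-qualified) and AP/ML
#' displacement (where quantity-qualified).
#'
#' @param session A `participant_session`.
#' @param config A [task_config()].
#' @return A data.frame, one row per trial.
#' @export
session_metrics <- function(session, config = task_config()) {
  session <- mirror_session_to_left(session)
  qq <- qualify_quality(session, config)
  qn <- qualify_quantity(session, config)
  thr <- tryCatch(compute_thresholds(session, config), error = function(e) NULL)
  n <- length(session$trials)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    tr <- session$trials[[i]]
    inc_q <- i %in% qq$included
    inc_n <- i %in% qn$included
    qm <- if (inc_q && !is.null(thr)) quality_metrics(tr, thr, config) else NULL
    dc <- if (inc_n) displacement_components(tr, config) else
      c(ap_total = NA_real_, ml_total = NA_real_)
    rows[[i]] <- data.frame(
      participant = session$participant_id,
      side = session$side,
      timepoint = session$timepoint,
      fma_ue = session$fma_ue,
      trial = tr$trial_index,
      direction = if (is.na(tr$target)) NA_character_ else tr$target,
      outcome = tr$outcome,
      included_quality = inc_q,
      included_quantity = inc_n,
      onset_ms = if (is.null(qm)) NA_integer_ else qm$onset,
      offset_ms = if (is.null(qm)) NA_integer_ else qm$offset,
      movement_time_ms = if (is.null(qm)) NA_integer_ else qm$movement_time,
      path_length_cm = if (is.null(qm)) NA_real_ else qm$path_length,
      n_velocity_peaks = if (is.null(qm)) NA_integer_ else qm$n_velocity_peaks,
      onset_fallback = if (is.null(qm)) NA else qm$onset_fallback,
      ap_total_cm = unname(dc["ap_total"]),
      ml_total_cm = unname(dc["ml_total"]),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-trial metric table of a whole cohort
#'
#' @param cohort A `reach_cohort`.
#' @param config A [task_config()] (defaults to the cohort's).
#' @return A long data.frame over all sessions with the participant group
#'   joined from the roster.
#' @export
cohort_metrics <- function(cohort, config = cohort$config) {
  tabs <- lapply(cohort$sessions, session_metrics, config = config)
  out <- as.data.frame(data.table::rbindlist(tabs))
  out$group <- cohort$roster$group[match(out$participant,
                                         cohort$roster$participant)]
  out
}
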