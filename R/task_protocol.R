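#' Task configuration for the visually guided center-out reaching task
#'
#' Encodes the geometry and timing of the 8-target horizontal reaching task:
#' a central start target, eight peripheral targets uniformly spaced on a
#' 10-cm circle, a 1,250--1,750 ms hold before target illumination, a
#' 3,000-ms reach limit, 64 trials per session, and 1-kHz / 0.01-cm
#' recording resolution.
#'
#' @param n_targets Number of peripheral targets (8).
#' @param target_distance Distance from start to each peripheral target, cm.
#' @param central_radius Radius of the central start target, cm.
#' @param peripheral_radius Radius of each peripheral target, cm.
#' @param cursor_radius Radius of the hand cursor, cm.
#' @param hold_min,hold_max Bounds of the pre-illumination hold, ms.
#' @param reach_limit Time allowed to reach a peripheral target, ms.
#' @param return_limit Time allowed to return to the centre, ms.
#' @param n_trials Trials per session; must be a multiple of `n_targets`.
#' @param sample_rate Recording rate, Hz.
#' @param spatial_resolution Position quantum, cm.
#' @param leave_rule How "the hand left the central target" is decided; see
#'   [left_center_threshold()].
#' @param entry_rule How "the cursor entered a peripheral target" is decided:
#'   `"center_in"` (cursor centre within the target circle) or `"overlap"`
#'   (cursor circle overlaps the target circle).
#' @return A `reach_task_config` list.
#' @export
task_config <- function(n_targets = 8L,
                        target_distance = 10,
                        central_radius = 1,
                        peripheral_radius = 1,
                        cursor_radius = 0.4,
                        hold_min = 1250,
                        hold_max = 1750,
                        reach_limit = 3000,
                        return_limit = 5000,
                        n_trials = 64L,
                        sample_rate = 1000,
                        spatial_resolution = 0.01,
                        leave_rule = c("cursor_clear", "containment_exit", "center_exit"),
                        entry_rule = c("center_in", "overlap")) {
  leave_rule <- match.arg(leave_rule)
  entry_rule <- match.arg(entry_rule)
  stopifnot(
    n_targets == 8L,
    target_distance > 0, central_radius > 0, peripheral_radius > 0,
    cursor_radius > 0, hold_min > 0, hold_max > hold_min,
    reach_limit > 0, return_limit > 0,
    n_trials >= n_targets, n_trials %% n_targets == 0,
    sample_rate > 0, spatial_resolution > 0,
    target_distance > central_radius + peripheral_radius
  )
  structure(list(
    n_targets = as.integer(n_targets),
    target_distance = target_distance,
    central_radius = central_radius,
    peripheral_radius = peripheral_radius,
    cursor_radius = cursor_radius,
    hold_min = hold_min, hold_max = hold_max,
    reach_limit = reach_limit, return_limit = return_limit,
    n_trials = as.integer(n_trials),
    sample_rate = sample_rate,
    spatial_resolution = spatial_resolution,
    leave_rule = leave_rule, entry_rule = entry_rule
  ), class = "reach_task_config")
}

#' Direction labels of the eight peripheral targets
#'
#' Labels follow the medial/forward/lateral/backward naming of the task, in
#' counter-clockwise order starting at medial. All sessions are expressed in
#' the left-arm workspace frame: +x is medial (toward the midline), +y is
#' forward (away from the body).
#'
#' @return Character vector of the 8 labels.
#' @export
direction_labels <- function() {
  c("M", "MF", "F", "LF", "L", "LB", "B", "MB")
}

#' Angle of each target direction in the left-arm frame
#'
#' @param labels Direction labels.
#' @return Named numeric vector of angles in degrees (M = 0 at +x, F = 90 at
#'   +y, 45-degree spacing).
#' @export
direction_angle <- function(labels = direction_labels()) {
  all_angles <- stats::setNames(seq(0, 315, by = 45), direction_labels())
  bad <- setdiff(labels, names(all_angles))
  if (length(bad)) stop("unknown direction label(s): ", paste(bad, collapse = ", "))
  all_angles[labels]
}

# Anteroposterior weight of a direction: |sin(angle)| (1 for F/B, 0 for M/L).
direction_apness <- function(labels = direction_labels()) {
  ang <- direction_angle(labels)
  stats::setNames(abs(sinpi(ang / 180)), labels)
}

#' Peripheral target positions
#'
#' @param config A [task_config()].
#' @return A data.frame with columns `direction`, `x`, `y` (cm, start at the
#'   origin), one row per target in label order.
#' @export
target_positions <- function(config = task_config()) {
  ang <- direction_angle()
  data.frame(
    direction = names(ang),
    x = config$target_distance * cospi(ang / 180),
    y = config$target_distance * sinpi(ang / 180),
    row.names = NULL
  )
}

target_xy <- function(label, config) {
  ang <- unname(direction_angle(label))
  c(config$target_distance * cospi(ang / 180),
    config$target_distance * sinpi(ang / 180))
}

#' Classify upper-extremity impairment severity from FMA-UE scores
#'
#' The Fugl-Meyer assessment for upper extremity (FMA-UE, integer 0--66)
#' defines mild impairment as a score above 45, moderate as 30--45 and
#' severe as below 30. Analyses split participants into a mild group and a
#' moderate-to-severe group.
#'
#' @param fma_ue Integer FMA-UE score(s) in 0--66.
#' @return A data.frame with columns `fma_ue`, `level` (mild/moderate/severe)
#'   and `group` (mild/moderate_to_severe).
#' @export
classify_severity <- function(fma_ue) {
  if (length(fma_ue) == 0) stop("no FMA-UE scores supplied")
  if (any(is.na(fma_ue)) || any(fma_ue != round(fma_ue))) {
    stop("FMA-UE scores must be integers in 0-66")
  }
  if (any(fma_ue < 0 | fma_ue > 66)) {
    stop("FMA-UE score out of range 0-66: ", paste(fma_ue[fma_ue < 0 | fma_ue > 66], collapse = ", "))
  }
  level <- ifelse(fma_ue > 45, "mild", ifelse(fma_ue >= 30, "moderate", "severe"))
  data.frame(
    fma_ue = as.integer(fma_ue),
    level = level,
    group = ifelse(level == "mild", "mild", "moderate_to_severe")
  )
}

#' Mirror a direction label across the body midline
#'
#' Reflection about the anteroposterior axis (x negation): medial and
#' lateral labels swap, forward/backward labels are unchanged.
#'
#' @param labels Direction labels.
#' @return Remapped labels of the same length.
#' @export
mirror_direction <- function(labels) {
  map <- c(M = "L", MF = "LF", F = "F", LF = "MF",
           L = "M", LB = "MB", B = "B", MB = "LB")
  out <- unname(map[labels])
  out[is.na(labels)] <- NA_character_
  out
}

#' Reflect a trial across the body midline
#'
#' Negates x about the start position, remaps the direction labels so that
#' "medial" stays toward the midline, and flips the recorded-arm flag.
#' Joint angles are unchanged (the shoulder-adduction / elbow-flexion
#' convention is side-symmetric). The operation is an involution:
#' `mirror_trial(mirror_trial(t))` is bit-identical to `t`.
#'
#' @param trial A `reach_trial`.
#' @return The reflected trial.
#' @export
mirror_trial <- function(trial) {
  trial$x <- (2 * trial$start_xy[1]) - trial$x
  if (!is.null(trial$target_xy) && !anyNA(trial$target_xy)) {
    trial$target_xy[1] <- (2 * trial$start_xy[1]) - trial$target_xy[1]
  }
  trial$scheduled_target <- mirror_direction(trial$scheduled_target)
  if (!is.na(trial$target)) trial$target <- mirror_direction(trial$target)
  trial$recorded_arm <- if (trial$recorded_arm == "left") "right" else "left"
  trial
}

#' Express a trial in the left-arm workspace frame
#'
#' Right-arm recordings are flipped to correspond to left-arm data;
#' left-arm recordings are returned unchanged.
#'
#' @param trial A `reach_trial` carrying a `recorded_arm` flag.
#' @return The trial in the left-arm frame.
#' @export
mirror_to_left <- function(trial) {
  if (identical(trial$recorded_arm, "right")) mirror_trial(trial) else trial
}

#' Express a whole session in the left-arm frame
#'
#' @param session A `participant_session`.
#' @return The session with all trials mirrored to the left-arm frame.
#' @export
mirror_session_to_left <- function(session) {
  if (identical(session$recorded_arm, "right")) {
    session$trials <- lapply(session$trials, mirror_trial)
    session$recorded_arm <- "left"
    session$mirrored <- TRUE
  }
  session
}
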