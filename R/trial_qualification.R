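# Trial qualification: the two exclusion regimes of the analysis.
# The quality arm (movement time / path length / velocity peaks) keeps only
# trials where a target appeared and was reached within the reach limit;
# the quantity arm (AP/ML displacement) keeps every trial where a target
# appeared and the hand left the centre, even if the reach failed.

#' Distance from start at which the hand counts as having left the centre
#'
#' Rules, in cm for the default task: `"cursor_clear"` — the cursor centre
#' is farther than `central_radius + cursor_radius` (1.4 cm) from the start;
#' `"containment_exit"` — the cursor circle is no longer contained in the
#' central target (`central_radius - cursor_radius`, 0.6 cm);
#' `"center_exit"` — the cursor centre leaves the central circle (1.0 cm).
#'
#' @param config A [task_config()].
#' @return Threshold distance, cm.
#' @export
left_center_threshold <- function(config = task_config()) {
  switch(config$leave_rule,
    cursor_clear = config$central_radius + config$cursor_radius,
    containment_exit = config$central_radius - config$cursor_radius,
    center_exit = config$central_radius
  )
}

#' Distance to a peripheral target centre at which the cursor has entered it
#'
#' @param config A [task_config()].
#' @return Entry radius, cm.
#' @export
target_entry_radius <- function(config = task_config()) {
  switch(config$entry_rule,
    center_in = config$peripheral_radius,
    overlap = config$peripheral_radius + config$cursor_radius
  )
}

qualification_report <- function(arm, session, included, causes) {
  n_total <- length(session$trials)
  n_excluded <- n_total - length(included)
  dirs <- vapply(session$trials[included],
                 function(tr) tr$target, character(1))
  per_dir <- table(factor(dirs, levels = direction_labels()))
  structure(list(
    analysis_arm = arm,
    participant = session$participant_id,
    side = session$side,
    timepoint = session$timepoint,
    n_total = n_total,
    n_excluded = n_excluded,
    pct_excluded = 100 * n_excluded / n_total,
    causes = causes,
    per_direction_included = stats::setNames(as.integer(per_dir),
                                             names(per_dir))
  ), class = "qualification_report")
}

#' Qualify trials for the movement-quality analysis
#'
#' A trial is included iff a peripheral target appeared, the target was
#' reached, and the reach took no more than the configured limit
#' (3,000 ms). Hold-failure trials (no target) count in the denominator of
#' the exclusion percentage, matching the device's 64-trial counter.
#'
#' @param session A `participant_session`.
#' @param config A [task_config()].
#' @return A list with `included` (trial indices) and `report`
#'   (a `qualification_report`).
#' @export
qualify_quality <- function(session, config = task_config()) {
  appeared <- vapply(session$trials, function(tr) !is.na(tr$target), logical(1))
  reached <- vapply(session$trials, function(tr) isTRUE(tr$reached_target),
                    logical(1))
  within_limit <- vapply(session$trials, function(tr) {
    !is.na(tr$reach_duration) && tr$reach_duration <= config$reach_limit
  }, logical(1))
  inc <- which(appeared & reached & within_limit)
  causes <- c(no_target = sum(!appeared),
              not_reached = sum(appeared & !(reached & within_limit)))
  list(included = inc,
       report = qualification_report("quality", session, inc, causes))
}

#' Qualify trials for the movement-quantity analysis
#'
#' A trial is included iff a peripheral target appeared and the hand left
#' the central target, regardless of whether the reach succeeded.
#'
#' @param session A `participant_session`.
#' @param config A [task_config()].
#' @return A list with `included` (trial indices) and `report`.
#' @export
qualify_quantity <- function(session, config = task_config()) {
  appeared <- vapply(session$trials, function(tr) !is.na(tr$target), logical(1))
  left <- vapply(session$trials, function(tr) isTRUE(tr$left_center),
                 logical(1))
  inc <- which(appeared & left)
  causes <- c(no_target = sum(!appeared),
              never_left = sum(appeared & !left))
  list(included = inc,
       report = qualification_report("quantity", session, inc, causes))
}

#' Flatten a qualification report to a one-row data.frame
#'
#' @param report A `qualification_report`.
#' @return A data.frame row suitable for CSV export.
#' @export
qualification_row <- function(report) {
  data.frame(
    participant = report$participant,
    side = report$side,
    timepoint = report$timepoint,
    analysis_arm = report$analysis_arm,
    n_total = report$n_total,
    n_excluded = report$n_excluded,
    pct_excluded = report$pct_excluded,
    n_no_target = unname(report$causes[["no_target"]]),
    n_failed_movement = unname(report$causes[[2]]),
    stringsAsFactors = FALSE
  )
}
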