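# Synthetic cohort generator: seeded participants and 1-kHz reaching
# sessions with the statistical structure the downstream analysis assumes
# (direction-dependent slowing, side differences, severity-dependent
# incomplete reaches biased mediolaterally, partial recovery over time).

#' Two-link planar arm geometry
#'
#' Link lengths and shoulder position of the two-link (upper arm + forearm)
#' planar model used to derive joint angles from hand position. The shoulder
#' position is constructed so that with the hand at the central target the
#' posture is exactly `start_shoulder_deg` of shoulder horizontal adduction
#' and `start_elbow_deg` of elbow flexion (the task's documented start
#' posture, 30 and 90 degrees). Conventions: shoulder horizontal adduction
#' positive (toward the midline, +x medial in the left-arm frame), elbow
#' flexion positive, 0 degrees elbow = full extension; elbow-down branch.
#'
#' @param L1,L2 Upper-arm and forearm (to fingertip) lengths, cm.
#' @param start_shoulder_deg,start_elbow_deg Anchoring start posture, deg.
#' @param start_xy Hand position at the start posture (workspace origin).
#' @return An `arm_geometry` list with the derived shoulder position.
#' @export
arm_geometry <- function(L1 = 30, L2 = 33,
                         start_shoulder_deg = 30, start_elbow_deg = 90,
                         start_xy = c(0, 0)) {
  stopifnot(L1 > 0, L2 > 0)
  alpha0 <- (90 - start_shoulder_deg) * pi / 180
  beta0 <- alpha0 - start_elbow_deg * pi / 180
  shoulder_xy <- start_xy - L1 * c(cos(alpha0), sin(alpha0)) -
    L2 * c(cos(beta0), sin(beta0))
  structure(list(L1 = L1, L2 = L2, shoulder_xy = shoulder_xy,
                 start_shoulder_deg = start_shoulder_deg,
                 start_elbow_deg = start_elbow_deg),
            class = "arm_geometry")
}

#' Inverse kinematics: joint angles from hand positions
#'
#' Planar two-link inverse kinematics (elbow-down branch). At the central
#' target the returned angles equal the geometry's anchoring start posture.
#'
#' @param x,y Hand position series, cm.
#' @param geometry An [arm_geometry()].
#' @param context Optional label used in error messages.
#' @return A list with numeric vectors `shoulder_deg` (horizontal adduction)
#'   and `elbow_deg` (flexion; 0 = full extension).
#' @export
joint_angles_from_hand <- function(x, y, geometry = arm_geometry(),
                                   context = "series") {
  S <- geometry$shoulder_xy
  L1 <- geometry$L1; L2 <- geometry$L2
  dx <- x - S[1]; dy <- y - S[2]
  r2 <- dx^2 + dy^2
  cphi <- (r2 - L1^2 - L2^2) / (2 * L1 * L2)
  bad <- which(cphi > 1 + 1e-9 | cphi < -1 - 1e-9)
  if (length(bad)) {
    stop("unreachable hand position in ", context, " at sample ", bad[1],
         " (distance ", sqrt(r2[bad[1]]), " cm outside [",
         abs(L1 - L2), ", ", L1 + L2, "])")
  }
  cphi <- pmin(1, pmax(-1, cphi))
  phi <- acos(cphi)
  gamma <- atan2(L2 * sin(phi), L1 + L2 * cos(phi))
  alpha <- atan2(dy, dx) + gamma
  list(shoulder_deg = 90 - alpha * 180 / pi,
       elbow_deg = phi * 180 / pi)
}

#' Forward kinematics: hand position from joint angles
#'
#' Inverse of [joint_angles_from_hand()]; used for round-trip validation.
#'
#' @param shoulder_deg,elbow_deg Joint angle series, deg.
#' @param geometry An [arm_geometry()].
#' @return A list with vectors `x`, `y` (cm).
#' @export
hand_from_joint_angles <- function(shoulder_deg, elbow_deg,
                                   geometry = arm_geometry()) {
  S <- geometry$shoulder_xy
  alpha <- (90 - shoulder_deg) * pi / 180
  beta <- alpha - elbow_deg * pi / 180
  list(x = S[1] + geometry$L1 * cos(alpha) + geometry$L2 * cos(beta),
       y = S[2] + geometry$L1 * sin(alpha) + geometry$L2 * sin(beta))
}

#' Minimum-jerk point-to-point trajectory
#'
#' The canonical smooth-reach profile: position interpolates from `start`
#' to `end` with the fifth-order minimum-jerk time course, whose speed
#' profile is unimodal (a single positive peak).
#'
#' @param start,end Endpoints, cm (length-2).
#' @param duration_ms Movement duration, ms.
#' @param rate Sampling rate, Hz.
#' @return An n x 2 matrix of positions, inclusive of both endpoints
#'   (`n = duration_ms * rate / 1000 + 1`).
#' @export
minimum_jerk_reach <- function(start, end, duration_ms, rate = 1000) {
  stopifnot(duration_ms > 0)
  n <- round(duration_ms * rate / 1000) + 1
  tau <- seq(0, 1, length.out = n)
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  cbind(start[1] + s * (end[1] - start[1]),
        start[2] + s * (end[2] - start[2]))
}

#' Rebuild a reach as a main movement plus corrective submovements
#'
#' Decomposes the reach into a chained sequence of minimum-jerk segments:
#' one main movement covering most of the distance followed by `k` short
#' corrective segments, each covering about `amplitude` cm, with speed
#' falling to zero at the junctions. The filtered speed profile therefore
#' shows exactly `1 + k` positive peaks — the classic staircase velocity of
#' discretely corrected reaching. Endpoints and total duration are
#' preserved; the path must be long enough to host the corrections
#' (roughly `260 + 190 k` ms at the defaults).
#'
#' @param path An n x 2 position matrix (a reach from row 1 to row n).
#' @param k Number of corrective submovements (>= 0).
#' @param amplitude Distance covered by one intermediate correction, cm.
#' @param final_amplitude Distance covered by the last correction, cm. It is
#'   deliberately larger than the others so that downstream offset
#'   detection (cursor entry within ~1 cm of the target) falls safely
#'   beyond that correction's speed maximum and all `1 + k` peaks lie
#'   inside the onset--offset window.
#' @param correction_ms,final_ms Nominal durations, ms.
#' @param rate Sampling rate, Hz.
#' @param seed Optional seed making the duration/amplitude jitter
#'   reproducible in isolation; by default the current RNG stream is used.
#' @return The modified n x 2 path.
#' @export
add_submovements <- function(path, k, amplitude = 0.9, final_amplitude = 3,
                             correction_ms = 170, final_ms = 300,
                             rate = 1000, seed = NULL) {
  stopifnot(k >= 0)
  if (k == 0) return(path)
  if (!is.null(seed)) {
    return(with_preserved_seed(seed, add_submovements(path, k, amplitude,
                                                      final_amplitude,
                                                      correction_ms, final_ms,
                                                      rate)))
  }
  n <- nrow(path)
  total_ms <- (n - 1) / rate * 1000
  p0 <- path[1, ]; p1 <- path[n, ]
  len <- sqrt(sum((p1 - p0)^2))
  if (len < 1e-9) stop("degenerate path: endpoints coincide")
  u <- (p1 - p0) / len
  d_corr <- round(c(correction_ms * stats::runif(k - 1, 0.9, 1.1),
                    final_ms * stats::runif(1, 0.9, 1.1)))
  main_ms <- total_ms - sum(d_corr)
  if (main_ms < 250) {
    stop("reach too short for ", k, " submovements (", total_ms, " ms)")
  }
  a_corr <- c(amplitude * stats::runif(k - 1, 0.8, 1.2),
              final_amplitude * stats::runif(1, 0.9, 1.1))
  if (sum(a_corr) > 0.65 * len) a_corr <- a_corr * 0.65 * len / sum(a_corr)
  # waypoints along the chord: main covers the rest, then each correction
  cum <- len - rev(cumsum(rev(a_corr)))
  pts <- rbind(p0, t(vapply(c(cum, len), function(d) p0 + d * u, numeric(2))))
  dur <- c(main_ms, d_corr)
  segs <- lapply(seq_len(k + 1), function(i) {
    minimum_jerk_reach(pts[i, ], pts[i + 1, ], dur[i], rate)
  })
  out <- segs[[1]]
  for (i in seq_len(k)) out <- rbind(out, segs[[i + 1]][-1, , drop = FALSE])
  stopifnot(nrow(out) == n)
  out
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Impairment profile of one arm at one timepoint
#'
#' Phenomenological knobs that shape a simulated session: the probability of
#' surviving the pre-illumination hold, of leaving the centre at all, and of
#' completing the reach per direction; direction-dependent slowing (the
#' anteroposterior directions are scaled up); the expected number of
#' corrective submovements per direction; the mediolateral energy share of
#' incomplete excursions; and the positional noise scale.
#'
#' @param attempt_prob Probability the hand leaves the centre after a target
#'   appears.
#' @param completion_prob_by_direction Named probability per direction of
#'   completing the reach, given the hand leaves the centre.
#' @param time_scale_by_direction Named multiplier (>= 1) on reach duration.
#' @param extra_submovements_by_direction Named Poisson mean of corrective
#'   submovements per direction.
#' @param ml_bias Fraction (0--1) of incomplete-excursion energy directed
#'   mediolaterally.
#' @param hold_failure_prob Probability the hold fails (no target appears).
#' @param noise_sd Positional jitter SD, cm (white noise low-passed at 5 Hz).
#' @param base_reach_ms Baseline reach duration before direction scaling, ms.
#' @return An `impairment_profile` list.
#' @export
impairment_profile <- function(attempt_prob = 1,
                               completion_prob_by_direction =
                                 stats::setNames(rep(1, 8), direction_labels()),
                               time_scale_by_direction =
                                 stats::setNames(rep(1, 8), direction_labels()),
                               extra_submovements_by_direction =
                                 stats::setNames(rep(0, 8), direction_labels()),
                               ml_bias = 0.5,
                               hold_failure_prob = 0,
                               noise_sd = 0,
                               base_reach_ms = 650) {
  labs <- direction_labels()
  completion_prob_by_direction <- completion_prob_by_direction[labs]
  time_scale_by_direction <- time_scale_by_direction[labs]
  extra_submovements_by_direction <- extra_submovements_by_direction[labs]
  stopifnot(
    attempt_prob >= 0, attempt_prob <= 1,
    all(completion_prob_by_direction >= 0 & completion_prob_by_direction <= 1),
    all(time_scale_by_direction >= 1),
    all(extra_submovements_by_direction >= 0),
    ml_bias >= 0, ml_bias <= 1,
    hold_failure_prob >= 0, hold_failure_prob <= 1,
    noise_sd >= 0, base_reach_ms > 0
  )
  structure(list(
    attempt_prob = attempt_prob,
    completion_prob_by_direction = completion_prob_by_direction,
    time_scale_by_direction = time_scale_by_direction,
    extra_submovements_by_direction = extra_submovements_by_direction,
    ml_bias = ml_bias,
    hold_failure_prob = hold_failure_prob,
    noise_sd = noise_sd,
    base_reach_ms = base_reach_ms
  ), class = "impairment_profile")
}

#' Unimpaired reference profile
#'
#' @param noise_sd Positional jitter SD, cm.
#' @return An [impairment_profile()] that always completes with no
#'   direction-dependent slowing and no submovements.
#' @export
healthy_profile <- function(noise_sd = 0) {
  impairment_profile(noise_sd = noise_sd)
}

#' Map an FMA-UE score to an impairment profile
#'
#' Severity-dependent defaults for one arm. The more-affected arm's
#' probability of leaving the centre and of completing a reach rise with the
#' FMA-UE score (logistic maps calibrated so mean exclusion rates land near
#' the reported clinical ranges); reaches slow and gain submovements toward
#' the anteroposterior directions. The less-affected arm is near-healthy
#' with a mild anteroposterior slowing shared by both sides.
#'
#' @param fma_ue Integer FMA-UE score, 0--66.
#' @param side `"more_affected"` or `"less_affected"`.
#' @param ml_bias Mediolateral energy share for incomplete excursions.
#' @return An [impairment_profile()].
#' @export
profile_from_fma <- function(fma_ue, side = c("more_affected", "less_affected"),
                             ml_bias = 0.5) {
  side <- match.arg(side)
  classify_severity(fma_ue)  # validates range/integrality
  sev <- 1 - fma_ue / 66
  ap <- direction_apness()
  if (side == "more_affected") {
    impairment_profile(
      attempt_prob = stats::plogis(-2.58 + 0.101 * fma_ue),
      completion_prob_by_direction = stats::plogis(-8 + 0.2 * fma_ue) * (1 - 0.05 * ap),
      time_scale_by_direction = 1 + (0.25 + 0.20 * sev) * ap,
      extra_submovements_by_direction = (0.45 + 1.0 * sev) * (1 + 0.5 * ap),
      ml_bias = ml_bias,
      hold_failure_prob = 0.02 + 0.06 * sev,
      noise_sd = 0.04 + 0.04 * sev,
      base_reach_ms = 650 * (1 + 0.6 * sev)
    )
  } else {
    sev_l <- 0.15 * sev
    impairment_profile(
      attempt_prob = 0.995,
      completion_prob_by_direction = 0.97 * (1 - 0.03 * ap),
      time_scale_by_direction = 1 + (0.18 + 0.05 * sev_l) * ap,
      extra_submovements_by_direction = 0.25 * (1 + 0.5 * ap),
      ml_bias = ml_bias,
      hold_failure_prob = 0.015,
      noise_sd = 0.04,
      base_reach_ms = 600 * (1 + 0.3 * sev_l)
    )
  }
}

# cached 5-Hz low-pass design for positional jitter
.reachkin_cache <- new.env(parent = emptyenv())

jitter_series <- function(n, sd, rate) {
  if (sd <= 0) return(numeric(n))
  key <- paste0("jit", rate)
  if (is.null(.reachkin_cache[[key]])) {
    .reachkin_cache[[key]] <- signal::butter(2, 5 / (rate / 2))
  }
  z <- signal::filtfilt(.reachkin_cache[[key]], stats::rnorm(n))
  s <- stats::sd(z)
  if (s < 1e-12) return(numeric(n))
  z / s * sd
}

quantize <- function(x, q) round(x / q) * q

#' Simulate a single trial of the center-out task
#'
#' Emits the trial state machine: a hold phase of uniform duration within
#' the configured bounds with low-pass-filtered positional jitter; then
#' either a hold failure (no target appears), a completed minimum-jerk reach
#' with Poisson-many corrective submovements, an incomplete bout of
#' sub-excursions whose mediolateral/anteroposterior energy split is
#' governed by the profile's `ml_bias`, or no movement at all. Positions are
#' quantized to the configured spatial resolution and joint angles derived
#' by two-link inverse kinematics. Outcome flags (`left_center`,
#' `reached_target`, `reach_duration`) are recomputed from the realized
#' quantized series with the configured leave/entry rules. Uses the current
#' RNG stream.
#'
#' @param profile An [impairment_profile()].
#' @param target Scheduled direction label.
#' @param config A [task_config()].
#' @param geometry An [arm_geometry()].
#' @param trial_index Trial counter stored in the record.
#' @param recorded_arm Arm flag stored in the record.
#' @return A `reach_trial` list.
#' @export
simulate_trial <- function(profile, target, config = task_config(),
                           geometry = arm_geometry(), trial_index = 1L,
                           recorded_arm = "left") {
  rate <- config$sample_rate
  illum <- round(stats::runif(1, config$hold_min, config$hold_max))
  hold_fail <- stats::runif(1) < profile$hold_failure_prob
  tgt <- target_xy(target, config)
  lat <- round(stats::runif(1, 200, 400))
  sim_k <- NA_integer_; sim_reach_ms <- NA_integer_

  if (hold_fail) {
    n <- illum + round(stats::runif(1, 300, 800))
    sx <- numeric(n); sy <- numeric(n)
    appeared <- FALSE
  } else {
    appeared <- TRUE
    leaves <- stats::runif(1) < profile$attempt_prob
    if (!leaves) {
      n <- illum + config$reach_limit
      sx <- numeric(n); sy <- numeric(n)
    } else {
      complete <- stats::runif(1) < profile$completion_prob_by_direction[[target]]
      if (complete) {
        k <- min(stats::rpois(1, profile$extra_submovements_by_direction[[target]]), 4L)
        D <- profile$base_reach_ms * profile$time_scale_by_direction[[target]] *
          exp(stats::rnorm(1, 0, 0.12))
        D <- round(max(350, if (k > 0) 620 + 195 * (k - 1) else 0,
                       min(D, config$reach_limit - lat - 80)))
        reach <- minimum_jerk_reach(c(0, 0), tgt, D, rate)
        if (k > 0) reach <- add_submovements(reach, k, rate = rate)
        sim_k <- as.integer(k); sim_reach_ms <- as.integer(D)
        tail_n <- 150
        sx <- c(numeric(illum + lat), reach[-1, 1], rep(tgt[1], tail_n))
        sy <- c(numeric(illum + lat), reach[-1, 2], rep(tgt[2], tail_n))
        n <- length(sx)
      } else {
        # Incomplete mover: out-and-back sub-excursions leaving and
        # re-entering the centre region. The axis of each bout (mediolateral
        # vs anteroposterior) is chosen with a probability calibrated so the
        # *measured* pooled L1 mediolateral share matches ml_bias: the
        # calibration corrects both for the angular jitter of the bouts and
        # for the symmetric L1 displacement that quantized positional noise
        # contributes while the hand is still.
        window <- config$reach_limit
        n <- illum + window
        pre_nx <- jitter_series(n, profile$noise_sd, rate)
        pre_ny <- jitter_series(n, profile$noise_sd, rate)
        # bout plan (durations and amplitudes first, axes later)
        plan <- list(); t_used <- lat
        while (t_used < window - 600) {
          amp <- stats::runif(1, 2.2, 5.0)
          D_e <- round(stats::runif(1, 550, 950))
          pause <- round(stats::runif(1, 150, 350))
          plan[[length(plan) + 1L]] <- c(amp = amp, D_e = D_e, pause = pause)
          t_used <- t_used + D_e + pause
        }
        T_dir <- sum(vapply(plan, function(p) 2 * p[["amp"]], numeric(1)))
        move_ms <- sum(vapply(plan, function(p) p[["D_e"]], numeric(1)))
        still_frac <- max(0, window - move_ms) / window
        move_frac <- 1 - still_frac
        w <- (illum + 1):n
        q <- config$spatial_resolution
        tv_x <- sum(abs(diff(quantize(pre_nx[w], q))))
        tv_y <- sum(abs(diff(quantize(pre_ny[w], q))))
        sig_ang <- 3 * pi / 180
        s_j <- sqrt(2 / pi) * sig_ang      # E|sin(jitter)|
        c_j <- exp(-sig_ang^2 / 2)         # E[cos(jitter)]
        b <- profile$ml_bias
        # Fixed point for the axis-choice probability: noise L1 on an axis
        # is absorbed while that axis moves fast (~70% of a bout's course)
        # and accrues otherwise, so each axis's noise exposure depends on
        # the bout-axis mix itself.
        kappa <- 0.75  # quantization absorbs part of the superimposed noise TV
        b_adj <- b
        for (it in 1:4) {
          f_ml <- still_frac + move_frac * (1 - b_adj)
          f_ap <- still_frac + move_frac * b_adj
          e_ml <- kappa * tv_x * f_ml
          e_ap <- kappa * tv_y * f_ap
          b_adj <- ((b * (T_dir * (c_j + s_j) + e_ml + e_ap) - e_ml) / T_dir - s_j) /
            (c_j - s_j)
          b_adj <- min(1, max(0, b_adj))
        }
        ex <- numeric(lat); ey <- numeric(lat)
        for (p in plan) {
          is_ml <- stats::runif(1) < b_adj
          ang <- (if (is_ml) 0 else pi / 2) + sample(c(0, pi), 1) +
            stats::rnorm(1, 0, sig_ang)
          d_out <- round(p[["D_e"]] / 2); d_back <- p[["D_e"]] - d_out
          peak <- p[["amp"]] * c(cos(ang), sin(ang))
          out <- minimum_jerk_reach(c(0, 0), peak, d_out, rate)
          back <- minimum_jerk_reach(peak, c(0, 0), d_back, rate)
          ex <- c(ex, out[-1, 1], back[-1, 1], numeric(p[["pause"]]))
          ey <- c(ey, out[-1, 2], back[-1, 2], numeric(p[["pause"]]))
        }
        keep <- seq_len(min(length(ex), window))
        ex <- ex[keep]; ey <- ey[keep]
        pad <- window - length(ex)
        if (pad > 0) { ex <- c(ex, rep(ex[length(ex)], pad)); ey <- c(ey, rep(ey[length(ey)], pad)) }
        sx <- c(numeric(illum), ex)
        sy <- c(numeric(illum), ey)
      }
    }
  }

  if (!exists("pre_nx", inherits = FALSE)) {
    pre_nx <- jitter_series(n, profile$noise_sd, rate)
    pre_ny <- jitter_series(n, profile$noise_sd, rate)
  }
  x <- quantize(sx + pre_nx, config$spatial_resolution)
  y <- quantize(sy + pre_ny, config$spatial_resolution)

  t <- 0:(n - 1)
  onset_time <- if (appeared) illum else NA_integer_
  leave_thr <- left_center_threshold(config)
  entry_r <- target_entry_radius(config)
  left_center <- FALSE; reached <- FALSE
  reach_duration <- NA_integer_
  if (appeared) {
    post <- (illum + 1):n
    d0 <- sqrt(x[post]^2 + y[post]^2)
    i_leave <- which(d0 > leave_thr)[1]
    left_center <- !is.na(i_leave)
    dt <- sqrt((x[post] - tgt[1])^2 + (y[post] - tgt[2])^2)
    i_entry <- which(dt <= entry_r)[1]
    if (left_center && !is.na(i_entry) && (i_entry - 1) <= config$reach_limit) {
      reached <- TRUE
      reach_duration <- as.integer(i_entry - 1)
    }
  }
  ja <- joint_angles_from_hand(x, y, geometry,
                               context = paste0("trial ", trial_index))
  outcome <- if (!appeared) "no_target"
  else if (reached) "reached"
  else if (left_center) "incomplete"
  else "never_left"

  structure(list(
    trial_index = as.integer(trial_index),
    scheduled_target = target,
    target = if (appeared) target else NA_character_,
    t = as.integer(t),
    x = x, y = y,
    shoulder_deg = ja$shoulder_deg,
    elbow_deg = ja$elbow_deg,
    start_xy = c(0, 0),
    target_xy = tgt,
    target_onset_time = onset_time,
    left_center = left_center,
    reached_target = reached,
    reach_duration = reach_duration,
    outcome = outcome,
    recorded_arm = recorded_arm,
    sim = list(latency_ms = lat, reach_ms = sim_reach_ms,
               n_submovements = sim_k)
  ), class = "reach_trial")
}

#' Simulate one participant x side x timepoint session
#'
#' Generates a blocked-random target schedule (each consecutive block of
#' eight trials contains every direction exactly once) and simulates the
#' configured number of trials under one impairment profile. Right-arm
#' sessions are simulated in the left-arm frame and then mirrored, so the
#' stored recording is in the arm's own frame (the analysis flips it back).
#'
#' @param participant_id Identifier string.
#' @param side `"more_affected"` or `"less_affected"`.
#' @param timepoint `"admission"` or `"discharge"`.
#' @param recorded_arm `"left"` or `"right"`.
#' @param fma_ue FMA-UE score at this timepoint.
#' @param profile An [impairment_profile()].
#' @param config A [task_config()].
#' @param geometry An [arm_geometry()].
#' @param seed Session seed (all randomness derives from it).
#' @return A `participant_session` list.
#' @export
simulate_session <- function(participant_id, side, timepoint, recorded_arm,
                             fma_ue, profile, config = task_config(),
                             geometry = arm_geometry(), seed = 1L) {
  set.seed(seed)
  n_blocks <- config$n_trials / config$n_targets
  schedule <- unlist(lapply(seq_len(n_blocks),
                            function(i) sample(direction_labels())))
  trials <- vector("list", config$n_trials)
  for (i in seq_len(config$n_trials)) {
    trials[[i]] <- simulate_trial(profile, schedule[i], config, geometry,
                                  trial_index = i, recorded_arm = "left")
  }
  if (recorded_arm == "right") trials <- lapply(trials, mirror_trial)
  structure(list(
    participant_id = participant_id,
    side = side, timepoint = timepoint,
    recorded_arm = recorded_arm,
    fma_ue = as.integer(fma_ue),
    seed = as.integer(seed),
    trials = trials
  ), class = "participant_session")
}

#' Cohort specification
#'
#' Defaults encode the study conditions: 13 mild and 15 moderate-to-severe
#' participants, FMA-UE distributions per group and timepoint (means/SDs
#' from the cohort's demographics, clipped to each group's legal range), a
#' non-negative admission-to-discharge improvement, and the mediolateral
#' energy shares of incomplete movement per side and timepoint.
#'
#' @param n_mild,n_severe Group sizes.
#' @param fma_mild,fma_severe `c(mean, sd)` of the admission FMA-UE score.
#' @param gain_mild,gain_severe `c(mean, sd)` of the improvement (truncated
#'   at zero so discharge is never worse than admission).
#' @param ml_bias_more,ml_bias_less `c(admission, discharge)` mediolateral
#'   shares for the more-/less-affected side.
#' @param ml_bias_sd_more,ml_bias_sd_less SD of the persistent
#'   between-participant jitter on those shares.
#' @param right_affected_prob Probability the more-affected arm is the right
#'   one, per group.
#' @param seed Cohort seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_mild = 13L, n_severe = 15L,
                        fma_mild = c(mean = 59.0, sd = 5.7),
                        fma_severe = c(mean = 19.4, sd = 14.4),
                        gain_mild = c(mean = 3.3, sd = 4.8),
                        gain_severe = c(mean = 9.5, sd = 6.75),
                        ml_bias_more = c(admission = 0.686, discharge = 0.617),
                        ml_bias_less = c(admission = 0.531, discharge = 0.523),
                        ml_bias_sd_more = 0.055,
                        ml_bias_sd_less = 0.018,
                        right_affected_prob = c(mild = 3 / 13, severe = 7 / 15),
                        seed = 1L) {
  stopifnot(n_mild >= 0, n_severe >= 0,
            all(ml_bias_more >= 0 & ml_bias_more <= 1),
            all(ml_bias_less >= 0 & ml_bias_less <= 1))
  structure(as.list(environment()), class = "cohort_spec")
}

clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))

#' Simulate a full cohort
#'
#' For each participant: two sides x two timepoints of reaching sessions.
#' FMA-UE scores are sampled within the group's legal range; the discharge
#' score is never worse than admission; the more-affected profile severity
#' is tied to the sampled score while the less-affected side is
#' near-healthy. One cohort seed expands to per-session seeds as
#' `seed * 1000 + session_index`, so any single session is reproducible in
#' isolation.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param geometry An [arm_geometry()].
#' @param progress Emit a message per participant.
#' @return A `reach_cohort` list with `roster` (data.frame) and `sessions`.
#' @export
simulate_cohort <- function(spec = cohort_spec(), config = task_config(),
                            geometry = arm_geometry(), progress = FALSE) {
  set.seed(spec$seed)
  n_total <- spec$n_mild + spec$n_severe
  roster <- data.frame(
    participant = sprintf("P%02d", seq_len(n_total)),
    group = rep(c("mild", "moderate_to_severe"),
                c(spec$n_mild, spec$n_severe)),
    stringsAsFactors = FALSE
  )
  fma_adm <- integer(n_total); fma_dis <- integer(n_total)
  arm_more <- character(n_total)
  jit_more <- numeric(n_total); jit_less <- numeric(n_total)
  for (i in seq_len(n_total)) {
    if (roster$group[i] == "mild") {
      fma_adm[i] <- round(clip(stats::rnorm(1, spec$fma_mild["mean"],
                                            spec$fma_mild["sd"]), 46, 66))
      gain <- max(0, round(stats::rnorm(1, spec$gain_mild["mean"],
                                        spec$gain_mild["sd"])))
      fma_dis[i] <- min(66L, fma_adm[i] + gain)
      p_right <- spec$right_affected_prob[["mild"]]
    } else {
      fma_adm[i] <- round(clip(stats::rnorm(1, spec$fma_severe["mean"],
                                            spec$fma_severe["sd"]), 3, 45))
      gain <- max(0, round(stats::rnorm(1, spec$gain_severe["mean"],
                                        spec$gain_severe["sd"])))
      fma_dis[i] <- min(45L, fma_adm[i] + gain)
      p_right <- spec$right_affected_prob[["severe"]]
    }
    arm_more[i] <- if (stats::runif(1) < p_right) "right" else "left"
    jit_more[i] <- stats::rnorm(1, 0, spec$ml_bias_sd_more)
    jit_less[i] <- stats::rnorm(1, 0, spec$ml_bias_sd_less)
  }
  roster$fma_admission <- fma_adm
  roster$fma_discharge <- fma_dis
  roster$more_affected_arm <- arm_more

  sessions <- vector("list", 4 * n_total)
  counter <- 0L
  for (i in seq_len(n_total)) {
    if (progress) message("simulating ", roster$participant[i])
    for (side in c("more_affected", "less_affected")) {
      arm <- if (side == "more_affected") arm_more[i] else
        setdiff(c("left", "right"), arm_more[i])
      for (tp in c("admission", "discharge")) {
        counter <- counter + 1L
        fma <- if (tp == "admission") fma_adm[i] else fma_dis[i]
        base_bias <- if (side == "more_affected") spec$ml_bias_more[[tp]] else
          spec$ml_bias_less[[tp]]
        jit <- if (side == "more_affected") jit_more[i] else jit_less[i]
        prof <- profile_from_fma(fma, side,
                                 ml_bias = clip(base_bias + jit, 0.05, 0.95))
        sess_seed <- (as.numeric(spec$seed) * 1000 + counter) %%
          .Machine$integer.max
        sessions[[counter]] <- simulate_session(
          roster$participant[i], side, tp, arm, fma, prof,
          config, geometry, seed = sess_seed)
      }
    }
  }
  structure(list(spec = spec, config = config, geometry = geometry,
                 roster = roster, sessions = sessions),
            class = "reach_cohort")
}

#' Simulate a participant x side x time table of mediolateral proportions
#'
#' Direct generator of the response table the mixed model consumes, used
#' for calibration of the statistical engine (null behaviour, power).
#' Defaults reproduce the study-scale cell means; SDs default to the
#' module's variance components (participant SD 3, residual SD 3, in
#' percentage points).
#'
#' @param n_participants Number of participants.
#' @param intercept Less-affected admission mean, percent.
#' @param side_effect Added on the more-affected side.
#' @param time_effect Added at discharge.
#' @param interaction Added on the more-affected side at discharge.
#' @param sd_participant Random-intercept SD.
#' @param sd_resid Residual SD.
#' @param missing Optional number of randomly missing rows.
#' @return A data.frame with columns participant, side, time, ml_pct.
#' @export
simulate_proportion_table <- function(n_participants = 15,
                                      intercept = 53.1,
                                      side_effect = 15.5,
                                      time_effect = -0.8,
                                      interaction = -6.1,
                                      sd_participant = 3,
                                      sd_resid = 3,
                                      missing = 0) {
  d <- expand.grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    side = c("less_affected", "more_affected"),
    time = c("admission", "discharge"),
    stringsAsFactors = FALSE
  )
  b <- stats::setNames(stats::rnorm(n_participants, 0, sd_participant),
                       sprintf("P%02d", seq_len(n_participants)))
  more <- d$side == "more_affected"
  dis <- d$time == "discharge"
  d$ml_pct <- intercept + side_effect * more + time_effect * dis +
    interaction * (more & dis) + b[d$participant] +
    stats::rnorm(nrow(d), 0, sd_resid)
  if (missing > 0) d <- d[-sample(nrow(d), missing), ]
  d
}

#' Simulate a cohort table of per-cell quality metrics
#'
#' Direct generator of the participant x direction x side x time cell-mean
#' table consumed by the repeated-measures ANOVA, used for calibrating the
#' statistical engine (type-I error under the null, sphericity behaviour).
#'
#' @param n_participants Number of participants.
#' @param direction_effect Amplitude of an anteroposterior modulation
#'   (added as `effect * |sin(direction angle)|`).
#' @param side_effect Added on the more-affected side.
#' @param time_effect Added at discharge.
#' @param sd_participant Random-intercept SD.
#' @param sd_resid Residual SD.
#' @param intercept Baseline cell mean.
#' @param metric Metric name stored in the table.
#' @return A long data.frame: participant, group, side, timepoint,
#'   direction, metric, value.
#' @export
simulate_quality_table <- function(n_participants = 13,
                                   direction_effect = 0,
                                   side_effect = 0,
                                   time_effect = 0,
                                   sd_participant = 1,
                                   sd_resid = 1,
                                   intercept = 10,
                                   metric = "path_length") {
  d <- expand.grid(
    participant = sprintf("P%02d", seq_len(n_participants)),
    side = c("less_affected", "more_affected"),
    timepoint = c("admission", "discharge"),
    direction = direction_labels(),
    stringsAsFactors = FALSE
  )
  b <- stats::setNames(stats::rnorm(n_participants, 0, sd_participant),
                       sprintf("P%02d", seq_len(n_participants)))
  ap <- direction_apness()
  d$group <- "mild"
  d$metric <- metric
  d$value <- intercept + direction_effect * ap[d$direction] +
    side_effect * (d$side == "more_affected") +
    time_effect * (d$timepoint == "discharge") +
    b[d$participant] + stats::rnorm(nrow(d), 0, sd_resid)
  d[, c("participant", "group", "side", "timepoint", "direction",
        "metric", "value")]
}
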