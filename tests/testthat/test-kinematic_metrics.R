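cfg <- task_config()
geo <- arm_geometry()

test_that("speed computation: stationary, uniform and circular motion", {
  expect_equal(compute_speed(rep(1, 10), rep(2, 10)), rep(0, 10))
  # uniform motion: 1 cm per 100 ms = 10 cm/s
  t <- 0:500
  expect_equal(compute_speed(t * 0.01, rep(0, 501)), rep(10, 501))
  # circular path at constant angular rate: |v| = r * omega
  r <- 5; om <- 2 * pi  # one revolution per second
  tt <- seq(0, 1, by = 0.001)
  sp <- compute_speed(r * cos(om * tt), r * sin(om * tt))
  expect_equal(sp[2:1000], rep(r * om, 999), tolerance = 1e-4)
  expect_error(compute_speed(1:2, 1:2), "3 samples")
})

test_that("session thresholds pool pre-illumination windows", {
  set.seed(21)
  s <- simulate_session("P", "less_affected", "admission", "left", 60,
                        profile_from_fma(60, "less_affected"), cfg, geo,
                        seed = 77)
  thr <- compute_thresholds(s, cfg)
  # oracle: collect the same windows and apply a hand-rolled percentile
  pool <- unlist(lapply(s$trials, function(tr) {
    if (is.na(tr$target)) return(NULL)
    sp <- oracle_speed(tr$x, tr$y)
    sp[(tr$target_onset_time - 499):tr$target_onset_time]
  }))
  expect_equal(thr$lower, oracle_percentile(pool, 0.5), tolerance = 1e-10)
  expect_equal(thr$upper, oracle_percentile(pool, 0.95), tolerance = 1e-10)
  expect_lte(thr$lower, thr$upper)
  # order-free pooling
  s2 <- s; s2$trials <- rev(s2$trials)
  thr2 <- compute_thresholds(s2, cfg)
  expect_equal(thr$lower, thr2$lower)
  expect_equal(thr$upper, thr2$upper)
  # degenerate pool: a perfectly still hold gives (0, 0)
  s0 <- simulate_session("P", "less_affected", "admission", "left", 60,
                         healthy_profile(0), cfg, geo, seed = 78)
  thr0 <- compute_thresholds(s0, cfg)
  expect_equal(thr0$lower, 0)
  expect_equal(thr0$upper, 0)
})

test_that("onset detection follows the dual-threshold backward search", {
  # speed zero until motion starts, then strictly rising: onset is the last
  # sample below the lower threshold
  y <- c(numeric(701), cumsum(seq(0.001, 0.3, by = 0.001)))
  tr <- make_trial(numeric(length(y)), y, illum = 600)
  thr <- floor_thresholds(0.5, 2.0)
  onset <- detect_onset(tr, thr, cfg)
  expect_equal(as.integer(onset), oracle_onset(tr, thr, cfg))
  sp <- compute_speed(tr$x, tr$y)
  expect_lt(sp[onset + 1], 0.5)
  expect_gte(sp[onset + 2], 0.5)
  # monotone speed above both thresholds from illumination: fallback
  y2 <- c(numeric(601), cumsum(seq(0.02, 0.8, length.out = 900)))
  tr2 <- make_trial(numeric(length(y2)), y2, illum = 600)
  on2 <- detect_onset(tr2, floor_thresholds(0.001, 0.002), cfg)
  expect_equal(as.integer(on2), 600)
  expect_true(attr(on2, "fallback"))
  # a dip to a strict local minimum below the upper threshold is picked
  # when no later sample is below the lower threshold
  v <- c(numeric(400), 3 * sin(seq(0, pi, length.out = 200)),
         1.0 + 0.5 * sin(seq(0, pi, length.out = 100)) - 0.5,
         seq(1, 60, length.out = 500)) / 1000
  y3 <- cumsum(v)
  tr3 <- make_trial(numeric(length(y3)), y3, illum = 300)
  thr3 <- floor_thresholds(0.2, 2.0)
  on3 <- detect_onset(tr3, thr3, cfg)
  expect_equal(as.integer(on3), oracle_onset(tr3, thr3, cfg))
  expect_false(attr(on3, "fallback"))
  # preconditions
  trn <- tr; trn$target <- NA_character_
  expect_error(detect_onset(trn, thr, cfg), "no target")
})

test_that("offset detection returns the first containment sample", {
  # approach to 1.05 cm from the target, retreat, then enter
  tgt <- reachkin:::target_xy("M", cfg)
  d <- c(seq(10, 1.05, length.out = 500), seq(1.05, 1.6, length.out = 200),
         seq(1.6, 0.2, length.out = 300))
  x <- c(numeric(201), tgt[1] - d)
  y <- numeric(length(x))
  tr <- make_trial(x, y, illum = 200, target = "M", reached = TRUE)
  off <- detect_offset(tr, cfg)
  expect_equal(off, oracle_offset(tr, cfg))
  # entry is the first sample within 1 cm, not the closest approach
  dist_at <- sqrt((tr$x[off + 1] - tgt[1])^2 + (tr$y[off + 1] - tgt[2])^2)
  expect_lte(dist_at, cfg$peripheral_radius)
  expect_gt(off, 200 + 500)  # after the early near-miss
  trf <- tr; trf$reached_target <- FALSE
  expect_error(detect_offset(trf, cfg), "excluded")
})

test_that("path length sums segment norms and bounds the chord", {
  sq <- make_trial(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), illum = 0)
  expect_equal(path_length(sq, 0, 4), 4)
  # straight noiseless reach: path length equals the chord
  p <- minimum_jerk_reach(c(0, 0), c(0, 10), 700)
  tr <- make_trial(p[, 1], p[, 2], illum = 0, reached = TRUE)
  expect_equal(path_length(tr, 0, 700), 10, tolerance = 1e-9)
  # triangle inequality on simulated trials
  set.seed(23)
  for (i in 1:5) {
    trs <- simulate_trial(random_profile(), sample(direction_labels(), 1),
                          cfg, geo)
    if (!trs$reached_target) next
    off <- detect_offset(trs, cfg)
    on <- trs$target_onset_time
    chord <- sqrt((trs$x[off + 1] - trs$x[on + 1])^2 +
                    (trs$y[off + 1] - trs$y[on + 1])^2)
    expect_gte(path_length(trs, on, off), chord - 1e-12)
  }
})

test_that("zero-phase filtering: DC gain, band edges, no phase shift", {
  expect_equal(filter_speed(rep(3.2, 2000)), rep(3.2, 2000), tolerance = 1e-9)
  tt <- seq(0, 2, by = 0.001)
  s1 <- sin(2 * pi * 1 * tt)
  f1 <- filter_speed(s1)
  mid <- 500:1500
  expect_gt(max(f1[mid]) / max(s1[mid]), 0.99)
  s50 <- sin(2 * pi * 50 * tt)
  f50 <- filter_speed(s50)
  expect_lt(max(abs(f50[mid])), 0.01)
  # symmetric pulse keeps its peak sample
  pulse <- exp(-(seq(-500, 500))^2 / (2 * 60^2))
  fp <- filter_speed(pulse)
  expect_equal(which.max(fp), which.max(pulse))
  expect_error(filter_speed(rep(1, 10)), "too short")
})

test_that("peak counting uses strict neighbour comparisons", {
  expect_equal(count_velocity_peaks(c(0, 1, 2, 3, 2, 1, 0), 0, 6), 1)
  expect_equal(count_velocity_peaks(c(0, 1, 2, 1, 2, 1, 0), 0, 6), 2)
  # plateaus are not extrema
  expect_equal(count_velocity_peaks(c(0, 1, 1, 1, 0), 0, 4), 0)
  # window endpoints are never peaks
  expect_equal(count_velocity_peaks(c(3, 2, 1, 2, 3), 0, 4), 0)
  # agreement with the neighbour-scan oracle on random smooth series
  set.seed(24)
  for (i in 1:25) {
    v <- filter_speed(abs(cumsum(rnorm(600))))
    expect_equal(count_velocity_peaks(v, 0, 599), oracle_peaks(v))
  }
})

test_that("displacement decomposition and the L1 >= L2 identity", {
  tr <- make_trial(c(0, 1.5, 3), c(0, 2, 4), illum = 0)
  d <- displacement_components(tr, cfg)
  expect_equal(unname(d["ml_total"]), 3)
  expect_equal(unname(d["ap_total"]), 4)
  sq <- make_trial(c(0, 1, 1, 0, 0), c(0, 0, 1, 1, 0), illum = 0)
  dsq <- displacement_components(sq, cfg)
  expect_equal(unname(dsq["ml_total"]), 2)
  expect_equal(unname(dsq["ap_total"]), 2)
  # L1 total >= Euclidean path length over the same span
  set.seed(25)
  for (i in 1:6) {
    trs <- simulate_trial(random_profile(), sample(direction_labels(), 1),
                          cfg, geo)
    if (!trs$left_center) next
    d2 <- displacement_components(trs, cfg, span = "full")
    pl <- path_length(trs, trs$target_onset_time, trs$t[length(trs$t)])
    expect_gte(d2[["ml_total"]] + d2[["ap_total"]], pl - 1e-9)
  }
  # precondition: hand must have left the centre
  trn <- make_trial(numeric(100), numeric(100), illum = 10,
                    left_center = FALSE)
  expect_error(displacement_components(trn, cfg), "never left")
})

test_that("pooled mediolateral proportion and its missing-data rule", {
  expect_equal(participant_ml_proportion(1, 3), 75)
  expect_equal(participant_ml_proportion(c(2, 3), c(2, 3)), 50)
  expect_true(is.na(participant_ml_proportion(numeric(0), numeric(0))))
  expect_true(is.na(participant_ml_proportion(0, 0)))
})

test_that("joint-angle resampling normalizes trials onto a fixed grid", {
  tr <- make_trial(numeric(1001), numeric(1001), illum = 0)
  tr$shoulder_deg <- seq(30, 50, length.out = 1001)
  tr$elbow_deg <- seq(90, 60, length.out = 1001)
  nj <- resample_joint_angles(tr, 100, 900)
  expect_equal(nrow(nj), 101)
  expect_equal(nj$shoulder_delta[1], 0)
  expect_equal(nj$elbow_delta[1], 0)
  # linear ramps stay linear in percent
  expect_equal(nj$shoulder_delta, nj$percent / 100 * (20 * 800 / 1000),
               tolerance = 1e-9)
  # constant angles give all-zero deltas
  trc <- make_trial(numeric(500), numeric(500), illum = 0)
  njc <- resample_joint_angles(trc, 10, 400)
  expect_equal(njc$shoulder_delta, rep(0, 101))
  # grid length independent of duration
  expect_equal(nrow(resample_joint_angles(tr, 0, 300)), 101)
  expect_equal(nrow(resample_joint_angles(tr, 0, 1000)), 101)
})

test_that("metrics are invariant to translation and mirroring", {
  set.seed(26)
  prof <- random_profile()
  tr <- simulate_trial(prof, "LF", cfg, geo)
  while (!tr$reached_target) tr <- simulate_trial(prof, "LF", cfg, geo)
  thr <- floor_thresholds(0.6, 2.5)
  base <- quality_metrics(tr, thr, cfg)
  based <- displacement_components(tr, cfg)
  # translation by a resolution-multiple offset
  trt <- tr
  trt$x <- tr$x + 0.37; trt$y <- tr$y - 1.12
  trt$start_xy <- tr$start_xy + c(0.37, -1.12)
  trt$target_xy <- tr$target_xy + c(0.37, -1.12)
  shifted <- quality_metrics(trt, thr, cfg)
  expect_equal(shifted[c("onset", "offset", "movement_time")],
               base[c("onset", "offset", "movement_time")])
  expect_equal(shifted$path_length, base$path_length, tolerance = 1e-9)
  expect_equal(shifted$n_velocity_peaks, base$n_velocity_peaks)
  expect_equal(displacement_components(trt, cfg), based, tolerance = 1e-9)
  # mirroring
  trm <- mirror_trial(tr)
  mirrored <- quality_metrics(trm, thr, cfg)
  expect_equal(mirrored[c("onset", "offset", "movement_time")],
               base[c("onset", "offset", "movement_time")])
  expect_equal(mirrored$path_length, base$path_length, tolerance = 1e-12)
  expect_equal(mirrored$n_velocity_peaks, base$n_velocity_peaks)
  expect_equal(displacement_components(trm, cfg), based, tolerance = 1e-12)
})

test_that("noiseless unimpaired sessions recover the generated kinematics", {
  set.seed(27)
  s <- simulate_session("P", "less_affected", "admission", "left", 66,
                        healthy_profile(0), cfg, geo, seed = 555)
  m <- session_metrics(s, cfg)
  q <- m[m$included_quality, ]
  expect_gt(nrow(q), 55)
  # with degenerate (0,0) thresholds onset falls back to illumination, so
  # movement time equals the realized reach duration exactly
  rd <- vapply(s$trials, function(tr) if (is.na(tr$reach_duration)) NA_integer_
               else tr$reach_duration, integer(1))
  expect_true(all(abs(q$movement_time_ms - rd[q$trial]) <= 2))
  expect_true(all(q$onset_fallback))
  # path length: straight 10-cm reach minus the 1-cm entry margin
  expect_true(all(abs(q$path_length_cm - 9) < 0.02 * 10))
  # smoothness judged from the movement window via device-floor thresholds
  thr <- floor_thresholds(0.5, 2.0)
  for (i in q$trial[1:10]) {
    qm <- quality_metrics(s$trials[[i]], thr, cfg)
    expect_equal(qm$n_velocity_peaks, 1)
  }
})
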