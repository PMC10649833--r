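cfg <- task_config()
geo <- arm_geometry()

test_that("minimum-jerk reach hits its endpoints with a unimodal speed profile", {
  path <- minimum_jerk_reach(c(0, 0), c(0, 10), 800)
  expect_equal(nrow(path), 801)
  expect_equal(path[1, ], c(0, 0))
  expect_equal(path[801, ], c(0, 10))
  fsp <- filter_speed(compute_speed(path[, 1], path[, 2]))
  expect_equal(count_velocity_peaks(fsp, 0, 800), 1)
  # and for a variety of durations/directions
  set.seed(2)
  for (i in 1:5) {
    D <- round(runif(1, 400, 2000))
    p <- minimum_jerk_reach(c(0, 0), reachkin:::target_xy(
      sample(direction_labels(), 1), cfg), D)
    expect_equal(count_velocity_peaks(
      filter_speed(compute_speed(p[, 1], p[, 2])), 0, D), 1)
  }
})

test_that("submovements add exactly one filtered speed peak each", {
  set.seed(3)
  for (k in 0:4) {
    D <- max(350, if (k > 0) 620 + 195 * (k - 1) else 0) + 300
    path <- minimum_jerk_reach(c(0, 0), c(10, 0), D)
    out <- add_submovements(path, k)
    expect_equal(out[1, ], path[1, ])
    expect_equal(out[nrow(out), ], path[nrow(path), ])
    expect_equal(nrow(out), nrow(path))
    fsp <- filter_speed(compute_speed(out[, 1], out[, 2]))
    expect_equal(count_velocity_peaks(fsp, 0, D), 1 + k)
  }
  # identity at k = 0 and determinism under an explicit seed
  path <- minimum_jerk_reach(c(0, 0), c(0, 10), 900)
  expect_identical(add_submovements(path, 0), path)
  a <- add_submovements(path, 2, seed = 99)
  b <- add_submovements(path, 2, seed = 99)
  expect_identical(a, b)
})

test_that("two-link inverse kinematics anchors the start posture and round-trips", {
  ja <- joint_angles_from_hand(0, 0, geo)
  expect_equal(ja$shoulder_deg, 30, tolerance = 1e-10)
  expect_equal(ja$elbow_deg, 90, tolerance = 1e-10)
  # forward/inverse round trip over random workspace points
  set.seed(4)
  x <- runif(50, -11, 11); y <- runif(50, -11, 11)
  ja <- joint_angles_from_hand(x, y, geo)
  h <- hand_from_joint_angles(ja$shoulder_deg, ja$elbow_deg, geo)
  expect_equal(h$x, x, tolerance = 1e-9)
  expect_equal(h$y, y, tolerance = 1e-9)
  # full extension: elbow angle zero at distance L1 + L2 from the shoulder
  S <- geo$shoulder_xy
  u <- c(0.6, 0.8)
  p <- S + (geo$L1 + geo$L2) * u
  expect_equal(joint_angles_from_hand(p[1], p[2], geo)$elbow_deg, 0,
               tolerance = 1e-5)
  # unreachable point rejected with a sample reference
  expect_error(joint_angles_from_hand(S[1] + 70, S[2], geo), "unreachable")
})

test_that("simulated trials honour the state machine's outcome branches", {
  set.seed(5)
  # unimpaired limit: always reached, near-straight path
  tr <- simulate_trial(healthy_profile(0), "MF", cfg, geo)
  expect_true(tr$reached_target)
  expect_true(tr$left_center)
  expect_lte(tr$reach_duration, cfg$reach_limit)
  off <- detect_offset(tr, cfg)
  pl <- path_length(tr, tr$target_onset_time, off)
  chord <- sqrt(sum((c(tr$x[off + 1], tr$y[off + 1]))^2))
  expect_lt(pl, 1.02 * chord)
  # forced hold failure: no target, not left
  trf <- simulate_trial(impairment_profile(hold_failure_prob = 1), "F", cfg, geo)
  expect_true(is.na(trf$target))
  expect_false(trf$left_center)
  expect_identical(trf$outcome, "no_target")
  # forced never-left branch
  trn <- simulate_trial(impairment_profile(attempt_prob = 0, noise_sd = 0.05),
                        "F", cfg, geo)
  expect_false(trn$left_center)
  expect_false(trn$reached_target)
  # incomplete mover leaves but never reaches
  tri <- simulate_trial(impairment_profile(
    completion_prob_by_direction = setNames(rep(0, 8), direction_labels()),
    noise_sd = 0.05), "F", cfg, geo)
  expect_true(tri$left_center)
  expect_false(tri$reached_target)
  expect_identical(tri$outcome, "incomplete")
})

test_that("all emitted coordinates are multiples of the spatial resolution", {
  set.seed(6)
  for (i in 1:6) {
    tr <- simulate_trial(random_profile(), sample(direction_labels(), 1),
                         cfg, geo)
    expect_true(all(abs(tr$x * 100 - round(tr$x * 100)) < 1e-9))
    expect_true(all(abs(tr$y * 100 - round(tr$y * 100)) < 1e-9))
    expect_identical(diff(tr$t), rep(1L, length(tr$t) - 1))
  }
})

test_that("sessions use a blocked-random schedule and are seed-reproducible", {
  prof <- profile_from_fma(40, "more_affected")
  s1 <- simulate_session("P01", "more_affected", "admission", "left", 40,
                         prof, cfg, geo, seed = 123)
  s2 <- simulate_session("P01", "more_affected", "admission", "left", 40,
                         prof, cfg, geo, seed = 123)
  expect_identical(s1, s2)
  expect_length(s1$trials, 64)
  sched <- vapply(s1$trials, function(tr) tr$scheduled_target, character(1))
  for (b in seq_len(8)) {
    block <- sched[((b - 1) * 8 + 1):(b * 8)]
    expect_setequal(block, direction_labels())
  }
  # a different seed gives a different session
  s3 <- simulate_session("P01", "more_affected", "admission", "left", 40,
                         prof, cfg, geo, seed = 124)
  expect_false(identical(s1$trials[[1]]$x, s3$trials[[1]]$x))
})

test_that("cohort generation respects group sizes, FMA ranges and determinism", {
  spec <- cohort_spec(n_mild = 3, n_severe = 3, seed = 11)
  co <- simulate_cohort(spec, cfg, geo)
  expect_equal(nrow(co$roster), 6)
  expect_length(co$sessions, 24)
  mild <- co$roster[co$roster$group == "mild", ]
  expect_true(all(mild$fma_admission > 45 & mild$fma_discharge > 45))
  sev <- co$roster[co$roster$group == "moderate_to_severe", ]
  expect_true(all(sev$fma_admission <= 45 & sev$fma_discharge <= 45))
  expect_true(all(co$roster$fma_discharge >= co$roster$fma_admission))
  # severity labels agree with the classifier
  expect_true(all(classify_severity(mild$fma_admission)$group == "mild"))
  expect_true(all(classify_severity(sev$fma_admission)$group ==
                    "moderate_to_severe"))
  co2 <- simulate_cohort(cohort_spec(n_mild = 3, n_severe = 3, seed = 11),
                         cfg, geo)
  expect_identical(co, co2)
})

test_that("injected direction time-scaling lengthens measured movement times", {
  labs <- direction_labels()
  base <- impairment_profile(noise_sd = 0.04,
                             extra_submovements_by_direction =
                               setNames(rep(0.3, 8), labs))
  scaled <- base
  scaled$time_scale_by_direction <- setNames(
    ifelse(labs %in% c("F", "B"), 1.5, 1), labs)
  mt_for <- function(prof, seed) {
    s <- simulate_session("P", "more_affected", "admission", "left", 60,
                          prof, cfg, geo, seed = seed)
    m <- session_metrics(s, cfg)
    m <- m[m$included_quality & m$direction %in% c("F", "B"), ]
    mean(m$movement_time_ms)
  }
  for (seed in c(41, 42, 43)) {
    expect_gte(mt_for(scaled, seed), mt_for(base, seed))
  }
})
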