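# Independent brute-force oracles and small fixture builders.
# Oracles are written as literal loops over the definitions, deliberately
# structured differently from the package's vectorized implementations.

# speed by explicit per-sample differences
oracle_speed <- function(x, y, rate = 1000) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (i == 1) {
      out[i] <- sqrt((x[2] - x[1])^2 + (y[2] - y[1])^2) * rate
    } else if (i == n) {
      out[i] <- sqrt((x[n] - x[n - 1])^2 + (y[n] - y[n - 1])^2) * rate
    } else {
      out[i] <- sqrt(((x[i + 1] - x[i - 1]) / 2)^2 +
                       ((y[i + 1] - y[i - 1]) / 2)^2) * rate
    }
  }
  out
}

# backward scan from the leave sample, sample by sample
oracle_onset <- function(trial, thresholds, config) {
  sp <- oracle_speed(trial$x, trial$y, config$sample_rate)
  illum <- trial$target_onset_time
  thr_leave <- left_center_threshold(config)
  t_leave <- NA
  for (t in illum:(length(trial$x) - 1)) {
    d <- sqrt((trial$x[t + 1] - trial$start_xy[1])^2 +
                (trial$y[t + 1] - trial$start_xy[2])^2)
    if (d > thr_leave) { t_leave <- t; break }
  }
  if (is.na(t_leave)) stop("oracle: hand never left centre")
  n <- length(sp)
  for (t in seq(t_leave, illum)) {
    i <- t + 1
    s <- sp[i]
    s_prev <- sp[max(i - 1, 1)]
    s_next <- sp[min(i + 1, n)]
    if (s < s_prev && s < s_next && s < thresholds$upper) return(t)
    if (s < thresholds$lower) return(t)
  }
  illum
}

# forward scan for the first containment sample
oracle_offset <- function(trial, config) {
  r <- target_entry_radius(config)
  illum <- trial$target_onset_time
  for (t in illum:(length(trial$x) - 1)) {
    d <- sqrt((trial$x[t + 1] - trial$target_xy[1])^2 +
                (trial$y[t + 1] - trial$target_xy[2])^2)
    if (d <= r) return(t)
  }
  stop("oracle: never entered the target")
}

# neighbour scan peak counter
oracle_peaks <- function(v) {
  count <- 0L
  for (j in seq(2, length(v) - 1)) {
    if (v[j] > v[j - 1] && v[j] > v[j + 1]) count <- count + 1L
  }
  count
}

# linear-interpolation percentile between closest ranks, from first principles
oracle_percentile <- function(pool, p) {
  s <- sort(pool)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Balanced fully-within repeated-measures ANOVA from first principles:
# inclusion-exclusion effect estimates per observation; SS of an effect is
# the sum of its squared estimates; each within effect is tested against
# its interaction with subject.
oracle_rm_anova <- function(data, dv, within, subject) {
  facs <- c(within, subject)
  for (f in facs) data[[f]] <- factor(data[[f]])
  grand <- mean(data[[dv]])
  mean_cache <- list()
  subset_mean <- function(U) {
    if (!length(U)) return(rep(grand, nrow(data)))
    k <- paste(sort(U), collapse = "|")
    if (is.null(mean_cache[[k]])) {
      g <- do.call(interaction, c(unname(data[U]), list(drop = TRUE)))
      mean_cache[[k]] <<- stats::ave(data[[dv]], g, FUN = mean)
    }
    mean_cache[[k]]
  }
  effect_vec <- function(T) {
    v <- rep(0, nrow(data))
    for (m in 0:length(T)) {
      subs <- if (m == 0) list(character(0)) else
        utils::combn(T, m, simplify = FALSE)
      for (U in subs) v <- v + (-1)^(length(T) - m) * subset_mean(U)
    }
    v
  }
  ss <- function(T) sum(effect_vec(T)^2)
  df <- function(T) prod(vapply(T, function(f) nlevels(data[[f]]) - 1L, 1L))
  effects <- unlist(lapply(seq_along(within), function(m)
    utils::combn(within, m, simplify = FALSE)), recursive = FALSE)
  rows <- lapply(effects, function(E) {
    ssE <- ss(E); dfE <- df(E)
    ssErr <- ss(c(E, subject)); dfErr <- df(c(E, subject))
    Fv <- (ssE / dfE) / (ssErr / dfErr)
    data.frame(effect = paste(E, collapse = ":"),
               df1 = dfE, df2 = dfErr, ss = ssE, ss_error = ssErr, F = Fv,
               p = stats::pf(Fv, dfE, dfErr, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# minimal trial fixture from raw coordinate series
make_trial <- function(x, y, illum = 0L, target = "F",
                       config = task_config(), left_center = TRUE,
                       reached = FALSE, reach_duration = NA_integer_,
                       arm = "left") {
  structure(list(
    trial_index = 1L,
    scheduled_target = target,
    target = target,
    t = as.integer(seq_along(x) - 1),
    x = x, y = y,
    shoulder_deg = rep(30, length(x)),
    elbow_deg = rep(90, length(x)),
    start_xy = c(0, 0),
    target_xy = reachkin:::target_xy(target, config),
    target_onset_time = as.integer(illum),
    left_center = left_center,
    reached_target = reached,
    reach_duration = reach_duration,
    outcome = if (reached) "reached" else if (left_center) "incomplete"
      else "never_left",
    recorded_arm = arm,
    sim = list(latency_ms = NA_integer_, reach_ms = NA_integer_,
               n_submovements = NA_integer_)
  ), class = "reach_trial")
}

# device-floor thresholds used for smoothness checks on noiseless traces
floor_thresholds <- function(lower = 0.5, upper = 2.0) {
  structure(list(lower = lower, upper = upper), class = "speed_thresholds")
}

# a mixed severity profile with a bit of everything, for oracle sweeps
random_profile <- function() {
  labs <- direction_labels()
  impairment_profile(
    attempt_prob = stats::runif(1, 0.6, 1),
    completion_prob_by_direction = stats::setNames(stats::runif(8, 0.3, 1), labs),
    time_scale_by_direction = stats::setNames(1 + stats::runif(8, 0, 0.5), labs),
    extra_submovements_by_direction = stats::setNames(stats::runif(8, 0, 1.5), labs),
    ml_bias = stats::runif(1, 0.3, 0.8),
    hold_failure_prob = stats::runif(1, 0, 0.1),
    noise_sd = stats::runif(1, 0.02, 0.08),
    base_reach_ms = stats::runif(1, 550, 900)
  )
}

# participants with complete direction x side x time cells (the analysis
# group definition: able to reach every direction at every session)
complete_case_participants <- function(quality_tab) {
  tab <- table(quality_tab$participant,
               interaction(quality_tab$direction, quality_tab$side,
                           quality_tab$timepoint, quality_tab$metric))
  rownames(tab)[apply(tab == 1, 1, all)]
}
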