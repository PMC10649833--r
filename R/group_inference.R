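# Group-level inference: aggregation to design cells, three-way
# repeated-measures ANOVA with Mauchly's sphericity test and conditional
# Greenhouse-Geisser correction, a random-intercept mixed model of the
# mediolateral displacement proportion, and paired t tests on FMA-UE.

#' Aggregate quality-arm trial metrics to design-cell means
#'
#' Mean movement time, path length and velocity-peak count per participant
#' x side x timepoint x direction, over quality-qualified trials of the
#' mild group (the group able to reach in all eight directions).
#'
#' @param metrics A [cohort_metrics()] table.
#' @param group Participant group retained.
#' @return A long data.frame: participant, group, side, timepoint,
#'   direction, metric, value.
#' @export
aggregate_quality <- function(metrics, group = "mild") {
  d <- metrics[metrics$group %in% group & metrics$included_quality, ]
  if (!nrow(d)) stop("no quality-qualified trials for group ", group)
  cols <- c(movement_time = "movement_time_ms",
            path_length = "path_length_cm",
            n_velocity_peaks = "n_velocity_peaks")
  out <- lapply(names(cols), function(m) {
    ag <- stats::aggregate(d[[cols[[m]]]],
                           by = list(participant = d$participant,
                                     side = d$side,
                                     timepoint = d$timepoint,
                                     direction = d$direction),
                           FUN = mean)
    names(ag)[names(ag) == "x"] <- "value"
    ag$metric <- m
    ag
  })
  out <- do.call(rbind, out)
  out$group <- unique(d$group)[1]
  out[, c("participant", "group", "side", "timepoint", "direction",
          "metric", "value")]
}

#' Aggregate quantity-arm trial metrics to per-session ML proportions
#'
#' Pools AP/ML displacement over each session's quantity-qualified trials
#' and computes the mediolateral percentage. Sessions with no qualified
#' trial yield no row; they are listed in the `missing` attribute rather
#' than silently dropped.
#'
#' @param metrics A [cohort_metrics()] table.
#' @param group Participant group retained.
#' @return A data.frame: participant, group, side, time, ap_total_cm,
#'   ml_total_cm, ml_pct; missing sessions in `attr(, "missing")`.
#' @export
aggregate_quantity <- function(metrics, group = "moderate_to_severe") {
  d <- metrics[metrics$group %in% group, ]
  if (!nrow(d)) stop("no trials for group ", group)
  key <- interaction(d$participant, d$side, d$timepoint, drop = TRUE)
  rows <- lapply(split(d, key), function(s) {
    q <- s[s$included_quantity, ]
    ml_pct <- participant_ml_proportion(q$ap_total_cm, q$ml_total_cm)
    data.frame(participant = s$participant[1], group = s$group[1],
               side = s$side[1], time = s$timepoint[1],
               n_trials = nrow(q),
               ap_total_cm = sum(q$ap_total_cm),
               ml_total_cm = sum(q$ml_total_cm),
               ml_pct = ml_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  missing <- out[is.na(out$ml_pct), c("participant", "side", "time")]
  out <- out[!is.na(out$ml_pct), ]
  attr(out, "missing") <- missing
  out
}

#' Repeated-measures ANOVA with sphericity handling
#'
#' Full within-subject decomposition for a completely crossed design
#' (every participant measured in every cell), computed through a
#' multivariate linear model with `car::Anova`. For each multi-level
#' effect, Mauchly's test of sphericity is run on the orthonormal-contrast
#' covariance; when its P value is below `alpha` the Greenhouse-Geisser
#' correction is applied to that effect's degrees of freedom and P value.
#' Corrected dfs are the uncorrected dfs multiplied by epsilon; epsilon is
#' 1 for two-level factors. A sum-of-squares conservation identity (total
#' SS equals subject SS plus all effect and error components) is verified
#' on every call.
#'
#' @param data Long data.frame.
#' @param dv Name of the response column.
#' @param within Names of the within-subject factor columns.
#' @param subject Name of the subject column.
#' @param alpha Significance level for Mauchly's test (and reported tests).
#' @return An `anova_rm_result`: a data.frame with one row per effect
#'   (df1, df2, F, p, mauchly_w, mauchly_p, gg_epsilon,
#'   correction_applied, df1_report, df2_report, p_report).
#' @export
rm_anova <- function(data, dv = "value",
                     within = c("direction", "side", "timepoint"),
                     subject = "participant", alpha = 0.05) {
  data <- as.data.frame(data)
  for (w in c(within, subject)) data[[w]] <- factor(data[[w]])
  cells <- do.call(interaction, c(unname(data[within]), list(drop = FALSE)))
  tab <- table(data[[subject]], cells)
  if (any(tab != 1)) {
    bad <- which(tab != 1, arr.ind = TRUE)
    stop("incomplete repeated-measures design: ",
         nrow(bad), " subject x cell combination(s) missing or duplicated, e.g. ",
         rownames(tab)[bad[1, 1]], " / ", colnames(tab)[bad[1, 2]])
  }
  # wide subject x cell matrix, cells in idata order
  idata <- expand.grid(lapply(data[within], levels))
  names(idata) <- within
  cell_names <- do.call(paste, c(idata, sep = "."))
  wide <- matrix(NA_real_, nlevels(data[[subject]]), nrow(idata),
                 dimnames = list(levels(data[[subject]]), cell_names))
  row_cell <- do.call(paste, c(unname(data[within]), sep = "."))
  wide[cbind(as.character(data[[subject]]), row_cell)] <- data[[dv]]
  mod <- stats::lm(wide ~ 1)
  idesign <- stats::as.formula(paste("~", paste(within, collapse = "*")))
  an <- car::Anova(mod, idata = idata, idesign = idesign, type = "III")
  sm <- withCallingHandlers(
    summary(an, multivariate = FALSE),
    warning = function(w) {
      if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
    })
  ut <- sm$univariate.tests
  effects <- setdiff(rownames(ut), "(Intercept)")
  res <- data.frame(
    effect = effects,
    df1 = ut[effects, "num Df"],
    df2 = ut[effects, "den Df"],
    ss = ut[effects, "Sum Sq"],
    ss_error = ut[effects, "Error SS"],
    F = ut[effects, "F value"],
    p = ut[effects, "Pr(>F)"],
    mauchly_w = NA_real_, mauchly_p = NA_real_,
    gg_epsilon = 1,
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(sm$sphericity.tests) && nrow(sm$sphericity.tests)) {
    st <- sm$sphericity.tests
    pa <- sm$pval.adjustments
    for (e in intersect(rownames(st), effects)) {
      i <- match(e, res$effect)
      res$mauchly_w[i] <- st[e, "Test statistic"]
      res$mauchly_p[i] <- st[e, "p-value"]
      res$gg_epsilon[i] <- pa[e, "GG eps"]
    }
  }
  res$correction_applied <- !is.na(res$mauchly_p) & res$mauchly_p < alpha
  res$df1_report <- res$df1 * ifelse(res$correction_applied, res$gg_epsilon, 1)
  res$df2_report <- res$df2 * ifelse(res$correction_applied, res$gg_epsilon, 1)
  res$p_gg <- stats::pf(res$F, res$df1 * res$gg_epsilon,
                        res$df2 * res$gg_epsilon, lower.tail = FALSE)
  res$p_report <- ifelse(res$correction_applied, res$p_gg, res$p)

  # SS conservation: total = subject + sum(effect + error)
  ss_subject <- ut["(Intercept)", "Error SS"]
  ss_total <- sum((wide - mean(wide))^2)
  ss_parts <- ss_subject + sum(res$ss) + sum(res$ss_error)
  if (abs(ss_total - ss_parts) > 1e-8 * max(1, ss_total)) {
    stop("sum-of-squares decomposition failed to conserve total SS")
  }
  structure(res, class = c("anova_rm_result", "data.frame"),
            alpha = alpha, n_subjects = nrow(wide),
            ss_total = ss_total, ss_subject = ss_subject)
}

#' Three-way repeated-measures ANOVA of one quality metric
#'
#' Within-participant factors direction (8) x side (2) x time (2), applied
#' to one metric of the aggregated quality table, as in the
#' direction-dependence analysis of the mild group.
#'
#' @param cohort_table An [aggregate_quality()] table.
#' @param metric One of `"movement_time"`, `"path_length"`,
#'   `"n_velocity_peaks"`.
#' @param alpha Significance level.
#' @return An `anova_rm_result`.
#' @export
rm_anova_3way <- function(cohort_table, metric, alpha = 0.05) {
  d <- cohort_table[cohort_table$metric == metric, ]
  if (!nrow(d)) stop("metric not found in table: ", metric)
  out <- rm_anova(d, dv = "value",
                  within = c("direction", "side", "timepoint"),
                  subject = "participant", alpha = alpha)
  attr(out, "metric") <- metric
  out
}

#' Mixed-effects model of the mediolateral displacement proportion
#'
#' Random-intercept model `ml_pct ~ side * time + (1 | participant)`, fit
#' by REML, with type-III F tests and Satterthwaite denominator degrees of
#' freedom (fractional dfs, as SPSS reports). Missing participant x
#' timepoint cells are tolerated without dropping whole participants.
#'
#' @param table An [aggregate_quantity()] table (or any data.frame with
#'   `participant`, `side`, `time`, `ml_pct`).
#' @return An `lmm_result` list: `fixed` (coefficient table), `anova`
#'   (F tests), `varcor` (random-intercept and residual variance),
#'   `logLik`, `singular`, `df_method`, and the fitted `model`.
#' @export
fit_lmm_proportion <- function(table) {
  d <- as.data.frame(table)
  d <- d[!is.na(d$ml_pct), ]
  if (length(unique(d$participant)) < 2) stop("need at least 2 participants")
  if (stats::var(d$ml_pct) == 0) {
    stop("degenerate response: all ml_pct values identical")
  }
  d$side <- factor(d$side)
  d$time <- factor(d$time)
  fit <- lmerTest::lmer(ml_pct ~ side * time + (1 | participant), data = d,
                        REML = TRUE,
                        contrasts = list(side = "contr.sum",
                                         time = "contr.sum"))
  av <- stats::anova(fit, type = 3, ddf = "Satterthwaite")
  co <- summary(fit)$coefficients
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(
    fixed = data.frame(term = rownames(co),
                       estimate = co[, "Estimate"],
                       se = co[, "Std. Error"],
                       df = co[, "df"],
                       t = co[, "t value"],
                       p = co[, "Pr(>|t|)"],
                       row.names = NULL),
    anova = data.frame(effect = rownames(av),
                       df1 = av$NumDF, df2 = av$DenDF,
                       F = av$`F value`, p = av$`Pr(>F)`,
                       row.names = NULL),
    varcor = c(participant = vc$vcov[vc$grp == "participant"],
               residual = vc$vcov[vc$grp == "Residual"]),
    logLik = as.numeric(stats::logLik(fit)),
    singular = lme4::isSingular(fit),
    df_method = "Satterthwaite",
    model = fit
  ), class = "lmm_result")
}

#' Paired t test on admission vs discharge scores
#'
#' Classical paired t on the differences (discharge minus admission),
#' df = n - 1, two-sided.
#'
#' @param admission,discharge Equal-length paired score vectors.
#' @return A list: t, df, p, mean_diff, n.
#' @export
paired_t <- function(admission, discharge) {
  if (length(admission) != length(discharge)) stop("unpaired samples")
  n <- length(admission)
  if (n < 2) stop("need at least 2 pairs")
  d <- discharge - admission
  if (stats::var(d) == 0) stop("zero variance of paired differences")
  tt <- stats::t.test(discharge, admission, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_diff = mean(d), n = n)
}

#' FMA-UE paired t tests per group
#'
#' @param roster A cohort roster with `group`, `fma_admission`,
#'   `fma_discharge`.
#' @return A data.frame, one row per group: n, mean gain, t, df, p.
#' @export
fma_paired_tests <- function(roster) {
  rows <- lapply(split(roster, roster$group), function(g) {
    pt <- paired_t(g$fma_admission, g$fma_discharge)
    data.frame(group = g$group[1], n = pt$n, mean_gain = pt$mean_diff,
               t = pt$t, df = pt$df, p = pt$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
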