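#!/usr/bin/env Rscript
# Stage 2: trial qualification and per-trial kinematic metrics.
#
# Right-arm sessions are flipped to the left-arm frame; each session's
# speed thresholds are pooled from the 500-ms pre-illumination windows;
# movement onset/offset, movement time, path length, velocity peaks and
# AP/ML displacement are computed per trial. Per-trial rows go to
# scratch/ (large); qualification summaries and the aggregated analysis
# tables go to results/.

suppressMessages(library(reachkin))

cohort <- readRDS("scratch/cohort.rds")
cfg <- cohort$config

message("computing per-trial metrics for ", length(cohort$sessions),
        " sessions ...")
metrics <- cohort_metrics(cohort, cfg)
write.csv(metrics, "scratch/metrics_per_trial.csv", row.names = FALSE)

qual <- do.call(rbind, lapply(cohort$sessions, function(s) {
  rbind(qualification_row(qualify_quality(s, cfg)$report),
        qualification_row(qualify_quantity(s, cfg)$report))
}))
qual$group <- cohort$roster$group[match(qual$participant,
                                        cohort$roster$participant)]
write.csv(qual, "results/qualification_reports.csv", row.names = FALSE)

message("mean exclusion percentages (more-affected side):")
print(aggregate(pct_excluded ~ analysis_arm + group + timepoint,
                qual[qual$side == "more_affected", ], mean))

quality_tab <- aggregate_quality(metrics)
write.csv(quality_tab, "results/quality_cell_means.csv", row.names = FALSE)

quantity_tab <- aggregate_quantity(metrics)
write.csv(quantity_tab, "results/quantity_ml_proportions.csv",
          row.names = FALSE)
miss <- attr(quantity_tab, "missing")
if (nrow(miss)) {
  message("sessions with no quantity-qualified trial (missing ml%):")
  print(miss)
}

message("pooled mediolateral proportion (moderate-to-severe group):")
print(aggregate(ml_pct ~ side + time, quantity_tab,
                function(x) round(c(mean = mean(x), sd = sd(x)), 1)))
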