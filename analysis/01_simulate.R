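#!/usr/bin/env Rscript
# Stage 1: simulate the synthetic study cohort.
#
# 13 mild and 15 moderate-to-severe participants, each recorded on the
# more- and less-affected side at admission and discharge: 112 sessions of
# 64 center-out reaching trials at 1 kHz. The full per-millisecond
# recordings are large and go to scratch/ (session CSVs plus an .rds used
# by the later stages); the roster and session manifest go to results/.

suppressMessages(library(reachkin))

seed <- 424242
spec <- cohort_spec(seed = seed)
cfg <- task_config()
geo <- arm_geometry()

dir.create("results", showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

message("simulating ", spec$n_mild, " mild + ", spec$n_severe,
        " moderate-to-severe participants (seed ", seed, ") ...")
cohort <- simulate_cohort(spec, cfg, geo, progress = TRUE)
saveRDS(cohort, "scratch/cohort.rds")

# write one example session in the on-disk interchange format, plus the
# cohort roster for the record
write_session(cohort$sessions[[1]], "scratch/example_session")
write.csv(cohort$roster, "results/roster.csv", row.names = FALSE)

fma <- fma_paired_tests(cohort$roster)
write.csv(fma, "results/fma_paired_t.csv", row.names = FALSE)
message("FMA-UE improvement, paired t per group:")
print(fma)
message("cohort in scratch/cohort.rds; roster in results/roster.csv")
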