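#!/usr/bin/env Rscript
# Step 1 — generate the synthetic study cohorts and persist them in the
# package's on-disk formats, so the rest of the workflow runs from files
# exactly as it would for acquisition-system exports.
#
# Writes under results/data/: minute-resolution drinking logs (CSV),
# schedule (YAML) and weights (CSV) for the 35-mouse reference cohort and
# the two minipump-pretreatment cohorts.

suppressPackageStartupMessages(library(bottlechoice))

seed <- 101
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)

message("Reference cohort: 35 mice, ascending 10/50/100/200 µg/ml task")
coh <- reference_cohort(seed = seed)
write_drink_log(coh$logs, "results/data/reference_logs.csv")
write_weights(coh$records, "results/data/reference_weights.csv")
write_schedule(coh$schedule, "results/data/reference_schedule.yaml")
write.csv(coh$truth, "results/data/reference_truth.csv", row.names = FALSE)

message("Minipump cohorts: single-step 100 µg/ml protocol")
for (tr in c("saline", "nicotine")) {
  mp <- minipump_cohort(tr, seed = seed + match(tr, c("saline", "nicotine")))
  write_drink_log(mp$logs, sprintf("results/data/minipump_%s_logs.csv", tr))
  write_weights(mp$records,
                sprintf("results/data/minipump_%s_weights.csv", tr))
  write_schedule(mp$schedule,
                 sprintf("results/data/minipump_%s_schedule.yaml", tr))
}

message("Cohort files written to results/data/")
message("Archetype mix: ",
        paste(capture.output(table(coh$truth$archetype)), collapse = "\n"))
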