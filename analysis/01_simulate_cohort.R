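#!/usr/bin/env Rscript
# Step 1: simulate the synthetic cohort (12 clinical vs 11 control
# participants, full condition grid: four 30 s sway conditions and two
# 8-perturbation trials each, plus counting records) and write it out as
# trial CSVs for the file-based pipeline.
#
# Raw trial files are bulky, so they go under scratch/; the per-trial
# ground truth and the participant table land in results/.

suppressPackageStartupMessages(library(posturolab))

seed <- 20260923
cohort_dir <- "scratch/cohort"
dir.create("results", showWarnings = FALSE)

cfg <- default_generator_config(seed = seed)
cohort <- simulate_cohort(cfg)
write_cohort(cohort, cohort_dir)

utils::write.csv(cohort$participants, "results/participants.csv",
                 row.names = FALSE)

cat(sprintf("Simulated %d trials for %d participants (seed %d)\n",
            length(cohort$trials), nrow(cohort$participants), seed))
cat(sprintf("Trial CSVs: %s; ground truth: %s/truth.json\n",
            cohort_dir, cohort_dir))
n_events <- sum(vapply(cohort$trials,
                       function(tr) nrow(tr$events), integer(1)))
cat(sprintf("Perturbation events simulated: %d\n", n_events))
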