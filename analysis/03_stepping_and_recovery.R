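#!/usr/bin/env Rscript
# Step 3: response-strategy breakdown. Tallies in-place vs stepping
# responses, compares multiple-step episode frequency between groups
# (plain chi-squared, Yates, Fisher side by side), and summarises recovery
# time per perturbation type. Checks the pipeline's recovery times against
# the generator's ground truth.

suppressPackageStartupMessages({
  library(posturolab)
  library(dplyr)
})

in_dir <- "scratch/cohort"
out_dir <- "results/analysis"
cohort_csv <- file.path(out_dir, "cohort.csv")
if (!file.exists(cohort_csv)) {
  stop("run analysis/02_analyze_cohort.R first (no ", cohort_csv, ")")
}
tbl <- tibble::as_tibble(utils::read.csv(cohort_csv))

rt <- tbl |>
  filter(trial_kind == "perturbation", !discarded, metric == "recovery_time")
strategy_tbl <- rt |> count(group, strategy) |> tidyr::pivot_wider(
  names_from = strategy, values_from = n, values_fill = 0)
cat("Response strategies (per perturbation):\n")
print(as.data.frame(strategy_tbl))

steppers <- rt |>
  group_by(participant_id, group) |>
  summarise(any_step = any(strategy != "in_place"),
            any_multi = any(strategy == "multiple_steps"), .groups = "drop") |>
  filter(any_step)
tab <- with(steppers, table(factor(group, c("PD", "control")),
                            factor(any_multi, c(TRUE, FALSE))))
tests <- categorical_2x2(tab)
cat(sprintf(
  "\nMultiple-step episodes among steppers: PD %d/%d vs control %d/%d\n",
  tab[1, 1], sum(tab[1, ]), tab[2, 1], sum(tab[2, ])))
cat(sprintf("  chi-squared %.3f (p = %.4f); Yates p = %.4f; Fisher p = %.4f\n",
            tests$chisq, tests$p_chisq, tests$p_yates, tests$p_fisher))

per_type <- rt |>
  group_by(ptype, group) |>
  summarise(mean_s = mean(value), sd_s = sd(value), n = n(), .groups = "drop")
utils::write.csv(per_type, file.path(out_dir, "recovery_by_type.csv"),
                 row.names = FALSE)
cat("\nRecovery time by perturbation type written to",
    file.path(out_dir, "recovery_by_type.csv"), "\n")

# ground-truth check: detected recovery vs the generator's noise-free truth
truth <- jsonlite::read_json(file.path(in_dir, "truth.json"),
                             simplifyVector = TRUE)
errs <- c()
for (key in grep("_pert_", names(truth), value = TRUE)) {
  tt <- truth[[key]]
  if (is.null(tt$true_recovery_s)) next
  parts <- strsplit(key, "_pert_")[[1]]
  det <- rt |> filter(participant_id == parts[1], condition == parts[2])
  det <- det[match(tt$event, det$event), ]
  ok <- !is.na(det$value)
  errs <- c(errs, det$value[ok] - tt$true_recovery_s[ok])
}
cat(sprintf("\nRecovery vs ground truth over %d events: median error %+.3f s, median |error| %.3f s\n",
            length(errs), median(errs), median(abs(errs))))
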