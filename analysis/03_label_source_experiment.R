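#!/usr/bin/env Rscript
# Step 2 of the workflow: the three-arm label-source experiment.
#
# On one shared 70/30 stratified split (2020 excluded), trains a logistic
# model with the noisy EHR-view labels and another with the validated
# (agreement-subset) labels, evaluating both on the validated test subset;
# the validated model is additionally rescored against the noisy labels of
# the full test set. Comparing the first two arms isolates train-label
# noise; the last two isolate test-label noise. Expects the files written
# by 01_simulate_cohort.R.

library(gdmnoise)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20180102L
out_dir <- "results"

cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
frame <- read_label_frame(file.path(out_dir, "label_frame.csv"))

plan <- split_plan(test_fraction = 0.3, seed = seed, exclude_years = 2020)
config <- logistic_config()
ex <- run_label_source_experiment(cohort, frame, plan, config, n_boot = 2000L)

summarise_arm <- function(ev) {
  list(roc_auc = ev$roc_auc,
       roc_auc_ci = as.list(ev$roc_auc_ci),
       average_precision = ev$average_precision,
       calibration_intercept = ev$calibration_intercept,
       calibration_slope = ev$calibration_slope,
       n = ev$n, prevalence = ev$prevalence)
}
jsonlite::write_json(
  list(arms = lapply(ex[1:3], summarise_arm), meta = ex$meta,
       manifest = list(seed = seed, split_plan = unclass(plan),
                       config = unclass(config))),
  file.path(out_dir, "label_source_experiment.json"),
  auto_unbox = TRUE, digits = NA
)
for (arm in names(ex)[1:3]) {
  utils::write.csv(ex[[arm]]$roc_curve,
                   file.path(out_dir, sprintf("%s_roc.csv", arm)), row.names = FALSE)
  utils::write.csv(ex[[arm]]$pr_curve,
                   file.path(out_dir, sprintf("%s_pr.csv", arm)), row.names = FALSE)
  utils::write.csv(ex[[arm]]$calibration_bins,
                   file.path(out_dir, sprintf("%s_calibration.csv", arm)),
                   row.names = FALSE)
}

for (arm in names(ex)[1:3]) {
  ev <- ex[[arm]]
  cat(sprintf("%-20s AUC %.3f (95%% CI %.3f-%.3f)  AP %.3f  cal slope %.3f int %+.3f  n=%d\n",
              arm, ev$roc_auc, ev$roc_auc_ci[["low"]], ev$roc_auc_ci[["high"]],
              ev$average_precision, ev$calibration_slope,
              ev$calibration_intercept, ev$n))
}
cat(sprintf("training-arm AUC gap %.4f; AP drop on noisy-label test %.3f\n",
            abs(ex$ehr_train_val_test$roc_auc - ex$val_train_val_test$roc_auc),
            ex$val_train_val_test$average_precision -
              ex$val_train_ehr_test$average_precision))
cat("wrote results/label_source_experiment.json and per-arm curve CSVs\n")
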