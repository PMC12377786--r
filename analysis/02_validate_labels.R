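#!/usr/bin/env Rscript
# Step 1 of the workflow: label validation.
#
# Compares the EHR-style observed labels against the ground truth: confusion
# composition, sensitivity/specificity-style rates, accuracy, precision,
# recall, F1 and Cohen's kappa, per year and pooled (with an "All minus
# 2020" row setting aside the under-ascertainment year). Expects the files
# written by 01_simulate_cohort.R.

library(gdmnoise)

out_dir <- "results"
cohort <- read_cohort(file.path(out_dir, "cohort.csv"))
frame <- read_label_frame(file.path(out_dir, "label_frame.csv"))
stopifnot(identical(cohort$patient_id, frame$patient_id))

report <- stratified_report(cohort$year, frame$observed, frame$truth,
                            exclude_stratum = 2020)
utils::write.csv(report, file.path(out_dir, "agreement_report.csv"),
                 row.names = FALSE)
jsonlite::write_json(report, file.path(out_dir, "agreement_report.json"),
                     digits = NA, dataframe = "rows")

all_years <- report[report$stratum == "All years", ]
cat("pooled agreement (observed vs truth):\n")
cat(sprintf("  kappa %.2f  accuracy %.2f  precision %.2f  recall %.2f  F1 %.2f\n",
            all_years$kappa, all_years$accuracy, all_years$precision,
            all_years$recall, all_years$f1))
cat(sprintf("  TPR %.1f%%  FNR %.1f%%  FPR %.1f%%  TN share %.1f%%\n",
            100 * all_years$tpr, 100 * all_years$fnr, 100 * all_years$fpr,
            100 * all_years$tn / all_years$n))

p_2020 <- report$prevalence_reference[report$stratum == "2020"]
p_rest <- report$prevalence_reference[report$stratum == "All minus 2020"]
cat(sprintf("true-label prevalence: 2020 %.1f%% vs other years %.1f%% -> relative reduction %.0f%%\n",
            100 * p_2020, 100 * p_rest,
            relative_reduction(100 * p_rest, 100 * p_2020)))
cat("wrote results/agreement_report.{csv,json}\n")
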