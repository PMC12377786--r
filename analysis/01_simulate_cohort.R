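#!/usr/bin/env Rscript
# Step 0 of the workflow: synthesize the study cohort.
#
# Generates a five-year antenatal cohort (37,651 pregnancies, 2018-2022)
# with the documented feature marginals, a latent logistic risk model
# calibrated to 10.5% outcome prevalence, and the 2020 under-ascertainment
# dip; then corrupts the ground-truth labels with class-conditional noise at
# the observed EHR discordance rates (FNR 14.3%, FPR 2.3%) to produce the
# EHR-style label view. Writes the cohort, the label frame and a manifest.

library(gdmnoise)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20180101L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

spec <- cohort_spec(
  n_patients = 37651,
  seed = seed,
  year_prevalence_multipliers = year_dip_multipliers()
)
cohort <- generate_cohort(spec)
noise <- noise_spec(fn_rate = 0.143, fp_rate = 0.023, seed = seed + 1L)
corrupted <- corrupt_labels(cohort$true_label, noise)
frame <- make_label_frame(cohort$patient_id, cohort$true_label,
                          corrupted$observed)

write_cohort(cohort, file.path(out_dir, "cohort.csv"))
write_label_frame(frame, file.path(out_dir, "label_frame.csv"))
jsonlite::write_json(
  list(seed = seed, n_patients = nrow(cohort),
       prevalence_truth = mean(frame$truth),
       prevalence_observed = mean(frame$observed),
       n_flipped = sum(corrupted$flip_mask),
       noise = unclass(noise)),
  file.path(out_dir, "simulate_manifest.json"),
  auto_unbox = TRUE, digits = NA
)

cat(sprintf("cohort: %d pregnancies, %d features\n", nrow(cohort),
            ncol(cohort_features(cohort))))
cat(sprintf("ground-truth prevalence %.4f, EHR-view prevalence %.4f\n",
            mean(frame$truth), mean(frame$observed)))
cat(sprintf("%d labels flipped (%.1f%% of records)\n",
            sum(corrupted$flip_mask),
            100 * mean(corrupted$flip_mask)))
cat("wrote results/cohort.csv, results/label_frame.csv\n")
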