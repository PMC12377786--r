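#!/usr/bin/env Rscript
# Step 3 of the workflow: the noise-sweep heatmaps.
#
# Sweeps false-negative x false-positive noise levels 0%..90% in steps of
# 10% through (a) the training labels, refitting the model per cell (100
# fits), and (b) the test labels, rescoring one clean-trained model; writes
# the four metric matrices (train/test AUC and AP) as CSVs plus a manifest.
# The cohort here is regenerated at 20,000 pregnancies to keep the 100
# refits quick; the grid shapes are insensitive to cohort size at this
# scale.

library(gdmnoise)

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args) >= 1) as.integer(args[[1]]) else 20180103L
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

cohort <- generate_cohort(cohort_spec(n_patients = 20000, seed = seed))
plan <- split_plan(test_fraction = 0.3, seed = seed + 1L,
                   exclude_years = integer(0))
lv <- grid_levels()

cat("test-noise sweep (1 fit, 100 rescorings)...\n")
tg <- run_test_noise_grid(cohort, cohort$true_label, plan,
                          fn_levels = lv, fp_levels = lv,
                          base_seed = seed + 2L)
cat("train-noise sweep (100 refits)...\n")
gg <- run_train_noise_grid(cohort, cohort$true_label, plan,
                           fn_levels = lv, fp_levels = lv,
                           base_seed = seed + 2L)

write_grid_result(tg, out_dir)
write_grid_result(gg, out_dir)
jsonlite::write_json(
  list(seed = seed, n_patients = nrow(cohort), levels = lv,
       clean_auc = tg$clean_auc, clean_ap = tg$clean_ap,
       split_plan = unclass(plan)),
  file.path(out_dir, "noise_grid_manifest.json"), auto_unbox = TRUE, digits = NA
)

prev <- mean(cohort$true_label[tg$split$test])
cat(sprintf("clean model: AUC %.3f, AP %.3f, test prevalence %.3f\n",
            tg$clean_auc, tg$clean_ap, prev))
cat(sprintf("test-noise FP axis (FN=0): AUC %.3f -> %.3f; AP %.3f -> min %.3f -> %.3f\n",
            tg$auc_test[1, 1], tg$auc_test[1, length(lv)],
            tg$ap_test[1, 1], min(tg$ap_test[1, ]),
            tg$ap_test[1, length(lv)]))
cat(sprintf("  (AP rises because 90%% FP noise inflates prevalence to %.2f)\n",
            noisy_prevalence(prev, 0, 0.9)))
cat(sprintf("train-noise diagonal: AUC %.3f (clean) %.3f (40/40) %.3f (90/90)\n",
            gg$auc_test[1, 1], gg$auc_test[5, 5],
            gg$auc_test[length(lv), length(lv)]))
cat("wrote results/{train,test}_noise_*.csv and noise_grid_manifest.json\n")
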