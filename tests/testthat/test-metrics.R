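# The four confusion counts printed for the full validation cohort; used as
# a worked example throughout.
printed_counts <- function() confusion_summary(tp = 3388, fp = 771, tn = 32928, fn = 564)

test_that("confusion counts match direct enumeration", {
  cs <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(unlist(cs[c("tp", "fp", "tn", "fn")]),
                   c(tp = 1L, fp = 1L, tn = 1L, fn = 1L))
  x <- rbinom(30, 1, 0.5)
  cs_id <- confusion(x, x)
  expect_identical(cs_id$fp + cs_id$fn, 0L)
  cs_all <- confusion(rep(1, 5), rep(0, 5))
  expect_identical(cs_all$fp, 5L)
  expect_identical(cs_all$tp + cs_all$tn + cs_all$fn, 0L)
  expect_error(confusion(c(1, 0), c(1, 0, 1)), "equal lengths")
  expect_error(confusion(c(1, 2), c(1, 0)), "0/1")
})

test_that("the printed validation counts reproduce every published rate", {
  r <- confusion_rates(printed_counts())
  expect_equal(round(100 * r$tpr, 1), 85.7)
  expect_equal(round(100 * r$fnr, 1), 14.3)
  expect_equal(round(100 * r$fpr, 1), 2.3)
  expect_equal(round(100 * r$tnr, 1), 97.7)
  expect_equal(round(100 * r$composition[["tp"]], 0), 9)
  expect_equal(round(100 * r$composition[["fp"]], 0), 2)
  expect_equal(round(100 * r$composition[["fn"]], 1), 1.5)
  expect_equal(round(100 * r$composition[["tn"]], 1), 87.5)
  expect_equal(round(100 * r$prevalence_observed, 0), 11)
  expect_equal(round(100 * r$prevalence_reference, 1), 10.5)
  expect_equal(sum(r$composition), 1, tolerance = 1e-12)
})

test_that("the printed validation counts reproduce the published agreement table", {
  s <- agreement_stats(printed_counts())
  expect_equal(round(s$kappa, 2), 0.82)
  expect_equal(round(s$accuracy, 2), 0.96)
  expect_equal(round(s$precision, 2), 0.81)
  expect_equal(round(s$recall, 2), 0.86)
  expect_equal(round(s$f1, 2), 0.84)
})

test_that("degenerate confusion tables flag undefined statistics", {
  r <- confusion_rates(confusion_summary(0, 0, 10, 0))
  expect_true(is.na(r$tpr))
  expect_identical(sort(r$undefined), c("fnr", "tpr"))
  expect_equal(r$fpr, 0)
  s <- agreement_stats(confusion_summary(0, 0, 10, 0))
  expect_true(is.na(s$precision))
  expect_true("precision" %in% s$undefined)
  # all-same-cell table: kappa 1 by the p_e = p_o = 1 convention
  expect_equal(agreement_stats(confusion_summary(5, 0, 0, 0))$kappa, 1)
})

test_that("kappa behaves at its anchor points", {
  # perfect agreement
  s <- agreement_stats(confusion_summary(7, 0, 13, 0))
  expect_equal(s$kappa, 1)
  expect_equal(s$f1, 1)
  # chance-level: observed all positive at reference prevalence 0.5
  s0 <- agreement_stats(confusion_summary(50, 50, 0, 0))
  expect_equal(s0$accuracy, 0.5)
  expect_equal(s0$kappa, 0)
  # kappa never exceeds accuracy
  for (i in 1:25) {
    cnt <- withr::with_seed(i, as.list(rmultinom(1, 200, c(0.2, 0.1, 0.6, 0.1))[, 1]))
    s_i <- agreement_stats(do.call(confusion_summary, cnt))
    if (!is.na(s_i$kappa)) expect_lte(s_i$kappa, s_i$accuracy + 1e-12)
  }
})

test_that("kappa matches the brute-force contingency definition and e1071", {
  skip_if_not_installed("e1071")
  for (i in 1:20) {
    withr::with_seed(1000 + i, {
      obs <- rbinom(200, 1, runif(1, 0.1, 0.9))
      ref <- ifelse(runif(200) < 0.7, obs, rbinom(200, 1, 0.5))
    })
    if (length(unique(obs)) < 2 || length(unique(ref)) < 2) next
    k_pkg <- agreement_stats(confusion(obs, ref))$kappa
    expect_equal(k_pkg, kappa_brute(obs, ref), tolerance = 1e-12)
    k_ind <- e1071::classAgreement(table(obs, ref))$kappa
    expect_equal(k_pkg, k_ind, tolerance = 1e-9)
  }
})

test_that("corruption rates are recovered exactly by the validation metrics", {
  truth <- c(rep(1L, 400), rep(0L, 3600))
  ns <- noise_spec(fn_rate = 0.143, fp_rate = 0.023, seed = 17)
  cor <- corrupt_labels(truth, ns)
  r <- confusion_rates(confusion(cor$observed, truth))
  expect_identical(r$fnr, round(0.143 * 400) / 400)
  expect_identical(r$fpr, round(0.023 * 3600) / 3600)
})

test_that("stratified reports pool additively across years", {
  coh <- generate_cohort(small_spec(n = 6000, seed = 19))
  cor <- corrupt_labels(coh$true_label, noise_spec(0.143, 0.023, seed = 20))
  rep_df <- stratified_report(coh$year, cor$observed, coh$true_label,
                              exclude_stratum = 2020)
  pooled <- rep_df[rep_df$stratum == "All years", ]
  yearly <- rep_df[grepl("^20", rep_df$stratum), ]
  for (col in c("tp", "fp", "tn", "fn", "n")) {
    expect_identical(sum(yearly[[col]]), pooled[[col]])
  }
  minus <- rep_df[rep_df$stratum == "All minus 2020", ]
  y2020 <- rep_df[rep_df$stratum == "2020", ]
  expect_identical(minus$n + y2020$n, pooled$n)
  # single-year input: pooled row equals the single year row
  idx <- coh$year == 2019
  rep1 <- stratified_report(coh$year[idx], cor$observed[idx], coh$true_label[idx])
  expect_equal(rep1[rep1$stratum == "All years", -1],
               rep1[rep1$stratum == "2019", -1], ignore_attr = TRUE)
})

test_that("the 2020 ascertainment preset shows up in the stratified report", {
  coh <- generate_cohort(cohort_spec(n_patients = 40000, seed = 23,
                                     year_prevalence_multipliers = year_dip_multipliers()))
  cor <- corrupt_labels(coh$true_label, noise_spec(0.143, 0.023, seed = 24))
  rep_df <- stratified_report(coh$year, cor$observed, coh$true_label,
                              exclude_stratum = 2020)
  p2020 <- rep_df$prevalence_reference[rep_df$stratum == "2020"]
  p_rest <- rep_df$prevalence_reference[rep_df$stratum == "All minus 2020"]
  expect_lt(p2020, p_rest)
  n2020 <- rep_df$n[rep_df$stratum == "2020"]
  expect_lt(p2020, p_rest - 3 * sqrt(p_rest * (1 - p_rest) / n2020) + 0.01)
})

test_that("relative reduction reproduces the printed 31% dip and edge cases", {
  expect_equal(round(relative_reduction(11.2, 7.7)), 31)
  expect_equal(relative_reduction(8.4, 8.4), 0)
  expect_equal(relative_reduction(10, 0), 100)
  expect_error(relative_reduction(0, 5), "positive")
})
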