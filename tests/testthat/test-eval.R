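test_that("ROC AUC matches hand-worked and anchor examples", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3), c(1, 0, 1)), 0.5)
  expect_equal(roc_auc(c(5, 4, 3, 2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), c(1, rep(0, 9))), 0.5)  # all ties
  expect_warning(a <- roc_auc(1:4, rep(1, 4)), "one class")
  expect_true(is.na(a))
})

test_that("ROC AUC and AP match brute-force oracles on random short inputs", {
  for (i in 1:300) {
    withr::with_seed(5000 + i, {
      n <- sample(2:12, 1)
      scores <- round(runif(n), sample(c(1, 2, 8), 1))  # induce ties sometimes
      labels <- rbinom(n, 1, 0.5)
    })
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels), auc_brute(scores, labels),
                 tolerance = 1e-12, label = paste("auc case", i))
    expect_equal(average_precision(scores, labels), ap_brute(scores, labels),
                 tolerance = 1e-12, label = paste("ap case", i))
  }
})

test_that("ROC AUC agrees with pROC on a larger sample", {
  skip_if_not_installed("pROC")
  withr::with_seed(61, {
    y <- rbinom(500, 1, 0.3)
    s <- rnorm(500) + y
  })
  expect_equal(roc_auc(s, y),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("ROC AUC is invariant to monotone transforms and flips under negation", {
  withr::with_seed(63, {
    y <- rbinom(200, 1, 0.4)
    s <- rnorm(200) + 0.8 * y
  })
  a <- roc_auc(s, y)
  expect_equal(roc_auc(qlogis(plogis(s)), y), a, tolerance = 1e-9)
  expect_equal(roc_auc(exp(s), y), a, tolerance = 1e-12)
  expect_equal(roc_auc(-s, y), 1 - a, tolerance = 1e-12)
})

test_that("average precision hits its closed-form anchors", {
  expect_equal(average_precision(c(0.9, 0.8, 0.3), c(1, 0, 1)),
               0.5 * 1 + 0.5 * (2 / 3))
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 1, 0, 0)), 1)
  y <- c(rep(1, 3), rep(0, 7))
  expect_equal(average_precision(rep(0.2, 10), y), 0.3)  # constant scores -> prevalence
  expect_warning(ap <- average_precision(1:3, rep(0, 3)), "no positive")
  expect_true(is.na(ap))
})

test_that("bootstrap AUC interval is seeded, ordered and covers the point", {
  withr::with_seed(65, {
    y <- rbinom(400, 1, 0.25)
    s <- rnorm(400) + 1.2 * y
  })
  ci1 <- auc_ci(s, y, n_boot = 500, seed = 9)
  ci2 <- auc_ci(s, y, n_boot = 500, seed = 9)
  expect_identical(ci1, ci2)
  expect_lt(ci1$low, ci1$high)
  expect_gte(ci1$point, ci1$low - 1e-9)
  expect_lte(ci1$point, ci1$high + 1e-9)
  expect_error(auc_ci(s, y, n_boot = 50), "at least 100")
})

test_that("bootstrap interval width shrinks roughly as 1/sqrt(n)", {
  width_at <- function(n, seed) {
    withr::with_seed(seed, {
      y <- rbinom(n, 1, 0.3)
      s <- rnorm(n) + y
    })
    ci <- auc_ci(s, y, n_boot = 400, seed = 1)
    ci$high - ci$low
  }
  w1 <- width_at(300, 71)
  w4 <- width_at(4 * 300, 71)
  expect_lt(w4, w1 * 0.75)  # should be ~0.5, allow simulation slack
})

test_that("ROC and PR curves are monotone and consistent with their scalars", {
  withr::with_seed(67, {
    y <- rbinom(300, 1, 0.2)
    s <- round(rnorm(300) + y, 2)
  })
  rc <- roc_curve(s, y)
  expect_true(all(diff(rc$fpr) >= 0))
  expect_true(all(diff(rc$tpr) >= 0))
  expect_equal(utils::tail(rc$fpr, 1), 1)
  expect_equal(utils::tail(rc$tpr, 1), 1)
  pc <- pr_curve(s, y)
  expect_true(all(diff(pc$recall) >= 0))
  expect_equal(utils::tail(pc$recall, 1), 1)
  # trapezoid under the ROC curve equals the Mann-Whitney AUC
  trap <- sum(diff(rc$fpr) * (utils::head(rc$tpr, -1) + utils::tail(rc$tpr, -1)) / 2)
  expect_equal(trap, roc_auc(s, y), tolerance = 1e-12)
})

test_that("reliability bins partition the sample and track true rates", {
  withr::with_seed(69, {
    p <- runif(20000, 0.01, 0.6)
    y <- rbinom(20000, 1, p)
  })
  bins <- calibration_curve(p, y, n_bins = 10)
  expect_identical(sum(bins$count), 20000L)
  for (k in seq_len(nrow(bins))) {
    se <- sqrt(bins$mean_predicted[k] * (1 - bins$mean_predicted[k]) / bins$count[k])
    expect_lt(abs(bins$observed_rate[k] - bins$mean_predicted[k]), 4 * se + 0.01)
  }
  one <- calibration_curve(rep(0.3, 50), rbinom(50, 1, 0.3), n_bins = 5)
  expect_identical(nrow(one), 1L)
  expect_error(calibration_curve(runif(5), rbinom(5, 1, 0.5), n_bins = 10),
               "exceeds")
})

test_that("logistic recalibration recovers slope 1 / intercept 0 when correct,
           slope 0.5 when overconfident, intercept -1 under an offset", {
  withr::with_seed(73, {
    n <- 50000
    lp <- rnorm(n, -2.2, 1.1)
    y <- rbinom(n, 1, plogis(lp))
  })
  cal <- calibration_intercept_slope(plogis(lp), y)
  expect_lt(abs(cal$slope - 1), 0.05)
  expect_lt(abs(cal$intercept), 0.05)
  cal2 <- calibration_intercept_slope(plogis(2 * lp), y)
  expect_lt(abs(cal2$slope - 0.5), 0.05)
  cal3 <- calibration_intercept_slope(plogis(lp + 1), y)
  expect_lt(abs(cal3$intercept - (-1)), 0.05)
  expect_lt(abs(cal3$slope - 1), 0.05)
  cal4 <- calibration_intercept_slope(rep(0.3, 100),
                                      withr::with_seed(1, rbinom(100, 1, 0.3)))
  expect_true(is.na(cal4$slope))
  expect_identical(cal4$undefined, "slope")
})

test_that("evaluation bundles are deterministic and internally consistent", {
  coh <- generate_cohort(small_spec(n = 2500, seed = 75))
  ev1 <- evaluate_predictions(coh$true_risk, coh$true_label, n_boot = 200, seed = 3)
  ev2 <- evaluate_predictions(coh$true_risk, coh$true_label, n_boot = 200, seed = 3)
  expect_equal(ev1, ev2)
  expect_equal(ev1$roc_auc, roc_auc(coh$true_risk, coh$true_label))
  expect_equal(ev1$prevalence, mean(coh$true_label))
  expect_identical(sum(ev1$calibration_bins$count), nrow(coh))
})

test_that("with zero label noise the three experiment arms coincide", {
  coh <- generate_cohort(small_spec(n = 3000, seed = 77))
  fr <- make_label_frame(coh$patient_id, coh$true_label, coh$true_label)
  ex <- run_label_source_experiment(coh, fr, split_plan(seed = 5, exclude_years = integer(0)))
  expect_equal(ex$ehr_train_val_test$roc_auc, ex$val_train_val_test$roc_auc)
  expect_equal(ex$val_train_val_test$roc_auc, ex$val_train_ehr_test$roc_auc)
  expect_equal(ex$ehr_train_val_test$average_precision,
               ex$val_train_ehr_test$average_precision)
})

test_that("the validated arms use only agreement rows", {
  coh <- generate_cohort(small_spec(n = 3000, seed = 79))
  cor <- corrupt_labels(coh$true_label, noise_spec(0.2, 0.05, seed = 80))
  fr <- make_label_frame(coh$patient_id, coh$true_label, cor$observed)
  ex <- run_label_source_experiment(coh, fr, split_plan(seed = 6, exclude_years = integer(0)))
  expect_identical(ex$val_train_val_test$n, ex$meta$n_test_agree)
  expect_identical(ex$val_train_ehr_test$n, ex$meta$n_test)
  expect_lt(ex$meta$n_train_agree, ex$meta$n_train)
})
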