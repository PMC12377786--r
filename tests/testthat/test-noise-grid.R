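test_that("noisy prevalence follows the mixture arithmetic", {
  expect_equal(noisy_prevalence(0.1, 0, 0.9), 0.91)  # 90% negative -> 91% positive
  expect_equal(noisy_prevalence(0.3, 0, 0), 0.3)
  expect_equal(noisy_prevalence(0.3, 1, 1), 0.7)
})

test_that("the mixture AUC oracle honours its identities", {
  expect_equal(expected_noisy_auc(0.82, 0.105, 0, 0), 0.82)
  expect_equal(expected_noisy_auc(0.82, 0.105, 1, 1), 1 - 0.82)
  for (fn in c(0, 0.3, 0.7)) {
    for (fp in c(0, 0.3, 0.7)) {
      expect_equal(expected_noisy_auc(0.5, 0.2, fn, fp), 0.5)
    }
  }
  expect_warning(v <- expected_noisy_auc(0.8, 0.105, 1, 0), "empty")
  expect_true(is.na(v))
})

test_that("the mixture AUC oracle matches large-sample simulation", {
  cases <- expand.grid(fn = c(0.1, 0.5), fp = c(0.1, 0.5))
  for (k in seq_len(nrow(cases))) {
    sim <- simulate_noisy_auc(100000, 0.105, 0.82, cases$fn[k], cases$fp[k],
                              seed = 300 + k)
    expected <- expected_noisy_auc(0.82, 0.105, cases$fn[k], cases$fp[k])
    se <- sqrt(1 / (12 * sim$n_pos) + 1 / (12 * sim$n_neg))  # conservative MW SE
    expect_lt(abs(sim$auc - expected), max(3 * se, 0.01),
              label = sprintf("fn=%.1f fp=%.1f", cases$fn[k], cases$fp[k]))
  }
})

test_that("test-noise sweep: clean cell exact, AUC falls along FP, AP floor holds", {
  coh <- generate_cohort(small_spec(n = 8000, seed = 81))
  lv <- c(0, 0.3, 0.6, 0.9)
  grid <- run_test_noise_grid(coh, coh$true_label,
                              split_plan(seed = 7, exclude_years = integer(0)),
                              fn_levels = lv, fp_levels = lv, base_seed = 9)
  expect_identical(dim(grid$auc_test), c(4L, 4L))
  expect_equal(grid$auc_test[1, 1], grid$clean_auc)
  expect_equal(grid$ap_test[1, 1], grid$clean_ap)
  # AUC decreases along the FP axis at zero FN; the expected decline between
  # adjacent high-FP cells is smaller than Monte-Carlo noise at this sample
  # size, so adjacent steps may only rise within that noise
  expect_true(all(diff(grid$auc_test[1, ]) < 0.02))
  expect_lt(grid$auc_test[1, length(lv)], grid$auc_test[1, 1] - 0.15)
  # and each noisy cell agrees with the analytic mixture oracle
  prev_test <- mean(y_test <- coh$true_label[grid$split$test])
  for (j in 2:length(lv)) {
    expect_lt(abs(grid$auc_test[1, j] -
                    expected_noisy_auc(grid$clean_auc, prev_test, 0, lv[j])),
              0.03)
  }
  # a random ranker scored against any corrupted cell's labels has
  # AP equal to that cell's noisy prevalence
  test_idx <- grid$split$test
  y_test <- coh$true_label[test_idx]
  withr::with_seed(10, rand_scores <- runif(length(test_idx)))
  for (j in seq_along(lv)) {
    cor <- corrupt_labels(y_test, noise_spec(0, lv[j], seed = grid$seeds[1, j]))
    if (length(unique(cor$observed)) < 2) next
    ap_rand <- average_precision(rand_scores, cor$observed)
    expect_lt(abs(ap_rand - mean(cor$observed)), 0.05)
  }
})

test_that("grid runs are reproducible and their flip counts are conserved", {
  coh <- generate_cohort(small_spec(n = 3000, seed = 83))
  lv <- c(0, 0.5)
  g1 <- run_test_noise_grid(coh, coh$true_label,
                            split_plan(seed = 2, exclude_years = integer(0)),
                            fn_levels = lv, fp_levels = lv, base_seed = 4)
  g2 <- run_test_noise_grid(coh, coh$true_label,
                            split_plan(seed = 2, exclude_years = integer(0)),
                            fn_levels = lv, fp_levels = lv, base_seed = 4)
  expect_equal(g1$auc_test, g2$auc_test)
  expect_equal(g1$flips, g2$flips)
  y <- coh$true_label[g1$split$test]
  P <- sum(y == 1); N <- sum(y == 0)
  expect_equal(g1$flips[2, 2], floor(0.5 * P + 0.5) + floor(0.5 * N + 0.5))
  expect_equal(g1$flips[1, 1], 0)
})

test_that("train-noise sweep: clean cell matches a direct clean fit and noise hurts", {
  coh <- generate_cohort(small_spec(n = 6000, seed = 85))
  plan <- split_plan(seed = 3, exclude_years = integer(0))
  lv <- c(0, 0.4)
  grid <- run_train_noise_grid(coh, coh$true_label, plan,
                               fn_levels = lv, fp_levels = lv, base_seed = 6)
  # (0,0) cell must equal the clean pipeline exactly (same split, no flips)
  clean <- run_test_noise_grid(coh, coh$true_label, plan,
                               fn_levels = 0, fp_levels = 0, base_seed = 6)
  expect_equal(grid$auc_test[1, 1], clean$clean_auc, tolerance = 1e-12)
  # symmetric 40/40 noise degrades clean-test discrimination
  expect_lt(grid$auc_test[2, 2], grid$auc_test[1, 1])
  expect_true(all(is.finite(grid$auc_train)))
})

test_that("grid CSV export lays FP levels across columns", {
  coh <- generate_cohort(small_spec(n = 2000, seed = 87))
  lv <- c(0, 0.5)
  grid <- run_test_noise_grid(coh, coh$true_label,
                              split_plan(seed = 2, exclude_years = integer(0)),
                              fn_levels = lv, fp_levels = lv, base_seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_grid_result(grid, dir)
  expect_true(all(file.exists(paths)))
  df <- utils::read.csv(paths[grepl("auc_test", paths)], check.names = FALSE)
  expect_identical(names(df), c("fn_level", "fp_0", "fp_0.5"))
  expect_equal(df$fn_level, lv)
  expect_equal(df[1, "fp_0"], grid$auc_test[1, 1])
})
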