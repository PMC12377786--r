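#' Prevalence of a label vector after noise-at-random corruption
#'
#' With prevalence `pi` and flip rates `(fn_rate, fp_rate)`, the corrupted
#' positive share is `pi (1 - fn_rate) + (1 - pi) fp_rate`; at
#' `fp_rate = 0.9` a 10%-positive sample becomes 91% positive, which is what
#' inflates average precision at high FP noise (a random ranker's AP equals
#' the prevalence of whatever labels it is scored against).
#'
#' @param prevalence Clean positive fraction in `[0, 1]`.
#' @param fn_rate,fp_rate Flip rates in `[0, 1]`.
#' @return Corrupted positive fraction.
#' @export
noisy_prevalence <- function(prevalence, fn_rate, fp_rate) {
  check_fraction(prevalence, "prevalence")
  check_fraction(fn_rate, "fn_rate")
  check_fraction(fp_rate, "fp_rate")
  prevalence * (1 - fn_rate) + (1 - prevalence) * fp_rate
}

#' Analytic AUC of a fixed scorer under test-label noise
#'
#' Closed-form mixture oracle: after class-conditional corruption the noisy
#' positive class is a mixture of true positives (weight
#' `pi (1 - fn_rate)`) and flipped negatives (`(1 - pi) fp_rate`), and
#' symmetrically for the noisy negative class. Writing
#' `a = P(truly positive | noisy positive)` and
#' `b = P(truly positive | noisy negative)`, the AUC against the noisy
#' labels is
#' `a b / 2 + a (1 - b) auc + (1 - a) b (1 - auc) + (1 - a)(1 - b) / 2`:
#' same-class pairs are coin flips, cross-class pairs inherit the clean AUC
#' or its complement. Identities: rates (0, 0) return `clean_auc`;
#' rates (1, 1) return `1 - clean_auc`; a clean AUC of 0.5 is invariant.
#'
#' @param clean_auc AUC of the scorer against the clean labels.
#' @param prevalence Clean positive fraction.
#' @param fn_rate,fp_rate Flip rates in `[0, 1]`.
#' @return Expected AUC against the corrupted labels; `NA` with a warning
#'   when a corrupted class is empty.
#' @export
expected_noisy_auc <- function(clean_auc, prevalence, fn_rate, fp_rate) {
  check_fraction(clean_auc, "clean_auc")
  check_fraction(prevalence, "prevalence")
  check_fraction(fn_rate, "fn_rate")
  check_fraction(fp_rate, "fp_rate")
  w_pp <- prevalence * (1 - fn_rate)       # true positive, still positive
  w_np <- (1 - prevalence) * fp_rate       # true negative, flipped positive
  w_pn <- prevalence * fn_rate             # true positive, flipped negative
  w_nn <- (1 - prevalence) * (1 - fp_rate) # true negative, still negative
  if (w_pp + w_np == 0 || w_pn + w_nn == 0) {
    warning("expected_noisy_auc undefined: a corrupted class is empty")
    return(NA_real_)
  }
  a <- w_pp / (w_pp + w_np)
  b <- w_pn / (w_pn + w_nn)
  a * b * 0.5 + a * (1 - b) * clean_auc + (1 - a) * b * (1 - clean_auc) +
    (1 - a) * (1 - b) * 0.5
}

empty_grid <- function(fn_levels, fp_levels) {
  matrix(NA_real_, nrow = length(fn_levels), ncol = length(fp_levels),
         dimnames = list(fn = sprintf("%g", fn_levels),
                         fp = sprintf("%g", fp_levels)))
}

#' Train-set label-noise sweep
#'
#' For every cell `(fn_level, fp_level)` of the grid, the clean training
#' labels are corrupted with that cell's noise-at-random spec (its own
#' deterministic RNG stream derived from `base_seed` and the cell indices),
#' preprocessing and the logistic model are refit, and the model is scored
#' both on its own noisy training labels and on the untouched clean test
#' set. The default 10-level grid on each axis trains 100 models. Cells
#' whose corrupted training labels collapse to a single class are flagged
#' undefined (`NA`) and the sweep continues.
#'
#' @param cohort A cohort data frame.
#' @param clean_labels Binary clean (validated) labels aligned to cohort rows.
#' @param plan A [split_plan()].
#' @param fn_levels,fp_levels Noise levels per axis, e.g. [grid_levels()].
#' @param config A [logistic_config()].
#' @param base_seed Base seed for the per-cell noise streams.
#' @return Object of class `grid_result`: list with the axes, matrices
#'   `auc_train`, `ap_train`, `auc_test`, `ap_test` (rows = FN levels,
#'   columns = FP levels), `flips` (realized flip counts), `seeds`, `split`,
#'   and `arm = "train_noise"`.
#' @export
run_train_noise_grid <- function(cohort, clean_labels, plan = split_plan(),
                                 fn_levels = grid_levels(),
                                 fp_levels = grid_levels(),
                                 config = logistic_config(),
                                 base_seed = 1L) {
  clean_labels <- check_binary(clean_labels, "clean_labels")
  features <- cohort_features(cohort)
  split <- split_cohort(cohort, reference = clean_labels, plan = plan)
  train <- split$train; test <- split$test
  y_train <- clean_labels[train]
  y_test <- clean_labels[test]
  auc_train <- ap_train <- auc_test <- ap_test <- flips <- seeds <-
    empty_grid(fn_levels, fp_levels)
  for (i in seq_along(fn_levels)) {
    for (j in seq_along(fp_levels)) {
      sd_ij <- cell_seed(base_seed, i, j)
      seeds[i, j] <- sd_ij
      cor <- corrupt_labels(y_train, noise_spec(fn_levels[i], fp_levels[j],
                                                seed = sd_ij))
      flips[i, j] <- sum(cor$flip_mask)
      if (length(unique(cor$observed)) < 2L) next  # undefined cell
      res <- fit_and_eval(features, train, cor$observed, test, y_test,
                          config, n_boot = 0L, seed = sd_ij)
      plan_pp <- res$preprocessor
      x_train <- transform_features(plan_pp, features[train, , drop = FALSE])
      p_train <- predict_proba(res$model, x_train)
      auc_train[i, j] <- roc_auc(p_train, cor$observed)
      ap_train[i, j] <- average_precision(p_train, cor$observed)
      auc_test[i, j] <- res$eval$roc_auc
      ap_test[i, j] <- res$eval$average_precision
    }
  }
  structure(list(arm = "train_noise", fn_levels = fn_levels,
                 fp_levels = fp_levels, auc_train = auc_train,
                 ap_train = ap_train, auc_test = auc_test, ap_test = ap_test,
                 flips = flips, seeds = seeds, split = split,
                 base_seed = base_seed),
            class = "grid_result")
}

#' Test-set label-noise sweep
#'
#' One model is fit on the clean training labels; its fixed test-set
#' predictions are then rescored, cell by cell, against corrupted copies of
#' the test labels. The model and predictions never change — only the
#' labels they are judged against do, which is what makes the average
#' precision rise again at high FP noise while the AUC falls.
#'
#' @inheritParams run_train_noise_grid
#' @return Object of class `grid_result` with matrices `auc_test`,
#'   `ap_test`, plus `clean_auc`, `clean_ap`, `flips`, `seeds`, `split`,
#'   and `arm = "test_noise"`.
#' @export
run_test_noise_grid <- function(cohort, clean_labels, plan = split_plan(),
                                fn_levels = grid_levels(),
                                fp_levels = grid_levels(),
                                config = logistic_config(),
                                base_seed = 1L) {
  clean_labels <- check_binary(clean_labels, "clean_labels")
  features <- cohort_features(cohort)
  split <- split_cohort(cohort, reference = clean_labels, plan = plan)
  train <- split$train; test <- split$test
  res <- fit_and_eval(features, train, clean_labels[train], test,
                      clean_labels[test], config, n_boot = 0L,
                      seed = base_seed)
  probs <- res$probs
  y_test <- clean_labels[test]
  auc_test <- ap_test <- flips <- seeds <- empty_grid(fn_levels, fp_levels)
  for (i in seq_along(fn_levels)) {
    for (j in seq_along(fp_levels)) {
      sd_ij <- cell_seed(base_seed, i, j)
      seeds[i, j] <- sd_ij
      cor <- corrupt_labels(y_test, noise_spec(fn_levels[i], fp_levels[j],
                                               seed = sd_ij))
      flips[i, j] <- sum(cor$flip_mask)
      if (length(unique(cor$observed)) < 2L) next
      auc_test[i, j] <- roc_auc(probs, cor$observed)
      ap_test[i, j] <- average_precision(probs, cor$observed)
    }
  }
  structure(list(arm = "test_noise", fn_levels = fn_levels,
                 fp_levels = fp_levels, auc_test = auc_test, ap_test = ap_test,
                 clean_auc = res$eval$roc_auc,
                 clean_ap = res$eval$average_precision,
                 model = res$model, flips = flips, seeds = seeds,
                 split = split, base_seed = base_seed),
            class = "grid_result")
}

#' Write grid-result metric matrices as CSV
#'
#' One CSV per metric matrix: header row = FP levels, first column = FN
#' levels, matching the heatmap orientation (FP on the x-axis, FN on the
#' y-axis).
#'
#' @param grid A `grid_result`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, defaults to the arm name.
#' @return Invisibly, the paths written.
#' @export
write_grid_result <- function(grid, dir, prefix = grid$arm) {
  stopifnot(inherits(grid, "grid_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mats <- grid[intersect(c("auc_train", "ap_train", "auc_test", "ap_test"),
                         names(grid))]
  paths <- character(0)
  for (nm in names(mats)) {
    df <- data.frame(fn_level = grid$fn_levels, mats[[nm]],
                     check.names = FALSE)
    names(df) <- c("fn_level", sprintf("fp_%g", grid$fp_levels))
    p <- file.path(dir, sprintf("%s_%s.csv", prefix, nm))
    utils::write.csv(df, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
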