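#' ROC AUC by the Mann-Whitney statistic
#'
#' Probability that a uniformly chosen positive outranks a uniformly chosen
#' negative, ties credited 0.5; computed from midranks, which is exactly the
#' pairwise definition. With a single class present the statistic is
#' undefined and `NA` is returned with a warning.
#'
#' @param scores Numeric scores (any monotone transform gives the same AUC).
#' @param labels Binary 0/1 labels.
#' @return AUC in `[0, 1]`, or `NA` if a class is absent.
#' @export
roc_auc <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal lengths", call. = FALSE)
  }
  n_pos <- as.numeric(sum(labels == 1L))  # doubles: count products overflow int
  n_neg <- as.numeric(sum(labels == 0L))
  if (n_pos == 0 || n_neg == 0) {
    warning("ROC AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Bootstrap confidence interval for the ROC AUC
#'
#' Label-stratified percentile bootstrap: positives and negatives are
#' resampled with replacement separately (so every resample retains both
#' classes), the AUC is recomputed, and the 2.5/97.5 percentiles are
#' returned. Deterministic given `seed`.
#'
#' @param scores,labels As in [roc_auc()].
#' @param n_boot Number of bootstrap resamples (at least 100).
#' @param seed Integer RNG seed.
#' @param level Confidence level.
#' @return List with `low`, `high`, `point`, `n_boot`.
#' @export
auc_ci <- function(scores, labels, n_boot = 2000L, seed = 1L, level = 0.95) {
  labels <- check_binary(labels, "labels")
  if (n_boot < 100L) stop("`n_boot` must be at least 100", call. = FALSE)
  pos <- which(labels == 1L)
  neg <- which(labels == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present for a bootstrap interval", call. = FALSE)
  }
  point <- roc_auc(scores, labels)
  stats_boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ip <- pos[sample.int(length(pos), replace = TRUE)]
      im <- neg[sample.int(length(neg), replace = TRUE)]
      idx <- c(ip, im)
      roc_auc(scores[idx], labels[idx])
    }, numeric(1))
  })
  alpha <- (1 - level) / 2
  qs <- stats::quantile(stats_boot, c(alpha, 1 - alpha), names = FALSE)
  list(low = qs[1], high = qs[2], point = point, n_boot = as.integer(n_boot))
}

#' Average precision of a ranking
#'
#' Step-wise summary of the precision-recall curve without interpolation:
#' over descending unique score thresholds (ties grouped at one threshold),
#' `AP = sum_k (R_k - R_{k-1}) P_k`. Equals the prevalence for constant
#' scores; `NA` with a warning when no positives are present.
#'
#' @param scores Numeric scores.
#' @param labels Binary 0/1 labels.
#' @return AP in `[0, 1]`, or `NA` if there are no positives.
#' @export
average_precision <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  if (length(scores) != length(labels)) {
    stop("`scores` and `labels` must have equal lengths", call. = FALSE)
  }
  n_pos <- sum(labels == 1L)
  if (n_pos == 0L) {
    warning("average precision undefined: no positive labels")
    return(NA_real_)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  cum_tp <- cumsum(y)
  k <- seq_along(y)
  block_end <- k[c(s[-1] != s[-length(s)], TRUE)]  # last index of each tie group
  precision <- cum_tp[block_end] / block_end
  recall <- cum_tp[block_end] / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' ROC curve points
#'
#' One point per descending unique threshold plus the (0, 0) origin;
#' `fpr` and `tpr` are non-decreasing along the curve.
#'
#' @param scores,labels As in [roc_auc()].
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1L); n_neg <- sum(y == 0L)
  k <- seq_along(y)
  block_end <- k[c(s[-1] != s[-length(s)], TRUE)]
  data.frame(
    threshold = c(Inf, s[block_end]),
    fpr = c(0, cumsum(y == 0L)[block_end] / max(1L, n_neg)),
    tpr = c(0, cumsum(y)[block_end] / max(1L, n_pos))
  )
}

#' Precision-recall curve points
#'
#' @param scores,labels As in [average_precision()].
#' @return Data frame with `threshold`, `recall`, `precision`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- check_binary(labels, "labels")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  n_pos <- sum(y == 1L)
  k <- seq_along(y)
  block_end <- k[c(s[-1] != s[-length(s)], TRUE)]
  data.frame(
    threshold = s[block_end],
    recall = cumsum(y)[block_end] / max(1L, n_pos),
    precision = cumsum(y)[block_end] / block_end
  )
}

#' Reliability diagram bins
#'
#' Equal-frequency bins by predicted probability (quantile breaks; ties fall
#' in the lower bin); empty bins are omitted, so constant predictions give a
#' single bin.
#'
#' @param probs Predicted probabilities in `[0, 1]`.
#' @param labels Binary 0/1 outcomes.
#' @param n_bins Number of bins (at most `length(probs)`).
#' @return Data frame with `bin`, `mean_predicted`, `observed_rate`, `count`.
#' @export
calibration_curve <- function(probs, labels, n_bins = 10L) {
  labels <- check_binary(labels, "labels")
  if (any(probs < 0 | probs > 1)) stop("`probs` must lie in [0, 1]", call. = FALSE)
  if (n_bins > length(probs)) {
    stop("`n_bins` exceeds the number of observations", call. = FALSE)
  }
  breaks <- unique(stats::quantile(probs, seq(0, 1, length.out = n_bins + 1),
                                   names = FALSE))
  if (length(breaks) == 1L) {
    return(data.frame(bin = 1L, mean_predicted = mean(probs),
                      observed_rate = mean(labels), count = length(probs)))
  }
  bin <- cut(probs, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  agg <- lapply(sort(unique(bin)), function(b) {
    idx <- bin == b
    data.frame(bin = b, mean_predicted = mean(probs[idx]),
               observed_rate = mean(labels[idx]), count = sum(idx))
  })
  do.call(rbind, agg)
}

#' Logistic recalibration: calibration intercept and slope
#'
#' The clinical-prediction-model reporting convention: the slope is the
#' coefficient of an unpenalised logistic regression of outcomes on the
#' logit of the predicted risk, and the intercept is calibration-in-the-
#' large — the intercept of a logistic regression with the logit entered as
#' a fixed offset (slope held at 1). Perfect calibration gives (0, 1).
#' Probabilities are clipped to `[1e-6, 1 - 1e-6]` before the logit.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 outcomes.
#' @return List with `intercept`, `slope`, `undefined` (character; `"slope"`
#'   when all predictions are identical).
#' @export
calibration_intercept_slope <- function(probs, labels) {
  labels <- check_binary(labels, "labels")
  if (length(unique(labels)) < 2L) {
    stop("both outcome classes must be present", call. = FALSE)
  }
  lp <- stats::qlogis(pmin(pmax(probs, 1e-6), 1 - 1e-6))
  intercept <- unname(stats::coef(stats::glm(labels ~ 1 + offset(lp),
                                             family = stats::binomial()))[1])
  if (stats::sd(lp) == 0) {
    return(list(intercept = intercept, slope = NA_real_, undefined = "slope"))
  }
  slope_fit <- stats::glm(labels ~ lp, family = stats::binomial())
  list(intercept = intercept,
       slope = unname(stats::coef(slope_fit)[2]),
       undefined = character(0))
}

#' Evaluate predicted probabilities against labels
#'
#' Assembles the full evaluation bundle: ROC AUC with a stratified
#' percentile-bootstrap interval, average precision, ROC and PR curves,
#' reliability bins, and the calibration intercept/slope.
#'
#' @param probs Predicted probabilities.
#' @param labels Binary 0/1 labels.
#' @param n_boot Bootstrap resamples for the AUC interval; `0` skips it.
#' @param seed RNG seed for the bootstrap.
#' @param n_bins Reliability-diagram bins.
#' @return An object of class `model_eval` (list).
#' @export
evaluate_predictions <- function(probs, labels, n_boot = 2000L, seed = 1L,
                                 n_bins = 10L) {
  labels <- check_binary(labels, "labels")
  auc <- roc_auc(probs, labels)
  ci <- if (n_boot > 0L) auc_ci(probs, labels, n_boot = n_boot, seed = seed) else NULL
  cal <- calibration_intercept_slope(probs, labels)
  structure(list(
    roc_auc = auc,
    roc_auc_ci = if (is.null(ci)) NULL else c(low = ci$low, high = ci$high),
    average_precision = average_precision(probs, labels),
    calibration_intercept = cal$intercept,
    calibration_slope = cal$slope,
    roc_curve = roc_curve(probs, labels),
    pr_curve = pr_curve(probs, labels),
    calibration_bins = calibration_curve(probs, labels, n_bins = n_bins),
    n = length(labels),
    prevalence = mean(labels)
  ), class = "model_eval")
}

#' Train under one label view and evaluate under another
#'
#' Core plumbing of the label-source experiment: fits the preprocessor and a
#' logistic model on the requested training rows/labels, then evaluates the
#' predicted risks on the requested test rows/labels.
#'
#' @keywords internal
fit_and_eval <- function(features, train_idx, train_labels,
                         test_idx, test_labels, config = logistic_config(),
                         n_boot = 0L, seed = 1L) {
  plan <- fit_preprocessor(features[train_idx, , drop = FALSE])
  x_train <- transform_features(plan, features[train_idx, , drop = FALSE])
  x_test <- transform_features(plan, features[test_idx, , drop = FALSE])
  model <- train_logistic(x_train, train_labels, config)
  probs <- predict_proba(model, x_test)
  ev <- evaluate_predictions(probs, test_labels, n_boot = n_boot, seed = seed)
  list(model = model, preprocessor = plan, eval = ev, probs = probs)
}

#' Three-arm label-source experiment
#'
#' The headline comparison of label accuracy's impact on modeling. On one
#' shared stratified split (ground-truth reference, 2020 excluded), three
#' train/test arms are run:
#' \describe{
#'   \item{ehr_train_val_test}{trained on all training rows with the noisy
#'     observed (EHR) labels, evaluated on the agreement (validated) subset
#'     of the test rows;}
#'   \item{val_train_val_test}{trained on the agreement subset of the
#'     training rows with validated labels, evaluated on the same validated
#'     test subset;}
#'   \item{val_train_ehr_test}{the validated-label model evaluated on all
#'     test rows scored against the noisy observed labels.}
#' }
#' Comparing the first two isolates train-label noise; comparing the last
#' two isolates test-label noise.
#'
#' @param cohort A cohort data frame.
#' @param frame A [make_label_frame()] aligned to the cohort rows.
#' @param plan A [split_plan()].
#' @param config A [logistic_config()].
#' @param n_boot Bootstrap resamples for AUC intervals (0 to skip).
#' @return List of three `model_eval`-bearing arms plus `split` and metadata.
#' @export
run_label_source_experiment <- function(cohort, frame, plan = split_plan(),
                                        config = logistic_config(),
                                        n_boot = 0L) {
  stopifnot(nrow(cohort) == nrow(frame))
  features <- cohort_features(cohort)
  split <- split_cohort(cohort, reference = frame$truth, plan = plan)
  train <- split$train
  test <- split$test
  train_agree <- train[frame$agreement[train]]
  test_agree <- test[frame$agreement[test]]
  if (length(train_agree) == 0L || length(test_agree) == 0L) {
    stop("agreement subset is empty in train or test", call. = FALSE)
  }
  seed_eval <- plan$seed + 1L
  ehr_arm <- fit_and_eval(features, train, frame$observed[train],
                          test_agree, frame$val[test_agree],
                          config, n_boot, seed_eval)
  val_arm <- fit_and_eval(features, train_agree, frame$val[train_agree],
                          test_agree, frame$val[test_agree],
                          config, n_boot, seed_eval)
  # third arm reuses the validated-label model, rescored on all test rows
  # against the observed labels
  x_test_all <- transform_features(val_arm$preprocessor,
                                   features[test, , drop = FALSE])
  probs_all <- predict_proba(val_arm$model, x_test_all)
  ehr_test_eval <- evaluate_predictions(probs_all, frame$observed[test],
                                        n_boot = n_boot, seed = seed_eval)
  list(
    ehr_train_val_test = ehr_arm$eval,
    val_train_val_test = val_arm$eval,
    val_train_ehr_test = ehr_test_eval,
    split = split,
    meta = list(n_train = length(train), n_train_agree = length(train_agree),
                n_test = length(test), n_test_agree = length(test_agree),
                config = unclass(config), split_plan = unclass(plan))
  )
}
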