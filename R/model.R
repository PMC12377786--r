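#' Train/test split plan
#'
#' Defaults mirror the study design: 70/30 split, stratified on the
#' reference label (at ~10% prevalence an unstratified 30% split is noisy),
#' and the under-ascertainment year 2020 excluded from modeling.
#'
#' @param test_fraction Fraction of included records assigned to the test
#'   set, in (0, 1).
#' @param seed Integer RNG seed for the split draw.
#' @param stratify_on_reference Stratify the draw on the reference label?
#' @param exclude_years Calendar years dropped before splitting.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(test_fraction = 0.3, seed = 1L,
                       stratify_on_reference = TRUE, exclude_years = 2020) {
  check_fraction(test_fraction, "test_fraction", open = TRUE)
  structure(list(test_fraction = test_fraction, seed = as.integer(seed),
                 stratify_on_reference = isTRUE(stratify_on_reference),
                 exclude_years = exclude_years),
            class = "split_plan")
}

#' Split a cohort into train and test index sets
#'
#' Indices are row positions into `cohort`. Excluded years appear in
#' neither set; the test set has `round(test_fraction * n_included)` rows.
#' Under stratification the positive-class quota is
#' `round(test_fraction * n_positive)`, keeping the reference prevalence of
#' each side within one count of the cohort's.
#'
#' @param cohort A cohort data frame (needs `year`).
#' @param reference Binary reference labels aligned to `cohort` rows used
#'   for stratification; defaults to `cohort$true_label`.
#' @param plan A [split_plan()].
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(cohort, reference = cohort$true_label, plan = split_plan()) {
  stopifnot(inherits(plan, "split_plan"))
  reference <- check_binary(reference, "reference")
  if (length(reference) != nrow(cohort)) {
    stop("`reference` must align with `cohort` rows", call. = FALSE)
  }
  included <- which(!(cohort$year %in% plan$exclude_years))
  n <- length(included)
  if (n < 2L) stop("fewer than 2 records remain after year exclusion", call. = FALSE)
  n_test <- as.integer(round_half_up(plan$test_fraction * n))
  n_test <- max(1L, min(n - 1L, n_test))
  withr::with_seed(plan$seed, {
    if (plan$stratify_on_reference) {
      pos <- included[reference[included] == 1L]
      neg <- included[reference[included] == 0L]
      if (length(pos) < 2L || length(neg) < 2L) {
        stop("a reference class has fewer than 2 members; use a non-stratified split",
             call. = FALSE)
      }
      n_test_pos <- as.integer(round_half_up(plan$test_fraction * length(pos)))
      n_test_pos <- max(1L, min(length(pos) - 1L, n_test_pos))
      n_test_neg <- max(1L, min(length(neg) - 1L, n_test - n_test_pos))
      test <- c(pos[sample.int(length(pos), n_test_pos)],
                neg[sample.int(length(neg), n_test_neg)])
    } else {
      test <- included[sample.int(n, n_test)]
    }
    test <- sort(test)
    list(train = setdiff(included, test), test = test)
  })
}

#' Pinned logistic-regression configuration
#'
#' "Default hyperparameters" are library-version-dependent, so the ridge
#' penalty, convergence threshold and iteration cap are pinned explicitly
#' and recorded in the fitted model's metadata. The default penalty
#' `lambda = 1/n` reproduces the conventional unit-strength L2
#' regularisation of common logistic-regression defaults (penalised
#' coefficients, unpenalised intercept) on the glmnet objective scale.
#'
#' @param lambda Ridge penalty on glmnet's per-observation scale, or `NULL`
#'   for `1/n`.
#' @param thresh Coordinate-descent convergence threshold.
#' @param maxit Maximum iterations.
#' @return An object of class `logistic_config`.
#' @export
logistic_config <- function(lambda = NULL, thresh = 1e-9, maxit = 100000L) {
  structure(list(lambda = lambda, thresh = thresh, maxit = as.integer(maxit)),
            class = "logistic_config")
}

#' Fit ridge-penalised logistic regression
#'
#' Thin deterministic wrapper around [glmnet::glmnet()] (binomial family,
#' `alpha = 0`, no internal standardisation — the design is already
#' z-scored by the preprocessor). The penalty keeps coefficients finite
#' under separation.
#'
#' @param design Numeric design matrix with column names.
#' @param labels Binary 0/1 outcome vector.
#' @param config A [logistic_config()].
#' @return Object of class `gdm_logit`: list with `coefficients` (named),
#'   `intercept`, `config`, and `meta` (lambda used, convergence info).
#' @export
train_logistic <- function(design, labels, config = logistic_config()) {
  labels <- check_binary(labels, "labels")
  design <- as.matrix(design)
  if (nrow(design) != length(labels)) {
    stop("`design` rows must match `labels` length", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("labels contain a single class; cannot fit a classifier", call. = FALSE)
  }
  lambda <- if (is.null(config$lambda)) 1 / nrow(design) else config$lambda
  x <- design
  padded <- FALSE
  if (ncol(x) < 2L) {  # glmnet needs >= 2 predictors; pad with an inert zero column
    x <- cbind(x, `.pad` = 0)
    padded <- TRUE
  }
  # glmnet is unreliable when handed a single small lambda; fit down a short
  # decreasing path (warm starts) and read off the final, target lambda.
  lambda_path <- exp(seq(log(max(lambda * 1e3, 1e-2)), log(lambda),
                         length.out = 20L))
  fit <- glmnet::glmnet(x, labels, family = "binomial", alpha = 0,
                        lambda = lambda_path, standardize = FALSE,
                        thresh = config$thresh, maxit = config$maxit)
  k <- length(fit$lambda)
  beta <- as.numeric(fit$beta[, k])
  names(beta) <- rownames(fit$beta)
  if (padded) beta <- beta[setdiff(names(beta), ".pad")]
  structure(list(coefficients = beta,
                 intercept = as.numeric(fit$a0[k]),
                 config = config,
                 meta = list(lambda = lambda, n = nrow(design),
                             npasses = fit$npasses,
                             converged = fit$npasses < config$maxit)),
            class = "gdm_logit")
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param model A `gdm_logit`.
#' @param design Numeric matrix whose columns match the model's
#'   coefficients (by name when named).
#' @return Vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, design) {
  stopifnot(inherits(model, "gdm_logit"))
  design <- as.matrix(design)
  if (ncol(design) != length(model$coefficients)) {
    stop(sprintf("design has %d columns but the model expects %d",
                 ncol(design), length(model$coefficients)), call. = FALSE)
  }
  if (!is.null(colnames(design)) && !is.null(names(model$coefficients))) {
    if (!identical(colnames(design), names(model$coefficients))) {
      if (!setequal(colnames(design), names(model$coefficients))) {
        stop("design column names do not match model coefficients", call. = FALSE)
      }
      design <- design[, names(model$coefficients), drop = FALSE]
    }
  }
  as.numeric(stats::plogis(model$intercept + design %*% model$coefficients))
}

#' Serialise / restore a fitted logistic model as JSON
#'
#' Full-precision round trip: predictions from a restored model match the
#' original to better than 1e-12.
#'
#' @param model A `gdm_logit`.
#' @param path File path.
#' @return `read_model()` returns a `gdm_logit`; `write_model()` returns
#'   `path` invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "gdm_logit"))
  payload <- list(
    coefficient_names = names(model$coefficients),
    coefficient_values = unname(model$coefficients),
    intercept = model$intercept,
    config = unclass(model$config),
    meta = model$meta
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- logistic_config(lambda = payload$config$lambda,
                         thresh = payload$config$thresh,
                         maxit = payload$config$maxit)
  structure(list(coefficients = stats::setNames(as.numeric(payload$coefficient_values),
                                                payload$coefficient_names),
                 intercept = as.numeric(payload$intercept),
                 config = cfg,
                 meta = payload$meta),
            class = "gdm_logit")
}
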