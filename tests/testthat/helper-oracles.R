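# Independent brute-force oracles. These deliberately use the naive
# definitional computation (pairwise loops, threshold enumeration, raw 2x2
# algebra) so they share no code path with the package implementations.

# ROC AUC as the mean over all positive-negative pairs (ties = 0.5).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Average precision by explicit enumeration of descending unique thresholds.
ap_brute <- function(scores, labels) {
  if (sum(labels == 1) == 0) return(NA_real_)
  thresholds <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(labels == 1)
  ap <- 0
  r_prev <- 0
  for (t in thresholds) {
    sel <- scores >= t
    precision <- sum(labels[sel] == 1) / sum(sel)
    recall <- sum(labels[sel] == 1) / n_pos
    ap <- ap + (recall - r_prev) * precision
    r_prev <- recall
  }
  ap
}

# Cohen's kappa straight from the 2x2 contingency definition.
kappa_brute <- function(observed, reference) {
  n <- length(observed)
  p_o <- mean(observed == reference)
  p_yes <- mean(observed == 1) * mean(reference == 1)
  p_no <- mean(observed == 0) * mean(reference == 0)
  p_e <- p_yes + p_no
  (p_o - p_e) / (1 - p_e)
}

# Monte-Carlo oracle for AUC under test-label noise: simulate scores from a
# binormal model with the requested clean AUC, corrupt the labels, measure.
simulate_noisy_auc <- function(n, prevalence, clean_auc, fn_rate, fp_rate, seed) {
  withr::with_seed(seed, {
    y <- rbinom(n, 1, prevalence)
    mu <- sqrt(2) * qnorm(clean_auc)  # binormal separation giving clean_auc
    s <- rnorm(n) + mu * y
    flip_pos <- y == 1 & runif(n) < fn_rate
    flip_neg <- y == 0 & runif(n) < fp_rate
    y_noisy <- y
    y_noisy[flip_pos] <- 0
    y_noisy[flip_neg] <- 1
    if (length(unique(y_noisy)) < 2) return(NULL)
    list(auc = gdmnoise::roc_auc(s, y_noisy),
         n_pos = sum(y_noisy == 1), n_neg = sum(y_noisy == 0))
  })
}

# Small fixed cohort spec used across tests: cheap but wide enough to
# exercise every feature type.
small_spec <- function(n = 4000, seed = 42, ...) {
  cohort_spec(n_patients = n, seed = seed, ...)
}
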