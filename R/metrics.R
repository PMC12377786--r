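#' Confusion counts of an observed label source against a reference
#'
#' Conventions follow EHR phenotype validation: a record is a TP when the
#' observed (EHR) label and the reference (registry) label are both
#' positive, an FP when observed-positive only, an FN when
#' reference-positive only, a TN when both negative.
#'
#' @param observed,reference Equal-length binary 0/1 vectors.
#' @return An object of class `confusion_summary`: list with integer counts
#'   `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(observed, reference) {
  observed <- check_binary(observed, "observed")
  reference <- check_binary(reference, "reference")
  if (length(observed) != length(reference)) {
    stop("`observed` and `reference` must have equal lengths", call. = FALSE)
  }
  confusion_summary(
    tp = sum(observed == 1L & reference == 1L),
    fp = sum(observed == 1L & reference == 0L),
    tn = sum(observed == 0L & reference == 0L),
    fn = sum(observed == 0L & reference == 1L)
  )
}

#' Construct a confusion summary from counts
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return An object of class `confusion_summary`.
#' @export
confusion_summary <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(stats::setNames(as.list(as.integer(counts)), names(counts)),
            class = "confusion_summary")
}

# A statistic with an undefined denominator is reported as NA_real_ and its
# name is listed in the `undefined` element of the returned object; it is
# never a silent NaN.
rate_or_undefined <- function(num, den) {
  if (den > 0) num / den else NA_real_
}

#' Agreement rates and composition of a confusion summary
#'
#' Sensitivity/miss/false-alarm/specificity of the observed source against
#' the reference (`tpr`, `fnr`, `fpr`, `tnr`), the composition shares of the
#' four cells, and the prevalence under each label source. Rates with an
#' empty denominator are `NA` and listed in `undefined`.
#'
#' @param cs A `confusion_summary`.
#' @return List with `tpr`, `fpr`, `tnr`, `fnr`, `composition` (named shares
#'   summing to 1), `prevalence_observed`, `prevalence_reference`, `n`, and
#'   `undefined` (character vector of rate names that could not be computed).
#' @export
confusion_rates <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"))
  n <- cs$tp + cs$fp + cs$tn + cs$fn
  if (n < 1L) stop("confusion summary is empty", call. = FALSE)
  out <- list(
    tpr = rate_or_undefined(cs$tp, cs$tp + cs$fn),
    fnr = rate_or_undefined(cs$fn, cs$tp + cs$fn),
    fpr = rate_or_undefined(cs$fp, cs$fp + cs$tn),
    tnr = rate_or_undefined(cs$tn, cs$fp + cs$tn),
    composition = c(tp = cs$tp / n, fp = cs$fp / n, tn = cs$tn / n, fn = cs$fn / n),
    prevalence_observed = (cs$tp + cs$fp) / n,
    prevalence_reference = (cs$tp + cs$fn) / n,
    n = n
  )
  out$undefined <- names(which(vapply(out[c("tpr", "fnr", "fpr", "tnr")],
                                      is.na, logical(1))))
  out
}

#' Accuracy, precision, recall, F1 and Cohen's kappa
#'
#' Chance-corrected agreement uses the standard two-rater kappa
#' `(p_o - p_e) / (1 - p_e)` with observed agreement `p_o = (tp + tn)/n` and
#' expected agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / n^2`. When both raters are
#' constant and identical (`p_e = 1`, `p_o = 1`) kappa is 1 by convention.
#' Undefined components (empty denominators) are `NA` and listed in
#' `undefined`.
#'
#' @param cs A `confusion_summary`.
#' @return List with `accuracy`, `precision`, `recall`, `f1`, `kappa`, `n`,
#'   `undefined`.
#' @export
agreement_stats <- function(cs) {
  stopifnot(inherits(cs, "confusion_summary"))
  n <- cs$tp + cs$fp + cs$tn + cs$fn
  if (n < 1L) stop("confusion summary is empty", call. = FALSE)
  accuracy <- (cs$tp + cs$tn) / n
  precision <- rate_or_undefined(cs$tp, cs$tp + cs$fp)
  recall <- rate_or_undefined(cs$tp, cs$tp + cs$fn)
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  p_e <- (as.numeric(cs$tp + cs$fp) * (cs$tp + cs$fn) +
            as.numeric(cs$fn + cs$tn) * (cs$fp + cs$tn)) / as.numeric(n)^2
  kappa <- if (p_e < 1) (accuracy - p_e) / (1 - p_e) else if (accuracy == 1) 1 else NA_real_
  out <- list(accuracy = accuracy, precision = precision, recall = recall,
              f1 = f1, kappa = kappa, n = n)
  out$undefined <- names(which(vapply(out[c("precision", "recall", "f1", "kappa")],
                                      is.na, logical(1))))
  out
}

agreement_row <- function(stratum, cs) {
  r <- confusion_rates(cs)
  s <- agreement_stats(cs)
  data.frame(
    stratum = stratum, n = r$n,
    tp = cs$tp, fp = cs$fp, tn = cs$tn, fn = cs$fn,
    tpr = r$tpr, fpr = r$fpr, tnr = r$tnr, fnr = r$fnr,
    prevalence_observed = r$prevalence_observed,
    prevalence_reference = r$prevalence_reference,
    accuracy = s$accuracy, precision = s$precision, recall = s$recall,
    f1 = s$f1, kappa = s$kappa,
    stringsAsFactors = FALSE
  )
}

#' Per-year and pooled agreement report
#'
#' One row per calendar year plus an `"All years"` pooled row and,
#' optionally, a pooled row excluding one stratum (e.g. `"All minus 2020"`
#' to set aside the under-ascertainment year). Years with zero records are
#' omitted with a message. Count columns are full precision; rounding to a
#' table's printed precision is left to the presentation layer.
#'
#' @param years Year per record.
#' @param observed,reference Aligned binary 0/1 label vectors.
#' @param exclude_stratum Optional year to additionally pool without.
#' @return Data frame of class `agreement_report`, one row per stratum.
#' @export
stratified_report <- function(years, observed, reference, exclude_stratum = NULL) {
  observed <- check_binary(observed, "observed")
  reference <- check_binary(reference, "reference")
  if (length(years) != length(observed) || length(observed) != length(reference)) {
    stop("`years`, `observed` and `reference` must have equal lengths",
         call. = FALSE)
  }
  rows <- list(agreement_row("All years", confusion(observed, reference)))
  for (y in sort(unique(years))) {
    idx <- years == y
    if (!any(idx)) {
      message("stratum ", y, " has no records; omitted")
      next
    }
    rows[[length(rows) + 1L]] <-
      agreement_row(as.character(y), confusion(observed[idx], reference[idx]))
  }
  if (!is.null(exclude_stratum)) {
    keep <- !(years %in% exclude_stratum)
    if (any(keep)) {
      rows[[length(rows) + 1L]] <-
        agreement_row(paste("All minus", paste(exclude_stratum, collapse = ", ")),
                      confusion(observed[keep], reference[keep]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("agreement_report", "data.frame")
  out
}

#' Relative reduction between two prevalences
#'
#' `100 * (1 - p_dip / p_baseline)`, the percentage drop of a dipped
#' prevalence relative to a baseline (both in the same units, e.g. percent).
#'
#' @param p_baseline Baseline prevalence, must be positive.
#' @param p_dip Prevalence in the dip period.
#' @return Relative reduction in percent.
#' @export
relative_reduction <- function(p_baseline, p_dip) {
  if (!is.numeric(p_baseline) || p_baseline <= 0) {
    stop("`p_baseline` must be positive", call. = FALSE)
  }
  100 * (1 - p_dip / p_baseline)
}
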