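#' Class-conditional noise-at-random specification
#'
#' Flip rates of the noise-at-random (NAR) label corruption: `fn_rate` is the
#' fraction of TRUE positives whose label is flipped to negative (creating
#' false negatives), `fp_rate` the fraction of TRUE negatives flipped to
#' positive (creating false positives). Class membership is taken from the
#' original labels, so the two flip sets are disjoint.
#'
#' @param fn_rate,fp_rate Flip fractions in `[0, 1]`.
#' @param seed Integer RNG seed for the flip draw.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(fn_rate = 0.143, fp_rate = 0.023, seed = 1L) {
  check_fraction(fn_rate, "fn_rate")
  check_fraction(fp_rate, "fp_rate")
  structure(list(fn_rate = fn_rate, fp_rate = fp_rate, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Corrupt binary labels with class-conditional noise at random
#'
#' Flips exactly `round(fn_rate * P)` of the `P` original positives to 0 and
#' `round(fp_rate * N)` of the `N` original negatives to 1 (round half away
#' from zero), each set drawn uniformly without replacement from its
#' original class. Because eligibility is fixed by the original labels, the
#' realized false-negative and false-positive rates of the corrupted labels
#' against the truth equal the requested rates up to the rounding of counts,
#' exactly.
#'
#' @param truth Binary 0/1 vector of true labels.
#' @param noise A [noise_spec()].
#' @return List with `observed` (corrupted 0/1 vector) and `flip_mask`
#'   (logical vector marking flipped positions).
#' @export
corrupt_labels <- function(truth, noise) {
  truth <- check_binary(truth, "truth")
  if (!inherits(noise, "noise_spec")) {
    stop("`noise` must be created by noise_spec()", call. = FALSE)
  }
  pos <- which(truth == 1L)
  neg <- which(truth == 0L)
  n_fn <- as.integer(round_half_up(noise$fn_rate * length(pos)))
  n_fp <- as.integer(round_half_up(noise$fp_rate * length(neg)))
  withr::with_seed(noise$seed, {
    flip <- logical(length(truth))
    if (n_fn > 0L) flip[pos[sample.int(length(pos), n_fn)]] <- TRUE
    if (n_fp > 0L) flip[neg[sample.int(length(neg), n_fp)]] <- TRUE
    observed <- truth
    observed[flip] <- 1L - observed[flip]
    list(observed = observed, flip_mask = flip)
  })
}

#' Assemble aligned truth / observed / validated label views
#'
#' The three label constructions of the validation design: `truth` (the
#' registry / ground-truth view), `observed` (the EHR view), the
#' `agreement` mask marking records where the two coincide, and `val` — the
#' validated label, defined (and equal to both views) only on agreement
#' records, `NA` elsewhere.
#'
#' @param ids Patient identifiers, one per record.
#' @param truth,observed Binary 0/1 vectors aligned to `ids`.
#' @return A data frame of class `label_frame` with columns `patient_id`,
#'   `truth`, `observed`, `agreement`, `val`.
#' @export
make_label_frame <- function(ids, truth, observed) {
  truth <- check_binary(truth, "truth")
  observed <- check_binary(observed, "observed")
  if (length(ids) != length(truth) || length(truth) != length(observed)) {
    stop("`ids`, `truth` and `observed` must have equal lengths", call. = FALSE)
  }
  agreement <- truth == observed
  val <- ifelse(agreement, truth, NA_integer_)
  structure(
    data.frame(patient_id = as.character(ids), truth = truth,
               observed = observed, agreement = agreement,
               val = as.integer(val), stringsAsFactors = FALSE),
    class = c("label_frame", "data.frame")
  )
}

#' Noise levels for a corruption sweep
#'
#' Arithmetic grid `{0, step, 2 step, ..., max_level}`; the defaults give the
#' ten levels 0%, 10%, ..., 90%, so a full FN-by-FP sweep has 100 cells.
#'
#' @param max_level Largest level, in `[0, 1]`.
#' @param step Grid step, in `(0, max_level]` (0 allowed when `max_level` is 0).
#' @return Numeric vector of levels.
#' @export
grid_levels <- function(max_level = 0.9, step = 0.1) {
  check_fraction(max_level, "max_level")
  check_fraction(step, "step")
  if (max_level == 0) return(0)
  if (step <= 0) stop("`step` must be positive when `max_level` > 0", call. = FALSE)
  if (step > max_level) stop("`step` must not exceed `max_level`", call. = FALSE)
  seq(0, max_level + 1e-12, by = step)
}

#' Write / read a label frame as CSV
#'
#' Columns `patient_id`, `truth`, `observed`, `agreement`, `val`; `val` is
#' blank where undefined (disagreement records).
#'
#' @param frame A `label_frame`.
#' @param path File path.
#' @return `read_label_frame()` returns a `label_frame`;
#'   `write_label_frame()` returns `path` invisibly.
#' @export
write_label_frame <- function(frame, path) {
  utils::write.csv(as.data.frame(frame), path, row.names = FALSE,
                   quote = TRUE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' @rdname write_label_frame
#' @export
read_label_frame <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                        na.strings = "")
  req <- c("patient_id", "truth", "observed")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0L) {
    stop("label frame file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  make_label_frame(df$patient_id, df$truth, df$observed)
}
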