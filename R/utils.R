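#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

# Round half away from zero. base::round() rounds half to even, which would
# make flip counts depend on the parity of the class size.
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Validate a 0/1 vector; `what` names the argument in error messages.
check_binary <- function(x, what = "labels") {
  if (length(x) == 0L) {
    stop(sprintf("`%s` must be non-empty", what), call. = FALSE)
  }
  if (anyNA(x) || !all(x %in% c(0, 1))) {
    stop(sprintf("`%s` must contain only 0/1 values with no missing entries", what),
         call. = FALSE)
  }
  as.integer(x)
}

check_fraction <- function(x, what, open = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("`%s` must be a single number", what), call. = FALSE)
  }
  ok <- if (open) x > 0 && x < 1 else x >= 0 && x <= 1
  if (!ok) {
    stop(sprintf("`%s` must lie in %s", what, if (open) "(0, 1)" else "[0, 1]"),
         call. = FALSE)
  }
  x
}

# Deterministic per-cell RNG stream for grid experiments: any single cell is
# reproducible in isolation from (base_seed, fn_index, fp_index). Stays below
# 2^31 for up to 32 levels per axis.
cell_seed <- function(base_seed, fn_index, fp_index) {
  stopifnot(fn_index >= 1L, fp_index >= 1L, fn_index <= 32L, fp_index <= 32L)
  (as.integer(base_seed) %% 1048576L) * 2048L +
    (as.integer(fn_index) - 1L) * 32L + (as.integer(fp_index) - 1L)
}
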