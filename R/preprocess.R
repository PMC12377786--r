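#' Fit the design-matrix preprocessor on training features
#'
#' Categorical (character/factor/logical) columns are one-hot encoded with
#' the first category dropped, "first" meaning the lexicographically
#' smallest level seen in training; numeric columns are z-scored with
#' training means and SDs. The returned plan carries all fitted state, so
#' [transform_features()] uses training statistics only: a test category
#' unseen in training encodes as all zeros for that feature's block, and a
#' numeric column with zero training SD transforms to 0.
#'
#' @param features Data frame of training features; missing values are an
#'   error (incomplete records are excluded upstream).
#' @return An object of class `preprocess_plan`.
#' @export
fit_preprocessor <- function(features) {
  if (!is.data.frame(features) || nrow(features) == 0L) {
    stop("`features` must be a non-empty data frame", call. = FALSE)
  }
  if (anyNA(features)) {
    stop("`features` contains missing values; exclude incomplete records first",
         call. = FALSE)
  }
  numeric_cols <- names(features)[vapply(features, is.numeric, logical(1))]
  cat_cols <- setdiff(names(features), numeric_cols)
  num_state <- lapply(features[numeric_cols], function(x) {
    list(mean = mean(x), sd = stats::sd(x))
  })
  cat_state <- lapply(features[cat_cols], function(x) {
    sort(unique(as.character(x)))  # first (dropped) level = lexicographic min
  })
  structure(list(columns = names(features), numeric = num_state,
                 categorical = cat_state),
            class = "preprocess_plan")
}

#' Transform features to a numeric design matrix
#'
#' @param plan A fitted `preprocess_plan`.
#' @param features Data frame with the same columns the plan was fitted on.
#' @return Numeric matrix; width is one column per numeric feature plus
#'   `n_levels - 1` per categorical feature.
#' @export
transform_features <- function(plan, features) {
  stopifnot(inherits(plan, "preprocess_plan"))
  missing_cols <- setdiff(plan$columns, names(features))
  if (length(missing_cols) > 0L) {
    stop("features are missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(features[plan$columns])) {
    stop("`features` contains missing values", call. = FALSE)
  }
  n <- nrow(features)
  blocks <- list()
  for (col in plan$columns) {
    if (col %in% names(plan$numeric)) {
      st <- plan$numeric[[col]]
      z <- if (is.na(st$sd) || st$sd == 0) rep(0, n) else (features[[col]] - st$mean) / st$sd
      blocks[[col]] <- matrix(z, ncol = 1, dimnames = list(NULL, col))
    } else {
      lev <- plan$categorical[[col]]
      keep <- lev[-1]  # drop first
      x <- as.character(features[[col]])
      m <- matrix(0, nrow = n, ncol = length(keep),
                  dimnames = list(NULL, paste0(col, "=", keep)))
      for (j in seq_along(keep)) m[, j] <- as.numeric(x == keep[j])
      blocks[[col]] <- m  # unseen categories: all-zero row block
    }
  }
  do.call(cbind, blocks)
}
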