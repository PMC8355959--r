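#' Random train/test partition
#'
#' Uniformly random partition without replacement; the training set size is
#' `round(train_fraction * n)`. For the study design of n = 172 at 75% this
#' yields 129 training and 43 test rows.
#'
#' @param n number of rows to partition (>= 4).
#' @param train_fraction proportion of rows assigned to training, in (0, 1).
#' @param seed integer seed; the partition is fully determined by it.
#' @return a `teac_split`: list with integer vectors `train`, `test` and the
#'   `seed`.
#' @export
make_split <- function(n, train_fraction = 0.75, seed = 42L) {
  stop_if_not_count(n, "n", min = 4L)
  if (!is.numeric(train_fraction) || length(train_fraction) != 1L ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1")
  }
  n_train <- as.integer(round(train_fraction * n))
  train <- with_seed(seed, sort(sample.int(n, n_train)))
  structure(
    list(train = train,
         test = setdiff(seq_len(n), train),
         seed = as.integer(seed)),
    class = "teac_split"
  )
}

#' Fit min-max normalization parameters
#'
#' Records per-column minimum and maximum for all feature columns and the
#' target, over either the full dataset (`scope = "full"`, the default,
#' matching a pipeline that normalizes before splitting) or the training
#' rows only (`scope = "train"`, the leakage-free option).
#'
#' @param dataset a `teac_dataset`.
#' @param scope `"full"` or `"train"`.
#' @param split a `teac_split`; required when `scope = "train"`.
#' @return a `teac_norm_params`: per-column `min` and `max` (named vectors,
#'   target column named `TEAC`) plus the `scope`.
#' @export
fit_normalizer <- function(dataset, scope = c("full", "train"), split = NULL) {
  stopifnot(inherits(dataset, "teac_dataset"))
  scope <- match.arg(scope)
  rows <- if (scope == "train") {
    if (is.null(split)) stop("scope = \"train\" requires a split")
    split$train
  } else {
    seq_along(dataset$target)
  }
  M <- cbind(dataset$features, TEAC = dataset$target)[rows, , drop = FALSE]
  mins <- apply(M, 2L, min)
  maxs <- apply(M, 2L, max)
  const <- which(maxs <= mins)
  if (length(const)) {
    stop("constant column over the ", scope, " scope: ",
         paste(colnames(M)[const], collapse = ", "))
  }
  structure(list(min = mins, max = maxs, scope = scope),
            class = "teac_norm_params")
}

scale_minmax <- function(x, lo, hi) 2 * (x - lo) / (hi - lo) - 1
unscale_minmax <- function(x, lo, hi) (x + 1) / 2 * (hi - lo) + lo

#' Apply / invert min-max normalization
#'
#' Maps every column to `2 * (x - min) / (max - min) - 1`. Columns attain
#' exactly -1 and +1 at the rows holding the fitted extrema; values outside
#' the fitted range map outside `[-1, 1]` by design. `denormalize_dataset()`
#' inverts the map exactly (up to floating-point round-off).
#'
#' @param dataset a `teac_dataset`.
#' @param params a `teac_norm_params` from [fit_normalizer()].
#' @return a `teac_dataset` on the transformed scale.
#' @export
normalize_dataset <- function(dataset, params) {
  stopifnot(inherits(dataset, "teac_dataset"),
            inherits(params, "teac_norm_params"))
  cols <- c(dataset$feature_names, "TEAC")
  if (!all(cols %in% names(params$min))) {
    stop("normalization params do not cover all columns")
  }
  f <- dataset$features
  for (nm in dataset$feature_names) {
    f[, nm] <- scale_minmax(f[, nm], params$min[[nm]], params$max[[nm]])
  }
  new_teac_dataset(
    f, scale_minmax(dataset$target, params$min[["TEAC"]], params$max[["TEAC"]])
  )
}

#' @rdname normalize_dataset
#' @export
denormalize_dataset <- function(dataset, params) {
  stopifnot(inherits(dataset, "teac_dataset"),
            inherits(params, "teac_norm_params"))
  f <- dataset$features
  for (nm in dataset$feature_names) {
    f[, nm] <- unscale_minmax(f[, nm], params$min[[nm]], params$max[[nm]])
  }
  new_teac_dataset(
    f, unscale_minmax(dataset$target, params$min[["TEAC"]], params$max[["TEAC"]])
  )
}

#' Map predictions from the normalized scale back to TEAC units
#' @param y numeric vector on the normalized target scale.
#' @param params a `teac_norm_params`.
#' @export
denormalize_target <- function(y, params) {
  stopifnot(inherits(params, "teac_norm_params"))
  unscale_minmax(y, params$min[["TEAC"]], params$max[["TEAC"]])
}
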