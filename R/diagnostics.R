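#' Five-statistic goodness-of-fit summary for one phase
#'
#' All statistics are computed on the physical TEAC scale:
#' \itemize{
#'   \item `r2` — coefficient of determination `1 - SSres/SStot` (not the
#'     squared Pearson correlation; the two differ for biased predictors);
#'   \item `mre_percent` — mean relative error, `100/n * sum(|y - yhat| / |y|)`;
#'   \item `mse`, `rmse` — mean squared error and its square root;
#'   \item `std` — sample standard deviation of the absolute errors
#'     `|y - yhat|` (consistently smaller than the RMSE via the identity
#'     `sd(|e|)^2 ~ rmse^2 - mae^2`).
#' }
#'
#' @param actual,predicted equal-length numeric vectors.
#' @param phase label: `"train"`, `"test"` or `"total"`.
#' @return a `fit_metrics` object (list with the five statistics, `phase`,
#'   `n`).
#' @export
fit_metrics <- function(actual, predicted, phase = c("total", "train", "test")) {
  phase <- match.arg(phase)
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  n <- length(actual)
  if (n == 0L || length(predicted) != n) {
    stop("actual and predicted must be non-empty vectors of equal length")
  }
  if (any(actual == 0)) {
    stop("MRE is undefined: some actual values are exactly 0")
  }
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("R2 is undefined: actual values are constant")
  err <- actual - predicted
  mse <- mean(err^2)
  structure(
    list(
      r2 = 1 - sum(err^2) / sst,
      mre_percent = 100 * mean(abs(err) / abs(actual)),
      mse = mse,
      rmse = sqrt(mse),
      std = stats::sd(abs(err)),
      phase = phase,
      n = n
    ),
    class = "fit_metrics"
  )
}

#' @export
print.fit_metrics <- function(x, ...) {
  cat(sprintf("%-6s n=%-4d R2=%.3f  MRE%%=%.2f  MSE=%.2f  RMSE=%.2f  STD=%.2f\n",
              x$phase, x$n, x$r2, x$mre_percent, x$mse, x$rmse, x$std))
  invisible(x)
}

#' Per-sample absolute relative deviation (percent)
#'
#' `100 * |y - yhat| / |y|` per sample, order-preserving; its mean equals the
#' `mre_percent` of [fit_metrics()].
#' @inheritParams fit_metrics
#' @export
relative_deviation <- function(actual, predicted) {
  if (any(actual == 0)) {
    stop("relative deviation is undefined: some actual values are exactly 0")
  }
  100 * abs(actual - predicted) / abs(actual)
}

#' Williams-plot applicability-domain analysis
#'
#' Leverage (hat values) of every sample with respect to the training design
#' (normalized features plus an intercept column), paired with standardized
#' residuals (residual divided by the phase RMSE). Samples are flagged
#' `high_leverage` when their hat value exceeds the warning leverage
#' `h* = 3 (p + 1) / n_train` (p = feature count), `residual_outlier` when
#' the standardized residual exceeds 3 in magnitude, `both` when both hold,
#' and `in_domain` otherwise.
#'
#' @param features_norm_train training-partition normalized feature matrix.
#' @param features_norm_all normalized feature matrix of every sample to
#'   diagnose (may equal the training matrix).
#' @param residuals per-sample residuals `y - yhat` aligned with
#'   `features_norm_all`, physical scale.
#' @param rmse the phase RMSE used to standardize the residuals.
#' @return an `ad_result`: `leverages`, `std_residuals`, `warning_leverage`,
#'   `flags` (factor) and the design rank `p_plus_1`.
#' @export
williams_ad <- function(features_norm_train, features_norm_all, residuals, rmse) {
  Xtr <- cbind(1, as.matrix(features_norm_train))
  Xall <- cbind(1, as.matrix(features_norm_all))
  if (nrow(Xall) != length(residuals)) {
    stop("residuals must align with the rows of features_norm_all")
  }
  G <- crossprod(Xtr)
  R <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(R) || kappa(G) > 1e12) {
    stop("training design is rank deficient; inspect the feature columns for collinearity or constants")
  }
  # leverage h_i = x_i (X'X)^{-1} x_i' via the Cholesky factor
  B <- backsolve(R, t(Xall), transpose = TRUE)
  lev <- colSums(B^2)
  h_star <- 3 * ncol(Xtr) / nrow(Xtr)
  std_res <- residuals / rmse
  high_lev <- lev > h_star
  outlier <- abs(std_res) > 3
  flags <- factor(
    ifelse(high_lev & outlier, "both",
      ifelse(high_lev, "high_leverage",
        ifelse(outlier, "residual_outlier", "in_domain"))),
    levels = c("in_domain", "high_leverage", "residual_outlier", "both")
  )
  structure(
    list(leverages = lev, std_residuals = std_res,
         warning_leverage = h_star, flags = flags,
         p_plus_1 = ncol(Xtr)),
    class = "ad_result"
  )
}

#' Relevancy-factor sensitivity analysis
#'
#' The relevancy factor of an input variable is its Pearson product-moment
#' correlation with the target, computed on the raw (unnormalized) scale; the
#' sign gives the direction of the effect and the magnitude its strength.
#'
#' @param dataset a `teac_dataset`.
#' @return a `sensitivity_result`: named `relevancy` vector plus rankings by
#'   `|r|` and by signed value.
#' @export
relevancy_factors <- function(dataset) {
  stopifnot(inherits(dataset, "teac_dataset"))
  if (length(dataset$target) < 3L) stop("need at least 3 samples")
  sds <- apply(dataset$features, 2L, stats::sd)
  if (stats::sd(dataset$target) == 0 || any(sds == 0)) {
    bad <- if (any(sds == 0)) dataset$feature_names[sds == 0] else "TEAC"
    stop("relevancy factor undefined for constant column(s): ",
         paste(bad, collapse = ", "))
  }
  r <- drop(stats::cor(dataset$features, dataset$target))
  names(r) <- dataset$feature_names
  structure(
    list(relevancy = r,
         ranking_by_magnitude = names(sort(abs(r), decreasing = TRUE)),
         ranking_signed = names(sort(r, decreasing = TRUE))),
    class = "sensitivity_result"
  )
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Relevancy factors (Pearson r with TEAC):\n")
  for (nm in x$ranking_by_magnitude) {
    cat(sprintf("  %-5s %+0.3f\n", nm, x$relevancy[[nm]]))
  }
  invisible(x)
}

#' Evaluate a fitted model over the train/test/total phases
#'
#' Computes [fit_metrics()] on denormalized predictions for the training
#' rows, the test rows, and their union.
#' @param model a fitted `elm_model`.
#' @param dataset a `teac_dataset` (raw scale).
#' @param split a `teac_split`.
#' @param norm_params the `teac_norm_params` used in training.
#' @return named list of `fit_metrics` (`train`, `test`, `total`) plus the
#'   vector of denormalized `predictions`.
#' @export
evaluate_phases <- function(model, dataset, split, norm_params) {
  pred <- predict_teac(model, dataset, norm_params)
  y <- dataset$target
  list(
    train = fit_metrics(y[split$train], pred[split$train], "train"),
    test = fit_metrics(y[split$test], pred[split$test], "test"),
    total = fit_metrics(y, pred, "total"),
    predictions = pred
  )
}
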