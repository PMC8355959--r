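#' Feature names of the seed-composition panel
#'
#' Order is fixed: total phenolics (TP), inositol hexaphosphate (IP6),
#' glucosinolates (GLS), soluble proteins (PROT), ascorbic acid (AA),
#' total tocopherols (TTOT).
#' @export
teac_feature_names <- function() c("TP", "IP6", "GLS", "PROT", "AA", "TTOT")

default_target_correlations <- function() {
  c(TP = -0.45, IP6 = -0.35, GLS = -0.85, PROT = -0.40, AA = -0.25, TTOT = 0.26)
}

# Arbitrary but fixed location/scale for each assay (mg/g d.m. except GLS,
# micromol/g). Only the correlation structure matters downstream; min-max
# normalization removes these units before any model sees the data.
default_feature_means <- function() {
  c(TP = 12, IP6 = 18, GLS = 25, PROT = 280, AA = 0.8, TTOT = 0.20)
}
default_feature_sds <- function() {
  c(TP = 4, IP6 = 5, GLS = 10, PROT = 60, AA = 0.35, TTOT = 0.07)
}

#' Configuration for the synthetic composition-TEAC generator
#'
#' Defines a Gaussian latent-factor population in which each composition
#' variable carries a prescribed Pearson correlation with the TEAC target and
#' the six variables jointly explain a prescribed fraction `max_r2` of the
#' target variance. Both properties hold exactly in the population: the
#' target loads on a latent sample factor `z`, each feature combines `z` with
#' unique noise, and a fraction of every feature's unique noise is shared
#' across assays (one common nuisance factor `u`, e.g. sample-level handling
#' variation). The shared fraction is calibrated by root-finding so the
#' population coefficient of determination equals `max_r2` while the marginal
#' correlations stay at `target_correlations`.
#'
#' @param n_samples number of rows to generate (default 172).
#' @param target_correlations named vector of feature-target Pearson
#'   correlations, names matching [teac_feature_names()]; each in (-1, 1).
#' @param max_r2 population fraction of target variance jointly explainable
#'   by the six features, in (0, 1].
#' @param feature_means,feature_sds named location/scale used to map the
#'   standardized features onto concentration-like values; sds must be > 0.
#' @param target_mean,target_sd location/scale of the TEAC target
#'   (micromol Trolox per g dry mass). The default spread (21.8) puts the
#'   residual scale at `21.8 * sqrt(1 - 0.973) ~ 3.6`, commensurate with an
#'   RMSE of about 3.5 on a well-fitted model.
#' @param seed integer seed; identical configs with identical seeds generate
#'   bit-identical datasets.
#' @return an object of class `teac_generator_config`.
#' @export
generator_config <- function(n_samples = 172L,
                             target_correlations = default_target_correlations(),
                             max_r2 = 0.980,
                             feature_means = default_feature_means(),
                             feature_sds = default_feature_sds(),
                             target_mean = 50.0,
                             target_sd = 21.8,
                             seed = 42L) {
  stop_if_not_count(n_samples, "n_samples", min = 10L)
  feat <- teac_feature_names()
  rho <- target_correlations[feat]
  if (anyNA(rho)) {
    stop("target_correlations must name all of: ", paste(feat, collapse = ", "))
  }
  if (any(abs(rho) >= 1)) {
    stop("every |target correlation| must be < 1")
  }
  if (!is.numeric(max_r2) || length(max_r2) != 1L || max_r2 <= 0 || max_r2 > 1) {
    stop("max_r2 must lie in (0, 1]")
  }
  mu <- feature_means[feat]
  sd <- feature_sds[feat]
  if (anyNA(mu) || anyNA(sd)) {
    stop("feature_means and feature_sds must name all of: ",
         paste(feat, collapse = ", "))
  }
  if (any(sd <= 0) || target_sd <= 0) stop("all sds must be > 0")

  # Factor scale q > max_r2 leaves room for the loadings rho/sqrt(q); the
  # shared-noise fraction phi then closes the gap between the single-factor
  # R2 and max_r2.
  q <- (1 + max_r2) / 2
  loadings <- rho / sqrt(q)
  bad <- which(abs(loadings) >= 1)
  if (length(bad)) {
    stop(sprintf(
      "adjusted loading for feature %s is %.3f, outside (-1, 1); lower |target_correlations[%s]| or raise max_r2",
      feat[bad[1]], loadings[bad[1]], feat[bad[1]]
    ))
  }
  phi <- calibrate_shared_noise(loadings, q, max_r2)

  structure(
    list(
      n_samples = as.integer(n_samples),
      target_correlations = rho,
      max_r2 = max_r2,
      feature_means = mu,
      feature_sds = sd,
      target_mean = target_mean,
      target_sd = target_sd,
      seed = as.integer(seed),
      q = q,
      loadings = loadings,
      shared_noise = phi
    ),
    class = "teac_generator_config"
  )
}

# Population R2 of the target on the six features for shared-noise fraction
# phi: features f = l*z + noise, noise covariance (1-phi)*diag(a^2) +
# phi*a a', target = sqrt(q) z + sqrt(1-q) eta, so R2 = q * S/(1+S) with
# S = l' N^{-1} l (the Fisher information about z in the features).
population_r2 <- function(phi, loadings, q) {
  if (all(loadings == 0)) return(0)
  a2 <- 1 - loadings^2
  N <- (1 - phi) * diag(a2, length(loadings)) + phi * outer(sqrt(a2), sqrt(a2))
  S <- drop(crossprod(loadings, solve(N, loadings)))
  q * S / (1 + S)
}

calibrate_shared_noise <- function(loadings, q, max_r2) {
  if (all(loadings == 0)) return(0)
  if (max_r2 == 1) return(1)
  at_zero <- population_r2(0, loadings, q)
  if (at_zero >= max_r2) {
    stop(sprintf(
      "target_correlations already force a population R2 of %.3f >= max_r2 = %.3f; raise max_r2",
      at_zero, max_r2
    ))
  }
  stats::uniroot(
    function(phi) population_r2(phi, loadings, q) - max_r2,
    lower = 0, upper = 1 - 1e-12, tol = 1e-14
  )$root
}

#' Generate a synthetic composition-TEAC dataset
#'
#' Draws `n_samples` rows from the latent-factor population described in
#' [generator_config()]. In the population, `cor(feature_i, target)` equals
#' the configured correlation exactly and an ordinary least-squares fit of
#' the target on all six features attains `R2 = max_r2` exactly.
#'
#' @param config a `teac_generator_config`.
#' @return a `teac_dataset`: list with `features` (n x 6 matrix), `target`
#'   (length-n numeric) and `feature_names`.
#' @examples
#' d <- generate_dataset(generator_config(seed = 42))
#' nrow(d$features)  # 172
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "teac_generator_config"))
  n <- config$n_samples
  p <- length(config$loadings)
  l <- config$loadings
  a <- sqrt(1 - l^2)
  phi <- config$shared_noise
  q <- config$q

  with_seed(config$seed, {
    z <- stats::rnorm(n)
    u <- stats::rnorm(n)
    eta <- stats::rnorm(n)
    E <- matrix(stats::rnorm(n * p), n, p)

    feat_std <- outer(z, l) +
      sweep(sqrt(1 - phi) * E + sqrt(phi) * u, 2L, a, `*`)
    y_std <- sqrt(q) * z + sqrt(1 - q) * eta

    features <- sweep(sweep(feat_std, 2L, config$feature_sds, `*`),
                      2L, config$feature_means, `+`)
    colnames(features) <- names(config$loadings)
    new_teac_dataset(
      features,
      config$target_mean + config$target_sd * y_std
    )
  })
}

new_teac_dataset <- function(features, target) {
  stopifnot(is.matrix(features), nrow(features) == length(target),
            !anyNA(features), !anyNA(target))
  structure(
    list(
      features = features,
      target = as.numeric(target),
      feature_names = colnames(features)
    ),
    class = "teac_dataset"
  )
}

#' @export
print.teac_dataset <- function(x, ...) {
  cat(sprintf(
    "<teac_dataset> %d samples x %d features (%s); target range [%.2f, %.2f]\n",
    nrow(x$features), ncol(x$features),
    paste(x$feature_names, collapse = ", "),
    min(x$target), max(x$target)
  ))
  invisible(x)
}

#' @export
as.data.frame.teac_dataset <- function(x, ...) {
  out <- as.data.frame(x$features)
  out$TEAC <- x$target
  out
}

#' Write / read a dataset as CSV
#'
#' Plain-decimal CSV with header `TP,IP6,GLS,PROT,AA,TTOT,TEAC`, UTF-8,
#' LF line endings.
#' @param dataset a `teac_dataset`.
#' @param path file path.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "teac_dataset"))
  df <- as.data.frame(dataset)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  target_col <- "TEAC"
  if (!target_col %in% names(df)) {
    stop("CSV must contain a TEAC column")
  }
  feats <- setdiff(names(df), target_col)
  new_teac_dataset(as.matrix(df[feats]), df[[target_col]])
}
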