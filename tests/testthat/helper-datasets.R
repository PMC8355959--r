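# Build a teac_dataset directly from a feature matrix and target vector.
make_dataset <- function(features, target) {
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("X", seq_len(ncol(features)))
  }
  teacelm:::new_teac_dataset(features, target)
}

# A small raw-scale regression problem with a known linear signal.
toy_linear_dataset <- function(n = 40, d = 3, noise_sd = 0, seed = 7) {
  set.seed(seed)
  X <- matrix(runif(n * d, -2, 2), n, d)
  beta <- seq_len(d)
  y <- 5 + drop(X %*% beta) + rnorm(n, sd = noise_sd)
  make_dataset(X, y)
}
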