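#' Configuration for PSO-ELM training
#'
#' The swarm searches the hidden layer's input weights and biases (the output
#' weights stay analytic via the least-squares solve inside the fitness), so
#' the search dimension is `H * (d + 1)`. The hidden-neuron count H defaults
#' to 12, twice the width of the six-variable composition panel, which keeps
#' the search space at 84 dimensions.
#'
#' @param H hidden-neuron count.
#' @param d input dimension (6 for the composition panel).
#' @param activation activation identifier.
#' @param ridge regularization for the output-weight solve.
#' @param fitness_metric only `"rmse"` (training-partition RMSE on the
#'   normalized scale) is registered.
#' @param cv_folds optional integer >= 2: evaluate fitness as the
#'   cross-validated RMSE over this many folds of the training partition
#'   instead of the resubstitution RMSE. NULL (default) uses training RMSE.
#' @param n_particles,max_iterations,inertia,c1,c2 passed to [pso_config()].
#' @param seed master seed for the training run.
#' @return a `trainer_config` containing the derived `pso_config`.
#' @export
trainer_config <- function(H = 12L, d = 6L, activation = "sigmoid",
                           ridge = 1e-8, fitness_metric = "rmse",
                           cv_folds = NULL,
                           n_particles = 30L, max_iterations = 200L,
                           inertia = 0.729, c1 = 1.49445, c2 = 1.49445,
                           seed = 42L) {
  stop_if_not_count(H, "H")
  stop_if_not_count(d, "d")
  if (!identical(fitness_metric, "rmse")) {
    stop("unregistered fitness metric: ", fitness_metric)
  }
  D <- as.integer(H * (d + 1L))
  structure(
    list(H = as.integer(H), d = as.integer(d), activation = activation,
         ridge = ridge, fitness_metric = fitness_metric, cv_folds = cv_folds,
         pso = pso_config(n_particles = n_particles, dimension = D,
                          inertia = inertia, c1 = c1, c2 = c2,
                          max_iterations = max_iterations,
                          position_bounds = c(-1, 1),
                          seed = derive_seed(seed, "pso")),
         seed = as.integer(seed)),
    class = "trainer_config"
  )
}

#' Flatten / restore hidden-layer parameters for the swarm
#'
#' The position vector is the row-major flattening of the H x d input-weight
#' matrix followed by the H biases: `(w11, ..., w1d, w21, ..., wHd, c1, ..., cH)`.
#' @param input_weights H x d matrix.
#' @param hidden_biases length-H vector.
#' @export
encode_hidden <- function(input_weights, hidden_biases) {
  stopifnot(is.matrix(input_weights),
            nrow(input_weights) == length(hidden_biases))
  c(as.vector(t(input_weights)), hidden_biases)
}

#' @rdname encode_hidden
#' @param position numeric vector of length `H * (d + 1)`.
#' @param H,d hidden-neuron count and input dimension.
#' @export
decode_hidden <- function(position, H, d) {
  if (length(position) != H * (d + 1L)) {
    stop(sprintf("position length %d != H * (d + 1) = %d",
                 length(position), H * (d + 1L)))
  }
  list(
    input_weights = matrix(position[seq_len(H * d)], nrow = H, ncol = d,
                           byrow = TRUE),
    hidden_biases = position[H * d + seq_len(H)]
  )
}

#' Swarm fitness of one hidden-layer candidate
#'
#' Decodes the position, builds the hidden matrix on the (normalized)
#' training inputs, solves the output weights with the configured ridge, and
#' returns the training RMSE on the normalized scale (or the K-fold
#' cross-validated RMSE when `cv_folds` is set). Deterministic given its
#' inputs; non-finite results become `+Inf`.
#'
#' @param position numeric vector of length `H * (d + 1)`.
#' @param X_train,y_train normalized training inputs and targets.
#' @param config a `trainer_config`.
#' @export
elm_fitness <- function(position, X_train, y_train, config) {
  hp <- decode_hidden(position, config$H, config$d)
  model <- new_elm_model(hp$input_weights, hp$hidden_biases,
                         activation = config$activation)
  rmse_of <- function(train_idx, eval_idx) {
    A <- hidden_matrix(X_train[train_idx, , drop = FALSE], model)
    beta <- solve_output_weights(A, y_train[train_idx], ridge = config$ridge)
    A_eval <- if (identical(train_idx, eval_idx)) A else {
      hidden_matrix(X_train[eval_idx, , drop = FALSE], model)
    }
    sqrt(mean((y_train[eval_idx] - drop(A_eval %*% beta))^2))
  }
  n <- length(y_train)
  fit <- tryCatch({
    if (is.null(config$cv_folds)) {
      rmse_of(seq_len(n), seq_len(n))
    } else {
      folds <- rep_len(seq_len(config$cv_folds), n)
      sqrt(mean(unlist(lapply(seq_len(config$cv_folds), function(k) {
        (rmse_of(which(folds != k), which(folds == k)))^2
      }))))
    }
  }, error = function(e) Inf)
  if (!is.finite(fit)) Inf else fit
}

#' Train a PSO-ELM model
#'
#' Runs the swarm over [elm_fitness()] on the training partition only (test
#' rows never enter the fitness), then refits the output weights of the best
#' hidden layer on the full training partition.
#'
#' @param dataset a `teac_dataset` on the raw scale.
#' @param split a `teac_split`.
#' @param norm_params a `teac_norm_params` covering features and target.
#' @param config a `trainer_config`.
#' @return list with `model` (a fitted `elm_model`), `fitness_history`,
#'   `best_fitness` (normalized-scale training RMSE) and `config`.
#' @export
train_pso_elm <- function(dataset, split, norm_params, config = trainer_config()) {
  stopifnot(inherits(dataset, "teac_dataset"), inherits(split, "teac_split"),
            inherits(norm_params, "teac_norm_params"),
            inherits(config, "trainer_config"))
  if (length(split$train) == 0L) stop("empty training partition")
  if (ncol(dataset$features) != config$d) {
    stop(sprintf("dataset has %d features but the trainer expects %d",
                 ncol(dataset$features), config$d))
  }
  norm <- normalize_dataset(dataset, norm_params)
  X_train <- norm$features[split$train, , drop = FALSE]
  y_train <- norm$target[split$train]

  result <- pso_optimize(
    function(pos) elm_fitness(pos, X_train, y_train, config),
    config$pso
  )

  hp <- decode_hidden(result$best_position, config$H, config$d)
  model <- fit_elm(X_train, y_train,
                   new_elm_model(hp$input_weights, hp$hidden_biases,
                                 activation = config$activation),
                   ridge = config$ridge)
  list(model = model,
       fitness_history = result$fitness_history,
       best_fitness = result$best_fitness,
       config = config)
}

#' Predict TEAC on the physical scale
#'
#' Normalizes the inputs, applies the model, and denormalizes the output.
#' @param model a fitted `elm_model`.
#' @param dataset a `teac_dataset` on the raw scale.
#' @param norm_params the `teac_norm_params` used in training.
#' @export
predict_teac <- function(model, dataset, norm_params) {
  norm <- normalize_dataset(dataset, norm_params)
  denormalize_target(predict(model, norm$features), norm_params)
}
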