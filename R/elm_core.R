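#' Registered hidden-layer activation functions
#'
#' `sigmoid` is the logistic function 1/(1 + exp(-x)), the classic choice for
#' random-feature single-hidden-layer networks; `tanh` and `linear` are
#' provided for testing and for the linear-limit equivalence with ordinary
#' least squares.
#' @param name one of `"sigmoid"`, `"tanh"`, `"linear"`.
#' @return the activation as an R function.
#' @export
activation_fn <- function(name) {
  switch(name,
    sigmoid = function(x) 1 / (1 + exp(-x)),
    tanh    = base::tanh,
    linear  = identity,
    stop("unknown activation: ", name)
  )
}

#' Construct an extreme learning machine model object
#'
#' @param input_weights H x d matrix of hidden-layer input weights.
#' @param hidden_biases length-H vector of hidden biases.
#' @param activation activation identifier (see [activation_fn()]).
#' @param output_weights length-H vector, or NULL before the output layer is
#'   solved.
#' @return an `elm_model`.
#' @export
new_elm_model <- function(input_weights, hidden_biases,
                          activation = "sigmoid", output_weights = NULL) {
  stopifnot(is.matrix(input_weights),
            length(hidden_biases) == nrow(input_weights))
  activation_fn(activation)  # validates the identifier
  if (!is.null(output_weights) &&
      length(output_weights) != nrow(input_weights)) {
    stop("output_weights length must equal the hidden-neuron count")
  }
  structure(
    list(
      input_weights = input_weights,
      hidden_biases = as.numeric(hidden_biases),
      output_weights = if (is.null(output_weights)) NULL else as.numeric(output_weights),
      activation = activation,
      d = ncol(input_weights),
      H = nrow(input_weights)
    ),
    class = "elm_model"
  )
}

#' Random hidden-layer initialization
#'
#' Input weights and hidden biases are drawn i.i.d. uniform on \[-1, 1\].
#' @param d input dimension (>= 1).
#' @param H hidden-neuron count (>= 1).
#' @param seed integer seed; the draw is fully determined by it.
#' @return list with `input_weights` (H x d) and `hidden_biases` (length H).
#' @export
init_hidden <- function(d, H, seed = NULL) {
  stop_if_not_count(d, "d")
  stop_if_not_count(H, "H")
  with_seed(seed, {
    list(
      input_weights = matrix(stats::runif(H * d, -1, 1), nrow = H, ncol = d),
      hidden_biases = stats::runif(H, -1, 1)
    )
  })
}

#' Hidden-layer activation matrix
#'
#' Computes the N x H matrix with entries `f(w_i . x_j + c_i)`: rows are
#' samples, columns are hidden neurons.
#' @param X N x d matrix of inputs (normalized scale).
#' @param model an `elm_model`.
#' @export
hidden_matrix <- function(X, model) {
  stopifnot(inherits(model, "elm_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$d) {
    stop(sprintf("input width %d does not match model dimension %d",
                 ncol(X), model$d))
  }
  f <- activation_fn(model$activation)
  pre <- X %*% t(model$input_weights)
  pre <- sweep(pre, 2L, model$hidden_biases, `+`)
  A <- f(pre)
  if (!all(is.finite(A))) stop("non-finite entries in the hidden matrix")
  A
}

#' Solve the ELM output weights by least squares
#'
#' Minimum-norm least-squares solution of `A beta = Y` via the Moore-Penrose
#' pseudoinverse (`ridge = 0`), or the ridge-regularized normal equations
#' `(A'A + ridge I) beta = A'Y` for `ridge > 0`. The tiny default ridge
#' stabilizes near-singular hidden matrices encountered during swarm search;
#' set `ridge = 0` for exact interpolation.
#'
#' @param A N x H hidden matrix.
#' @param Y length-N target vector (normalized scale).
#' @param ridge nonnegative regularization constant.
#' @return length-H vector of output weights.
#' @export
solve_output_weights <- function(A, Y, ridge = 1e-8) {
  A <- as.matrix(A)
  Y <- as.numeric(Y)
  if (nrow(A) != length(Y)) stop("A rows must match length(Y)")
  if (!all(is.finite(A)) || !all(is.finite(Y))) {
    stop("non-finite entries in the least-squares system")
  }
  if (ridge > 0) {
    G <- crossprod(A) + diag(ridge, ncol(A))
    sol <- tryCatch(solve(G, crossprod(A, Y)), error = function(e) NULL)
    if (!is.null(sol)) return(drop(sol))
    # fall through to the pseudoinverse on (numerically) singular systems
  }
  sv <- svd(A)
  tol <- max(dim(A)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  drop(sv$v %*% (dinv * crossprod(sv$u, Y)))
}

#' Fit an ELM given fixed hidden parameters
#'
#' Convenience wrapper: builds the hidden matrix for `X`, solves the output
#' weights against `Y`, and returns the completed model.
#' @inheritParams hidden_matrix
#' @inheritParams solve_output_weights
#' @export
fit_elm <- function(X, Y, model, ridge = 1e-8) {
  A <- hidden_matrix(X, model)
  model$output_weights <- solve_output_weights(A, Y, ridge = ridge)
  model
}

#' Predict with a fitted ELM
#'
#' Returns `A %*% output_weights` on the normalized scale; denormalization is
#' the pipeline's job.
#' @param object an `elm_model` with populated output weights.
#' @param X N x d input matrix.
#' @param ... unused.
#' @export
predict.elm_model <- function(object, X, ...) {
  if (is.null(object$output_weights)) {
    stop("model output weights are not populated; fit the model first")
  }
  drop(hidden_matrix(X, object) %*% object$output_weights)
}

#' Hidden-feature-map kernel value
#'
#' The dot product `h(x_i) . h(x_j)` of the hidden-layer feature maps of two
#' input vectors; equals the corresponding entry of `A %*% t(A)`.
#' @param x_i,x_j numeric vectors of width d.
#' @param model an `elm_model`.
#' @export
kernel_value <- function(x_i, x_j, model) {
  if (length(x_i) != model$d || length(x_j) != model$d) {
    stop("kernel inputs must have width equal to the model dimension")
  }
  H2 <- hidden_matrix(rbind(x_i, x_j), model)
  drop(H2[1L, ] %*% H2[2L, ])
}

#' Serialize / restore an ELM model as JSON
#'
#' Stores weights, biases, activation identifier and (optionally) the
#' normalization parameters needed to apply the model to raw data.
#' @param model an `elm_model`.
#' @param path file path.
#' @param norm_params optional `teac_norm_params` to embed.
#' @export
write_elm_model <- function(model, path, norm_params = NULL) {
  stopifnot(inherits(model, "elm_model"))
  doc <- list(
    activation = model$activation,
    d = model$d, H = model$H,
    input_weights = model$input_weights,
    hidden_biases = model$hidden_biases,
    output_weights = model$output_weights
  )
  if (!is.null(norm_params)) {
    doc$normalization <- list(min = as.list(norm_params$min),
                              max = as.list(norm_params$max),
                              scope = norm_params$scope)
  }
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_elm_model
#' @export
read_elm_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- new_elm_model(
    matrix(doc$input_weights, nrow = doc$H, ncol = doc$d),
    doc$hidden_biases,
    activation = doc$activation,
    output_weights = doc$output_weights
  )
  if (!is.null(doc$normalization)) {
    attr(model, "norm_params") <- structure(
      list(min = unlist(doc$normalization$min),
           max = unlist(doc$normalization$max),
           scope = doc$normalization$scope),
      class = "teac_norm_params"
    )
  }
  model
}
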