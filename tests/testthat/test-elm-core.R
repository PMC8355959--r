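test_that("hidden initialization is uniform on [-1, 1], shaped, and seeded", {
  h <- init_hidden(6, 12, seed = 1)
  expect_equal(dim(h$input_weights), c(12L, 6L))
  expect_length(h$hidden_biases, 12L)
  expect_identical(h, init_hidden(6, 12, seed = 1))

  big <- init_hidden(100, 1000, seed = 2)
  draws <- c(big$input_weights, big$hidden_biases)
  expect_true(all(draws >= -1 & draws <= 1))
  expect_lt(abs(mean(draws)), 0.01)

  expect_error(init_hidden(0, 5), "d")
  expect_error(init_hidden(5, 0), "H")
})

test_that("hidden matrix matches the explicit per-entry loop", {
  set.seed(10)
  X <- matrix(rnorm(3 * 4), 3, 4)
  h <- init_hidden(4, 2, seed = 3)
  for (act in c("sigmoid", "tanh", "linear")) {
    m <- new_elm_model(h$input_weights, h$hidden_biases, activation = act)
    A <- hidden_matrix(X, m)
    f <- activation_fn(act)
    for (j in 1:3) for (i in 1:2) {
      expect_equal(A[j, i],
                   f(sum(h$input_weights[i, ] * X[j, ]) + h$hidden_biases[i]),
                   tolerance = 1e-12)
    }
  }
  # zero weights and biases under the sigmoid give a constant 0.5 map
  m0 <- new_elm_model(matrix(0, 2, 4), c(0, 0))
  expect_true(all(hidden_matrix(X, m0) == 0.5))
  # linear activation reduces to an affine map
  ml <- new_elm_model(h$input_weights, h$hidden_biases, activation = "linear")
  expect_equal(hidden_matrix(X, ml),
               X %*% t(h$input_weights) +
                 matrix(h$hidden_biases, 3, 2, byrow = TRUE),
               tolerance = 1e-12)
  expect_error(hidden_matrix(X[, 1:3], ml), "width")
})

test_that("output-weight solve agrees with the normal-equations oracle", {
  set.seed(4)
  A <- matrix(rnorm(10), 5, 2)
  Y <- rnorm(5)
  oracle <- solve(crossprod(A), crossprod(A, Y))
  expect_equal(solve_output_weights(A, Y, ridge = 0), drop(oracle),
               tolerance = 1e-10)

  # identity system returns the targets; square systems interpolate
  expect_equal(solve_output_weights(diag(4), Y[1:4], ridge = 0), Y[1:4])
  Asq <- matrix(rnorm(16), 4, 4)
  beta <- solve_output_weights(Asq, Y[1:4], ridge = 0)
  expect_lt(max(abs(Asq %*% beta - Y[1:4])), 1e-8)

  expect_error(solve_output_weights(matrix(c(1, NA), 1, 2), 1), "finite")
})

test_that("prediction equals the hidden-layer summation oracle", {
  set.seed(5)
  X <- matrix(rnorm(12), 4, 3)
  h <- init_hidden(3, 5, seed = 6)
  m <- new_elm_model(h$input_weights, h$hidden_biases,
                     output_weights = rnorm(5))
  pred <- predict(m, X)
  f <- activation_fn("sigmoid")
  for (j in 1:4) {
    e_j <- sum(vapply(1:5, function(i) {
      m$output_weights[i] * f(sum(m$input_weights[i, ] * X[j, ]) +
                                m$hidden_biases[i])
    }, numeric(1)))
    expect_equal(pred[j], e_j, tolerance = 1e-12)
  }
  # pass-through configuration: one linear neuron reading the first feature
  mp <- new_elm_model(matrix(c(1, 0, 0), 1, 3), 0, activation = "linear",
                      output_weights = 1)
  expect_equal(predict(mp, X), X[, 1])
  expect_error(predict(new_elm_model(h$input_weights, h$hidden_biases), X),
               "output weights")
})

test_that("ELM interpolates exactly when H equals the sample count", {
  set.seed(7)
  X <- matrix(runif(10 * 2, -1, 1), 10, 2)
  y <- rnorm(10)
  h <- init_hidden(2, 10, seed = 8)
  m <- fit_elm(X, y, new_elm_model(h$input_weights, h$hidden_biases),
               ridge = 0)
  expect_lt(sqrt(mean((predict(m, X) - y)^2)), 1e-6)
})

test_that("linear-activation ELM matches ordinary least squares", {
  set.seed(9)
  X <- matrix(rnorm(50 * 3), 50, 3)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(50, sd = 0.3)
  h <- init_hidden(3, 8, seed = 10)  # H >= d + 1
  m <- fit_elm(X, y, new_elm_model(h$input_weights, h$hidden_biases,
                                   activation = "linear"), ridge = 0)
  r2_elm <- 1 - sum((y - predict(m, X))^2) / sum((y - mean(y))^2)
  r2_ols <- summary(lm(y ~ X))$r.squared
  expect_equal(r2_elm, r2_ols, tolerance = 1e-6)
})

test_that("kernel values are consistent with the hidden feature map", {
  h <- init_hidden(3, 2, seed = 11)
  m <- new_elm_model(h$input_weights, h$hidden_biases)
  a <- c(0.3, -0.2, 0.9); b <- c(-1, 0.5, 0.1)
  f <- activation_fn("sigmoid")
  ha <- f(drop(h$input_weights %*% a) + h$hidden_biases)
  hb <- f(drop(h$input_weights %*% b) + h$hidden_biases)
  expect_equal(kernel_value(a, b, m), sum(ha * hb), tolerance = 1e-12)
  expect_equal(kernel_value(a, b, m), kernel_value(b, a, m))
  expect_gte(kernel_value(a, a, m), 0)
  expect_error(kernel_value(a[1:2], b, m), "width")

  # Gram consistency: the pairwise kernel matrix equals A A'
  set.seed(12)
  X <- matrix(rnorm(6 * 3), 6, 3)
  A <- hidden_matrix(X, m)
  K <- outer(1:6, 1:6, Vectorize(function(i, j) kernel_value(X[i, ], X[j, ], m)))
  expect_equal(K, A %*% t(A), tolerance = 1e-10)
})

test_that("model JSON serialization round-trips", {
  h <- init_hidden(4, 3, seed = 13)
  m <- new_elm_model(h$input_weights, h$hidden_biases, output_weights = rnorm(3))
  path <- withr::local_tempfile(fileext = ".json")
  d <- toy_linear_dataset()
  np <- fit_normalizer(d)
  write_elm_model(m, path, np)
  back <- read_elm_model(path)
  expect_equal(back$input_weights, m$input_weights)
  expect_equal(back$output_weights, m$output_weights)
  expect_equal(attr(back, "norm_params")$min, np$min)
})
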