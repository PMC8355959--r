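test_that("swarm encoding flattens row-major, weights before biases", {
  W <- matrix(c(11, 12, 21, 22), 2, 2, byrow = TRUE)
  b <- c(1, 2)
  expect_equal(encode_hidden(W, b), c(11, 12, 21, 22, 1, 2))
  dec <- decode_hidden(encode_hidden(W, b), H = 2, d = 2)
  expect_equal(dec$input_weights, W)
  expect_equal(dec$hidden_biases, b)

  expect_length(encode_hidden(matrix(0, 2, 3), c(0, 0)), 8L)
  expect_error(decode_hidden(1:7, H = 2, d = 3), "position length")
})

test_that("swarm fitness equals an externally recomputed training RMSE", {
  d <- toy_linear_dataset(n = 30, noise_sd = 0.5)
  split <- make_split(30, seed = 1)
  np <- fit_normalizer(d)
  norm <- normalize_dataset(d, np)
  cfg <- trainer_config(H = 5, d = 3, seed = 2)
  set.seed(3)
  pos <- runif(5 * 4, -1, 1)
  X_tr <- norm$features[split$train, ]
  y_tr <- norm$target[split$train]

  fit <- elm_fitness(pos, X_tr, y_tr, cfg)
  hp <- decode_hidden(pos, 5, 3)
  m <- fit_elm(X_tr, y_tr,
               new_elm_model(hp$input_weights, hp$hidden_biases),
               ridge = cfg$ridge)
  rmse <- fit_metrics(y_tr + 10, predict(m, X_tr) + 10, "train")$rmse
  expect_equal(fit, rmse, tolerance = 1e-12)
})

test_that("fitness degenerate cases: exact linear fit and constant targets", {
  set.seed(4)
  X <- matrix(runif(20 * 3, -1, 1), 20, 3)
  y <- drop(X %*% c(0.2, -0.4, 0.1))
  cfg <- trainer_config(H = 4, d = 3, activation = "linear", ridge = 0)
  pos <- runif(4 * 4, -1, 1)
  expect_lt(elm_fitness(pos, X, y, cfg), 1e-6)

  # zero position: all hidden outputs constant, bias absorbs a constant target
  cfg_s <- trainer_config(H = 4, d = 3, ridge = 0)
  expect_lt(elm_fitness(rep(0, 16), X, rep(0.7, 20), cfg_s), 1e-12)
})

test_that("test rows never influence the trained model", {
  d <- generate_dataset(generator_config(n_samples = 40, seed = 21))
  split <- make_split(40, seed = 22)
  np <- fit_normalizer(d, scope = "train", split = split)
  cfg <- trainer_config(H = 4, n_particles = 8, max_iterations = 15, seed = 23)
  fit1 <- train_pso_elm(d, split, np, cfg)

  d2 <- d
  d2$features[split$test, ] <- d2$features[split$test, ] * 3 + 1
  d2$target[split$test] <- rev(d2$target[split$test]) + 100
  fit2 <- train_pso_elm(d2, split, np, cfg)

  expect_identical(fit1$model, fit2$model)
  expect_identical(fit1$fitness_history, fit2$fitness_history)
})

test_that("training is reproducible and never worse than its initial swarm", {
  d <- generate_dataset(generator_config(n_samples = 50, seed = 31))
  split <- make_split(50, seed = 32)
  np <- fit_normalizer(d)
  cfg <- trainer_config(H = 4, n_particles = 8, max_iterations = 20, seed = 33)
  f1 <- train_pso_elm(d, split, np, cfg)
  f2 <- train_pso_elm(d, split, np, cfg)
  expect_identical(f1$model, f2$model)
  expect_lte(f1$best_fitness, f1$fitness_history[1])
  expect_true(all(diff(f1$fitness_history) <= 0))
})

test_that("swarm tuning beats untuned random hidden layers at equal H", {
  pso_rmse <- numeric(5)
  random_rmse <- numeric(5)
  for (s in 1:5) {
    d <- generate_dataset(generator_config(n_samples = 60, seed = 100 + s))
    split <- make_split(60, seed = 200 + s)
    np <- fit_normalizer(d)
    cfg <- trainer_config(H = 6, n_particles = 10, max_iterations = 30,
                          seed = 300 + s)
    fit <- train_pso_elm(d, split, np, cfg)
    pso_rmse[s] <- fit$best_fitness

    norm <- normalize_dataset(d, np)
    h <- init_hidden(6, 6, seed = 400 + s)
    m <- fit_elm(norm$features[split$train, ], norm$target[split$train],
                 new_elm_model(h$input_weights, h$hidden_biases))
    random_rmse[s] <- sqrt(mean((predict(m, norm$features[split$train, ]) -
                                   norm$target[split$train])^2))
  }
  expect_lt(median(pso_rmse), median(random_rmse))
})

test_that("noise-free generator configs are fit almost perfectly", {
  for (s in 1:3) {
    d <- generate_dataset(generator_config(n_samples = 60, max_r2 = 1,
                                           seed = 500 + s))
    split <- make_split(60, seed = 600 + s)
    np <- fit_normalizer(d)
    cfg <- trainer_config(H = 8, activation = "linear", n_particles = 10,
                          max_iterations = 20, seed = 700 + s)
    fit <- train_pso_elm(d, split, np, cfg)
    ev <- evaluate_phases(fit$model, d, split, np)
    expect_gte(ev$total$r2, 0.999)
  }
})

test_that("empty or mismatched training inputs are rejected", {
  d <- toy_linear_dataset(n = 20)
  split <- make_split(20, seed = 1)
  np <- fit_normalizer(d)
  empty_split <- structure(list(train = integer(0), test = 1:20, seed = 0L),
                           class = "teac_split")
  expect_error(train_pso_elm(d, empty_split, np, trainer_config(H = 2, d = 3)),
               "empty")
  expect_error(train_pso_elm(d, split, np, trainer_config(H = 2, d = 5)),
               "features")
})
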