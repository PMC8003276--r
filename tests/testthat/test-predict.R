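dense_params <- function(sizes) {
  sum(vapply(seq_len(length(sizes) - 1),
             function(l) sizes[l] * sizes[l + 1] + sizes[l + 1], 0))
}

test_that("model architectures match their specifications", {
  ri <- build_ri_model(10L)
  expect_equal(ri$sizes, c(10L, 128L, 128L, 128L, 128L, 1L))
  expect_equal(mlp_n_params(ri), dense_params(c(10, 128, 128, 128, 128, 1)))

  pi_m <- build_pi_model(8L)
  expect_equal(pi_m$sizes, c(12L, 64L, 32L, 16L, 1L))
  expect_equal(pi_m$embed$n_in, 8L)
  expect_equal(mlp_n_params(pi_m),
               8 * 3 + 3 + dense_params(c(12, 64, 32, 16, 1)))
  # single scalar output
  X <- cbind(encode_place("p1", sprintf("p%d", 1:8)), matrix(0.5, 1, 9))
  expect_length(predict(pi_m, X), 1L)
})

test_that("the architecture grid enumerates 27 distinct configurations", {
  g <- pi_grid()
  expect_equal(nrow(g), 27L)
  expect_false(any(duplicated(vapply(g$hidden, paste, "", collapse = "x"))))
  # the worked grid points: 256 x 0.5 x 3 and the selected 64 x 0.5 x 3
  expect_true(any(vapply(g$hidden, identical, TRUE, c(256L, 128L, 64L))))
  expect_true(any(vapply(g$hidden, identical, TRUE, c(64L, 32L, 16L))))
  # depth-1 specs appear once each
  expect_equal(sum(g$depth == 1L), 3L)
})

test_that("popularity-model inference is nonnegative for any input", {
  set.seed(13)
  m <- build_pi_model(5L, seed = 2L)
  X <- cbind(encode_place(sample(sprintf("p%d", 1:5), 50, TRUE),
                          sprintf("p%d", 1:5)),
             matrix(runif(50 * 9, -2, 2), 50, 9))
  expect_true(all(predict(m, X) >= 0))
})

test_that("training fits a constant and a known linear signal", {
  set.seed(4)
  X <- matrix(runif(240 * 5), 240, 5)
  const <- mlp_train(mlp_new(c(5, 16, 1), seed = 1), X, rep(0.42, 240),
                     epochs = 300, lr = 1e-2, seed = 1)
  expect_lt(evaluate_model(const, X, rep(0.42, 240))$mae, 0.01)

  sigma <- 0.02
  beta <- c(0.3, -0.2, 0.1, 0.25, -0.15)
  y <- 0.3 + as.numeric(X %*% beta) + rnorm(240, 0, sigma)
  sp <- train_test_split(240, 0.7, seed = 2)
  m <- mlp_train(mlp_new(c(5, 32, 32, 1), seed = 1),
                 X[sp$train, ], y[sp$train], epochs = 400, lr = 3e-3,
                 patience = 50, seed = 2)
  ev <- evaluate_model(m, X[sp$test, ], y[sp$test])
  expect_lte(ev$mae, 2 * sigma)

  # shuffled-label negative control: no better than the mean predictor
  y_shuf <- sample(y)
  m0 <- mlp_train(mlp_new(c(5, 32, 32, 1), seed = 1),
                  X[sp$train, ], y_shuf[sp$train], epochs = 100, seed = 2)
  ev0 <- evaluate_model(m0, X[sp$test, ], y_shuf[sp$test])
  baseline <- mean(abs(mean(y_shuf[sp$train]) - y_shuf[sp$test]))
  expect_gt(ev0$mae, 0.6 * baseline)
})

test_that("training is reproducible under a fixed seed", {
  set.seed(6)
  X <- matrix(runif(150 * 4), 150, 4)
  y <- X[, 1] * 0.5 + 0.1
  m1 <- mlp_train(mlp_new(c(4, 16, 1), seed = 3), X, y, epochs = 30, seed = 9)
  m2 <- mlp_train(mlp_new(c(4, 16, 1), seed = 3), X, y, epochs = 30, seed = 9)
  expect_identical(predict(m1, X), predict(m2, X))
  expect_error(mlp_train(mlp_new(c(4, 16, 1), seed = 3), X,
                         y + c(Inf, rep(0, 149)), epochs = 5, seed = 1),
               "non-finite")
})

test_that("grid search returns the lowest test MSE, first on ties", {
  set.seed(10)
  n <- 80
  pid <- sprintf("p%d", 1:3)
  X <- cbind(encode_place(sample(pid, n, TRUE), pid),
             matrix(runif(n * 9), n, 9))
  y <- rep(0.2, n)  # degenerate constant target
  gs <- grid_search(X[1:56, ], y[1:56], X[57:80, ], y[57:80],
                    n_places = 3, epochs = 2, patience = 1, seed = 1)
  expect_equal(nrow(gs$results), 27L)
  best_mse <- min(gs$results$mse)
  expect_equal(gs$best$mse, best_mse)
  expect_equal(gs$best$config, which(gs$results$mse == best_mse)[1])
})

test_that("fitted predictors round-trip through JSON serialization", {
  set.seed(14)
  rec <- tibble::tibble(
    date = as.Date("2020-02-01") + rep(0:29, each = 3),
    slot = rep(c("morning", "noon", "afternoon"), 30),
    workday = rep(c(TRUE, FALSE), length.out = 90),
    temperature_c = runif(90, 0, 30),
    walk_predisposition = rnorm(90),
    weather = sample(c("sunny", "cloudy", "rainy"), 90, TRUE),
    ri = runif(90, 0, 0.4)
  )
  fit <- train_ri_predictor(rec, epochs = 10, seed = 5)
  tmp <- withr::local_tempfile(fileext = ".json")
  save_predictor(fit, tmp)
  fit2 <- load_predictor(tmp)
  expect_s3_class(fit2, "ri_predictor")
  expect_equal(predict(fit2, rec), predict(fit, rec), tolerance = 1e-12)
})
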