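#' Community sociability regression network
#'
#' Builds the regressor for the Community Time-Specific Adjusted RI: one
#' input neuron per covariate (the season taking a block of its own), four
#' hidden layers of 128 ReLU units, and a single linear output.
#'
#' @param n_inputs Number of input features (see [encode_ri_features()]).
#' @param hidden Hidden layer widths.
#' @param seed Weight-initialization seed.
#' @return A [mlp_new()] model.
#' @export
build_ri_model <- function(n_inputs, hidden = c(128L, 128L, 128L, 128L),
                           seed = 1L) {
  mlp_new(c(n_inputs, hidden, 1L), seed = seed)
}

#' Place-popularity regression network
#'
#' The place one-hot block is first mapped onto a 3-dimensional latent
#' space; the latent vector is concatenated with the 9 remaining encoded
#' inputs (fuzzy season, hour, weather, temperature) giving 12 inputs to
#' the hidden stack. The output neuron uses a Leaky ReLU during training
#' and a ReLU at prediction time, so inferred popularity is nonnegative.
#' The default hidden stack `64, 32, 16` is the best configuration of the
#' grid in [pi_grid()].
#'
#' @param n_places Number of encodable places.
#' @param hidden Hidden layer widths.
#' @param latent_dim Dimension of the place latent space.
#' @param seed Weight-initialization seed.
#' @return A [mlp_new()] model.
#' @export
build_pi_model <- function(n_places, hidden = c(64L, 32L, 16L),
                           latent_dim = 3L, seed = 1L) {
  if (any(hidden < 1L)) stop("invalid hidden widths")
  mlp_new(c(latent_dim + 9L, hidden, 1L),
          out_train = "leaky_relu", out_pred = "relu",
          embed = list(n_in = as.integer(n_places), dim = as.integer(latent_dim)),
          seed = seed)
}

#' The architecture grid for the popularity model
#'
#' Enumerates first-hidden-layer dimension in {16, 64, 256}, a scaling
#' factor in {0.5, 1} applied when moving to each subsequent layer, and a
#' depth from 1 to 5 hidden layers. At depth 1 the scaling factor is
#' irrelevant, so the duplicated specifications are removed, leaving 27
#' distinct configurations.
#'
#' @return A tibble with columns `config`, `dim`, `scale`, `depth`,
#'   `hidden` (list column of width vectors).
#' @export
pi_grid <- function() {
  g <- expand.grid(dim = c(16L, 64L, 256L), scale = c(0.5, 1),
                   depth = 1:5, KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$dim, g$scale, g$depth), ]
  hidden <- lapply(seq_len(nrow(g)), function(r) {
    w <- as.integer(round(g$dim[r] * g$scale[r]^(seq_len(g$depth[r]) - 1L)))
    pmax(w, 1L)
  })
  key <- vapply(hidden, paste, "", collapse = "x")
  keep <- !duplicated(key)
  out <- tibble::tibble(config = seq_len(sum(keep)),
                        dim = g$dim[keep], scale = g$scale[keep],
                        depth = g$depth[keep], hidden = hidden[keep])
  out
}

#' Grid search over popularity-model architectures
#'
#' Trains every configuration of [pi_grid()] with a fixed seed and returns
#' the one with the smallest test MSE; ties break in enumeration order.
#'
#' @param X_train,y_train,X_test,y_test Disjoint encoded splits.
#' @param n_places Width of the place one-hot block in `X_*`.
#' @param epochs,batch_size,lr,patience Training settings (see
#'   [mlp_train()]).
#' @param seed Seed used for every configuration.
#' @return A list with `best` (row of the grid), `model` (the refitted best
#'   model), and `results` (the grid with test `mse` / `mae` columns).
#' @export
grid_search <- function(X_train, y_train, X_test, y_test, n_places,
                        epochs = 100L, batch_size = 32L, lr = 1e-3,
                        patience = 20L, seed = 1L) {
  grid <- pi_grid()
  mse <- mae <- numeric(nrow(grid))
  models <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    m <- build_pi_model(n_places, hidden = grid$hidden[[r]], seed = seed)
    m <- mlp_train(m, X_train, y_train, epochs = epochs,
                   batch_size = batch_size, lr = lr, patience = patience,
                   seed = seed)
    ev <- evaluate_model(m, X_test, y_test)
    mse[r] <- ev$mse
    mae[r] <- ev$mae
    models[[r]] <- m
  }
  grid$mse <- mse
  grid$mae <- mae
  best_r <- which.min(mse)  # first minimum wins on ties
  list(best = grid[best_r, ], model = models[[best_r]], results = grid)
}

#' Fit the community sociability predictor
#'
#' Encodes the records, splits them 70/30 into train and test sets, fits
#' the network of [build_ri_model()] with early stopping, and reports test
#' MAE and MSE.
#'
#' @param records Tibble of day-slot records with the covariate columns of
#'   [encode_ri_features()] plus the target column `ri`.
#' @param season_style Season encoding passed to [encode_ri_features()].
#' @param epochs,batch_size,lr,patience Training settings.
#' @param seed Single seed governing split, initialization, and shuffling.
#' @return A list of class `ri_predictor`: `model`, `season_style`,
#'   `metrics` (test MAE/MSE), `split`.
#' @export
train_ri_predictor <- function(records, season_style = "fuzzy",
                               epochs = 500L, batch_size = 32L, lr = 1e-3,
                               patience = 20L, seed = 1L) {
  X <- encode_ri_features(records, season_style)
  y <- records$ri
  sp <- train_test_split(nrow(X), 0.7, seed)
  model <- build_ri_model(ncol(X), seed = seed)
  model <- mlp_train(model, X[sp$train, , drop = FALSE], y[sp$train],
                     epochs = epochs, batch_size = batch_size, lr = lr,
                     patience = patience, seed = seed)
  metrics <- evaluate_model(model, X[sp$test, , drop = FALSE], y[sp$test])
  structure(list(model = model, season_style = season_style,
                 metrics = metrics, split = sp, seed = seed),
            class = "ri_predictor")
}

#' @export
predict.ri_predictor <- function(object, records, ...) {
  predict(object$model, encode_ri_features(records, object$season_style))
}

#' Fit the place-popularity predictor
#'
#' Applies the low-activity filter (PI < 0.01 removed), encodes the
#' records, splits 70/30, and either fits the default architecture of
#' [build_pi_model()] or runs the full [grid_search()].
#'
#' @param records Tibble of place-hour records with columns of
#'   [encode_pi_features()] plus the target `pi`.
#' @param place_ids Ordered encodable place ids; defaults to those present.
#' @param search Run the architecture grid search instead of the default
#'   stack.
#' @param epochs,batch_size,lr,patience,seed As in [train_ri_predictor()].
#' @return A list of class `pi_predictor`: `model`, `place_ids`, `metrics`,
#'   `split`, and `grid` when `search = TRUE`.
#' @export
train_pi_predictor <- function(records, place_ids = NULL, search = FALSE,
                               epochs = 150L, batch_size = 32L, lr = 1e-3,
                               patience = 20L, seed = 1L) {
  records <- low_activity_filter(records)
  if (nrow(records) == 0L) stop("no records above the low-activity threshold")
  if (is.null(place_ids)) place_ids <- sort(unique(records$place_id))
  X <- encode_pi_features(records, place_ids)
  y <- records$pi
  sp <- train_test_split(nrow(X), 0.7, seed)
  grid <- NULL
  if (search) {
    gs <- grid_search(X[sp$train, , drop = FALSE], y[sp$train],
                      X[sp$test, , drop = FALSE], y[sp$test],
                      n_places = length(place_ids), epochs = epochs,
                      batch_size = batch_size, lr = lr, patience = patience,
                      seed = seed)
    model <- gs$model
    grid <- gs$results
  } else {
    model <- build_pi_model(length(place_ids), seed = seed)
    model <- mlp_train(model, X[sp$train, , drop = FALSE], y[sp$train],
                       epochs = epochs, batch_size = batch_size, lr = lr,
                       patience = patience, seed = seed)
  }
  metrics <- evaluate_model(model, X[sp$test, , drop = FALSE], y[sp$test])
  structure(list(model = model, place_ids = place_ids, metrics = metrics,
                 split = sp, grid = grid, seed = seed),
            class = "pi_predictor")
}

#' @export
predict.pi_predictor <- function(object, records, ...) {
  predict(object$model, encode_pi_features(records, object$place_ids))
}

#' Save / load a fitted predictor
#'
#' Weights and metadata are serialized to a plain JSON document, so fitted
#' models can be versioned and diffed.
#'
#' @param object An `ri_predictor` or `pi_predictor`.
#' @param path Output path.
#' @export
save_predictor <- function(object, path) {
  m <- object$model
  doc <- list(
    class = class(object),
    sizes = m$sizes,
    out_train = m$out_train, out_pred = m$out_pred,
    W = lapply(m$W, unclass), b = lapply(m$b, unclass),
    embed = if (!is.null(m$embed)) {
      list(n_in = m$embed$n_in, dim = m$embed$dim, W = unclass(m$embed$W),
           b = unclass(m$embed$b))
    },
    season_style = object$season_style,
    place_ids = object$place_ids,
    metrics = object$metrics,
    seed = object$seed
  )
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_predictor
#' @export
load_predictor <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  has_embed <- length(doc$embed) > 0
  model <- mlp_new(doc$sizes, out_train = doc$out_train,
                   out_pred = doc$out_pred,
                   embed = if (has_embed)
                     list(n_in = doc$embed$n_in, dim = doc$embed$dim))
  model$W <- lapply(doc$W, as.matrix)
  model$b <- lapply(doc$b, function(x) matrix(x, nrow = 1))
  if (has_embed) {
    model$embed$W <- as.matrix(doc$embed$W)
    model$embed$b <- matrix(doc$embed$b, nrow = 1)
  }
  out <- list(model = model, season_style = doc$season_style,
              place_ids = doc$place_ids, metrics = doc$metrics,
              seed = doc$seed)
  class(out) <- doc$class[1]
  out
}
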