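# Minimal dense feed-forward regression networks.
#
# Both predictors in this package are small multilayer perceptrons trained
# with minibatch Adam on a mean-squared-error loss, with ReLU hidden
# activations and optional extras used by the place-popularity model: a
# linear embedding of the place one-hot block into a 3-dimensional latent
# space, a Leaky ReLU on the output at training time and a ReLU at
# prediction time (so inferred values are nonnegative while gradients never
# die during training).

act_fun <- function(z, kind, slope = 0.01) {
  switch(kind,
         identity = z,
         relu = pmax(z, 0),
         leaky_relu = ifelse(z > 0, z, slope * z),
         stop("unknown activation: ", kind))
}

act_grad <- function(z, kind, slope = 0.01) {
  switch(kind,
         identity = matrix(1, nrow(z), ncol(z)),
         relu = (z > 0) * 1,
         leaky_relu = ifelse(z > 0, 1, slope),
         stop("unknown activation: ", kind))
}

#' Initialize a dense feed-forward regression network
#'
#' @param sizes Integer vector of layer widths from input to output, e.g.
#'   `c(10, 128, 128, 1)`.
#' @param out_train,out_pred Output activation used during training /
#'   prediction (`"identity"`, `"relu"`, `"leaky_relu"`).
#' @param embed Optional list `list(n_in =, dim =)`: the first `n_in` input
#'   columns (a one-hot block) are first mapped linearly onto `dim` latent
#'   dimensions; `sizes[1]` must then equal `dim + (raw inputs - n_in)`.
#' @param seed Integer seed for the (He) weight initialization.
#' @return An object of class `proxisoc_mlp`.
#' @export
mlp_new <- function(sizes, out_train = "identity", out_pred = "identity",
                    embed = NULL, seed = 1L) {
  stopifnot(length(sizes) >= 2L, all(sizes >= 1L))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  he <- function(nin, nout) {
    matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  W <- b <- vector("list", length(sizes) - 1L)
  for (l in seq_along(W)) {
    W[[l]] <- he(sizes[l], sizes[l + 1L])
    b[[l]] <- matrix(0, 1, sizes[l + 1L])
  }
  if (!is.null(embed)) {
    embed$W <- he(embed$n_in, embed$dim)
    embed$b <- matrix(0, 1, embed$dim)
  }
  structure(list(sizes = as.integer(sizes), W = W, b = b,
                 out_train = out_train, out_pred = out_pred, embed = embed,
                 seed = as.integer(seed)),
            class = "proxisoc_mlp")
}

#' @export
print.proxisoc_mlp <- function(x, ...) {
  arch <- paste(x$sizes, collapse = " -> ")
  if (!is.null(x$embed)) {
    arch <- sprintf("[%d -> %d latent] + %s", x$embed$n_in, x$embed$dim, arch)
  }
  cat(sprintf("<proxisoc_mlp> %s (%d parameters)\n", arch, mlp_n_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param model A [mlp_new()] model.
#' @export
mlp_n_params <- function(model) {
  n <- sum(vapply(model$W, length, 0)) + sum(vapply(model$b, length, 0))
  if (!is.null(model$embed)) n <- n + length(model$embed$W) + length(model$embed$b)
  as.integer(n)
}

mlp_input <- function(model, X) {
  if (is.null(model$embed)) return(list(H0 = X, Xe = NULL))
  ne <- model$embed$n_in
  Xe <- X[, seq_len(ne), drop = FALSE]
  lat <- Xe %*% model$embed$W +
    matrix(model$embed$b, nrow(X), ncol(model$embed$b), byrow = TRUE)
  list(H0 = cbind(lat, X[, -seq_len(ne), drop = FALSE]), Xe = Xe)
}

mlp_forward <- function(model, X, training = FALSE) {
  inp <- mlp_input(model, X)
  L <- length(model$W)
  Z <- H <- vector("list", L)
  h <- inp$H0
  for (l in seq_len(L)) {
    Z[[l]] <- h %*% model$W[[l]] +
      matrix(model$b[[l]], nrow(h), ncol(model$b[[l]]), byrow = TRUE)
    kind <- if (l < L) "relu" else if (training) model$out_train else model$out_pred
    H[[l]] <- act_fun(Z[[l]], kind)
    h <- H[[l]]
  }
  list(pred = h, Z = Z, H = H, H0 = inp$H0, Xe = inp$Xe)
}

#' Predict from a fitted network
#'
#' Applies the prediction-time output activation; for the popularity model
#' this is a ReLU, so predictions are always nonnegative.
#'
#' @param object A `proxisoc_mlp`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.proxisoc_mlp <- function(object, X, ...) {
  as.numeric(mlp_forward(object, X, training = FALSE)$pred)
}

mlp_backward <- function(model, fw, y) {
  n <- length(y)
  L <- length(model$W)
  kind_out <- model$out_train
  dZ <- (fw$pred - y) * (2 / n) * act_grad(fw$Z[[L]], kind_out)
  gW <- gb <- vector("list", L)
  for (l in rev(seq_len(L))) {
    h_prev <- if (l == 1L) fw$H0 else fw$H[[l - 1L]]
    gW[[l]] <- crossprod(h_prev, dZ)
    gb[[l]] <- matrix(colSums(dZ), 1)
    if (l > 1L) {
      dH <- dZ %*% t(model$W[[l]])
      dZ <- dH * act_grad(fw$Z[[l - 1L]], "relu")
    } else if (!is.null(model$embed)) {
      dH0 <- dZ %*% t(model$W[[1L]])
      dLat <- dH0[, seq_len(model$embed$dim), drop = FALSE]
      gWe <- crossprod(fw$Xe, dLat)
      gbe <- matrix(colSums(dLat), 1)
      return(list(W = gW, b = gb, We = gWe, be = gbe))
    }
  }
  list(W = gW, b = gb, We = NULL, be = NULL)
}

adam_init <- function(model) {
  zero_like <- function(m) lapply(m, function(x) x * 0)
  st <- list(mW = zero_like(model$W), vW = zero_like(model$W),
             mb = zero_like(model$b), vb = zero_like(model$b), t = 0L)
  if (!is.null(model$embed)) {
    st$mWe <- model$embed$W * 0; st$vWe <- model$embed$W * 0
    st$mbe <- model$embed$b * 0; st$vbe <- model$embed$b * 0
  }
  st
}

adam_update <- function(p, g, m, v, t, lr, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g^2
  mhat <- m / (1 - b1^t)
  vhat <- v / (1 - b2^t)
  list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
}

#' Train a network with minibatch Adam and early stopping
#'
#' Minimizes the MSE on a training split, holding out `val_frac` of it as a
#' validation slice; training stops when the validation MSE has not
#' improved for `patience` epochs and the best weights are restored.
#'
#' @param model A [mlp_new()] model.
#' @param X,y Training features and targets.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param lr Adam learning rate.
#' @param val_frac Fraction of the rows held out for early stopping.
#' @param patience Epochs without validation improvement before stopping.
#' @param seed Seed governing shuffling and the validation split.
#' @return The fitted model, with a `history` attribute (per-epoch
#'   training / validation MSE).
#' @export
mlp_train <- function(model, X, y, epochs = 300L, batch_size = 32L,
                      lr = 1e-3, val_frac = 0.1, patience = 20L, seed = 1L) {
  stopifnot(nrow(X) == length(y))
  if (any(!is.finite(X)) || any(!is.finite(y))) {
    stop("non-finite values in training data")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  y <- as.numeric(y)
  n <- nrow(X)
  n_val <- max(1L, floor(val_frac * n))
  val_idx <- sample.int(n, n_val)
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y[val_idx]
  st <- adam_init(model)
  best <- list(mse = Inf, model = model)
  wait <- 0L
  hist_tr <- hist_val <- numeric(0)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(length(ytr))
    for (start in seq(1L, length(ytr), by = batch_size)) {
      bi <- ord[start:min(start + batch_size - 1L, length(ytr))]
      fw <- mlp_forward(model, Xtr[bi, , drop = FALSE], training = TRUE)
      if (any(!is.finite(fw$pred))) stop("non-finite loss during training")
      gr <- mlp_backward(model, fw, ytr[bi])
      st$t <- st$t + 1L
      for (l in seq_along(model$W)) {
        up <- adam_update(model$W[[l]], gr$W[[l]], st$mW[[l]], st$vW[[l]],
                          st$t, lr)
        model$W[[l]] <- up$p; st$mW[[l]] <- up$m; st$vW[[l]] <- up$v
        up <- adam_update(model$b[[l]], gr$b[[l]], st$mb[[l]], st$vb[[l]],
                          st$t, lr)
        model$b[[l]] <- up$p; st$mb[[l]] <- up$m; st$vb[[l]] <- up$v
      }
      if (!is.null(gr$We)) {
        up <- adam_update(model$embed$W, gr$We, st$mWe, st$vWe, st$t, lr)
        model$embed$W <- up$p; st$mWe <- up$m; st$vWe <- up$v
        up <- adam_update(model$embed$b, gr$be, st$mbe, st$vbe, st$t, lr)
        model$embed$b <- up$p; st$mbe <- up$m; st$vbe <- up$v
      }
    }
    mse_tr <- mean((predict(model, Xtr) - ytr)^2)
    mse_val <- mean((predict(model, Xval) - yval)^2)
    hist_tr <- c(hist_tr, mse_tr); hist_val <- c(hist_val, mse_val)
    if (mse_val < best$mse - 1e-12) {
      best <- list(mse = mse_val, model = model)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) break
    }
  }
  out <- best$model
  attr(out, "history") <- data.frame(epoch = seq_along(hist_tr),
                                     train_mse = hist_tr, val_mse = hist_val)
  out
}

#' Evaluate a fitted network
#'
#' @param model A fitted `proxisoc_mlp`.
#' @param X,y Held-out features and targets.
#' @return A list with elements `mae` and `mse`.
#' @export
evaluate_model <- function(model, X, y) {
  p <- predict(model, X)
  list(mae = mean(abs(p - y)), mse = mean((p - y)^2))
}

#' Split row indices into disjoint train / test sets
#'
#' @param n Number of rows.
#' @param train_frac Fraction assigned to the training set.
#' @param seed Seed for the random split.
#' @return A list with integer vectors `train` and `test`.
#' @export
train_test_split <- function(n, train_frac = 0.7, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tr <- sort(sample.int(n, floor(train_frac * n)))
  list(train = tr, test = setdiff(seq_len(n), tr))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
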