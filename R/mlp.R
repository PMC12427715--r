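#' Configuration for the feed-forward neural regressor
#'
#' The spectra-to-Qi network is a small fully connected regressor: inputs
#' are standardized per wavelength (training statistics only), the output is
#' a single linear unit on the Qi scale. All architectural choices are
#' explicit here; the defaults are one hidden layer of 32 tanh units trained
#' with mini-batch Adam (adaptive moment estimation) under early stopping on
#' a replicate-disjoint validation split.
#'
#' @param hidden_layer_sizes Integer vector of hidden widths, all `>= 1`.
#' @param activation `"tanh"` or `"relu"`.
#' @param max_epochs Maximum training epochs.
#' @param learning_rate Adam step size, `> 0`.
#' @param batch_size Mini-batch size (capped at the training size).
#' @param early_stopping_patience Epochs without validation improvement
#'   before stopping.
#' @param seed Integer seed; initialization and batch order are fully
#'   reproducible under it.
#' @return An `mlp_config` list.
#' @export
mlp_config <- function(hidden_layer_sizes = 32, activation = c("tanh", "relu"),
                       max_epochs = 600, learning_rate = 0.01,
                       batch_size = 64, early_stopping_patience = 50,
                       seed = 1) {
  activation <- match.arg(activation)
  if (length(hidden_layer_sizes) == 0 || any(hidden_layer_sizes < 1)) {
    abort("every hidden layer must have >= 1 unit")
  }
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (max_epochs < 1 || batch_size < 1 || early_stopping_patience < 1) {
    abort("max_epochs, batch_size and early_stopping_patience must be >= 1")
  }
  structure(list(
    hidden_layer_sizes = as.integer(hidden_layer_sizes),
    activation = activation,
    max_epochs = as.integer(max_epochs),
    learning_rate = learning_rate,
    batch_size = as.integer(batch_size),
    early_stopping_patience = as.integer(early_stopping_patience),
    seed = as.integer(seed)
  ), class = "mlp_config")
}

act_fun <- function(name) {
  switch(name,
         tanh = list(f = tanh, df = function(a) 1 - a^2),
         relu = list(f = function(z) pmax(z, 0), df = function(a) (a > 0) * 1))
}

mlp_forward <- function(weights, biases, X, act) {
  activations <- list(X)
  L <- length(weights)
  for (l in seq_len(L)) {
    z <- sweep(activations[[l]] %*% weights[[l]], 2, biases[[l]], `+`)
    activations[[l + 1]] <- if (l < L) act$f(z) else z
  }
  activations
}

#' Fit the spectra-to-Qi neural regressor
#'
#' Minimizes mean squared error by mini-batch gradient descent with
#' adaptive moment estimation (Adam). Training stops when the validation
#' loss has not improved for `early_stopping_patience` epochs, and the
#' best-validation weights are restored before returning. The validation
#' rows must be replicate-disjoint from the training rows (the caller's
#' split guarantees this in the pipeline).
#'
#' @param X_train,y_train Training predictors and Qi response (`y` in
#'   `[0, 1]`).
#' @param X_val,y_val Validation predictors and response used for early
#'   stopping.
#' @param config An [mlp_config()].
#' @return An `mlp_model`: weights, biases, input standardization vectors,
#'   per-epoch `history` tibble (`epoch`, `train_loss`, `val_loss`),
#'   `best_epoch` and the config.
#' @export
mlp_fit <- function(X_train, y_train, X_val, y_val, config = mlp_config()) {
  if (!inherits(config, "mlp_config")) abort("`config` must be an mlp_config")
  X_train <- as.matrix(X_train); X_val <- as.matrix(X_val)
  y_train <- as.numeric(y_train); y_val <- as.numeric(y_val)
  if (nrow(X_train) != length(y_train)) abort("X_train and y_train sizes differ")
  if (nrow(X_val) != length(y_val)) abort("X_val and y_val sizes differ")
  if (ncol(X_val) != ncol(X_train)) abort("validation width differs from training width")
  if (any(y_train < 0 | y_train > 1)) abort("y_train must lie in [0, 1] (Qi scale)")

  x_center <- colMeans(X_train)
  x_scale <- apply(X_train, 2, sd)
  x_scale[x_scale == 0] <- 1
  Xs <- sweep(sweep(X_train, 2, x_center), 2, x_scale, `/`)
  Xvs <- sweep(sweep(X_val, 2, x_center), 2, x_scale, `/`)

  sizes <- c(ncol(Xs), config$hidden_layer_sizes, 1L)
  L <- length(sizes) - 1
  act <- act_fun(config$activation)

  set.seed(config$seed)
  weights <- biases <- mw <- vw <- mb <- vb <- vector("list", L)
  for (l in seq_len(L)) {
    weights[[l]] <- matrix(rnorm(sizes[l] * sizes[l + 1], sd = sqrt(1 / sizes[l])),
                           sizes[l], sizes[l + 1])
    biases[[l]] <- rep(0, sizes[l + 1])
    mw[[l]] <- vw[[l]] <- matrix(0, sizes[l], sizes[l + 1])
    mb[[l]] <- vb[[l]] <- rep(0, sizes[l + 1])
  }

  n <- nrow(Xs)
  bs <- min(config$batch_size, n)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0
  best_val <- Inf; best_epoch <- 0L
  best_w <- weights; best_b <- biases
  history <- vector("list", config$max_epochs)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    idx <- sample(n)
    starts <- seq(1, n, by = bs)
    for (s in starts) {
      rows <- idx[s:min(s + bs - 1, n)]
      acts <- mlp_forward(weights, biases, Xs[rows, , drop = FALSE], act)
      delta <- 2 * (acts[[L + 1]] - y_train[rows]) / length(rows)
      for (l in rev(seq_len(L))) {
        gw <- crossprod(acts[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          delta <- (delta %*% t(weights[[l]])) * act$df(acts[[l]])
        }
        step_l <- step + 1  # shared timestep per batch
        mw[[l]] <- beta1 * mw[[l]] + (1 - beta1) * gw
        vw[[l]] <- beta2 * vw[[l]] + (1 - beta2) * gw^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhat_w <- mw[[l]] / (1 - beta1^step_l)
        vhat_w <- vw[[l]] / (1 - beta2^step_l)
        mhat_b <- mb[[l]] / (1 - beta1^step_l)
        vhat_b <- vb[[l]] / (1 - beta2^step_l)
        weights[[l]] <- weights[[l]] - config$learning_rate * mhat_w / (sqrt(vhat_w) + eps)
        biases[[l]] <- biases[[l]] - config$learning_rate * mhat_b / (sqrt(vhat_b) + eps)
      }
      step <- step + 1
    }
    train_loss <- mean((drop(mlp_forward(weights, biases, Xs, act)[[L + 1]]) - y_train)^2)
    val_loss <- mean((drop(mlp_forward(weights, biases, Xvs, act)[[L + 1]]) - y_val)^2)
    if (!is.finite(train_loss) || !is.finite(val_loss)) {
      abort("training diverged (non-finite loss); try a smaller learning_rate")
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_loss = train_loss,
                                       val_loss = val_loss)
    if (val_loss < best_val) {
      best_val <- val_loss; best_epoch <- epoch
      best_w <- weights; best_b <- biases
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$early_stopping_patience) break
    }
  }

  structure(list(
    weights = best_w, biases = best_b,
    x_center = x_center, x_scale = x_scale,
    activation = config$activation,
    history = dplyr::bind_rows(history),
    best_epoch = best_epoch, best_val_loss = best_val,
    config = config
  ), class = "mlp_model")
}

#' Predict from the neural regressor
#'
#' Deterministic forward pass through the stored best-validation weights.
#' Predictions are clipped to `[0, 1]` by default (Qi is defined on that
#' range).
#'
#' @param object An `mlp_model`.
#' @param X New predictor matrix on the training wavelength grid.
#' @param clip Clip predictions into `[0, 1]` (default `TRUE`).
#' @param ... Unused.
#' @return Numeric vector of predicted Qi.
#' @export
predict.mlp_model <- function(object, X, clip = TRUE, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_center)) {
    abort("predictor width does not match the training grid")
  }
  Xs <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, `/`)
  act <- act_fun(object$activation)
  yhat <- drop(mlp_forward(object$weights, object$biases, Xs, act)[[length(object$weights) + 1]])
  if (clip) yhat <- pmin(pmax(yhat, 0), 1)
  yhat
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Feed-forward Qi regressor: %s hidden units (%s), best epoch %d (val MSE %.3g)\n",
              paste(x$config$hidden_layer_sizes, collapse = "-"),
              x$activation, x$best_epoch, x$best_val_loss))
  invisible(x)
}

#' @export
glance.mlp_model <- function(x, ...) {
  tibble::tibble(best_epoch = x$best_epoch, best_val_loss = x$best_val_loss,
                 epochs_run = nrow(x$history),
                 hidden = paste(x$config$hidden_layer_sizes, collapse = "-"))
}

#' Training-history plot for the neural regressor
#'
#' @param object An `mlp_model`.
#' @param ... Unused.
#' @return A ggplot object showing train and validation loss per epoch.
#' @export
autoplot.mlp_model <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, c("train_loss", "val_loss"),
                              names_to = "series", values_to = "mse")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$mse,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "MSE", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Serialize / restore the neural regressor
#'
#' Weights, standardization vectors, config and training history are written
#' as JSON so a trained model can be versioned and reloaded without any
#' binary artifact.
#'
#' @param model An `mlp_model`.
#' @param path JSON file path.
#' @return `write_mlp_model()` returns `path` invisibly; `read_mlp_model()`
#'   the restored model.
#' @export
write_mlp_model <- function(model, path) {
  payload <- list(
    weights = lapply(model$weights, unclass),
    biases = model$biases,
    x_center = model$x_center, x_scale = model$x_scale,
    activation = model$activation,
    best_epoch = model$best_epoch, best_val_loss = model$best_val_loss,
    history = as.data.frame(model$history),
    config = unclass(model$config)
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_mlp_model
#' @export
read_mlp_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- do.call(mlp_config, p$config)
  structure(list(
    weights = lapply(p$weights, as.matrix),
    biases = if (is.list(p$biases)) p$biases else list(p$biases),
    x_center = p$x_center, x_scale = p$x_scale,
    activation = p$activation,
    history = tibble::as_tibble(p$history),
    best_epoch = p$best_epoch, best_val_loss = p$best_val_loss,
    config = cfg
  ), class = "mlp_model")
}
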