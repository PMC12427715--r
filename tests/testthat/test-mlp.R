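fast_config <- function(...) {
  args <- utils::modifyList(
    list(hidden_layer_sizes = 8, max_epochs = 800, batch_size = 16,
         early_stopping_patience = 60, seed = 5),
    list(...))
  do.call(mlp_config, args)
}

linear_problem <- function(n = 120, p = 4, sd_noise = 0, seed = 51) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  lin <- drop(X %*% c(0.1, -0.08, 0.05, 0.02))
  y <- 0.5 + lin + rnorm(n, 0, sd_noise)
  y <- pmin(pmax(y, 0), 1)
  tr <- 1:(0.75 * n)
  list(X_train = X[tr, ], y_train = y[tr],
       X_val = X[-tr, ], y_val = y[-tr])
}

test_that("the network learns a linear target to high R-squared", {
  d <- linear_problem()
  model <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val, fast_config())
  yhat <- predict(model, d$X_val, clip = FALSE)
  r2 <- 1 - sum((d$y_val - yhat)^2) / sum((d$y_val - mean(d$y_val))^2)
  expect_gt(r2, 0.99)
  expect_lte(model$best_epoch, nrow(model$history))
  # history tracks both losses and best epoch attains the recorded minimum
  expect_equal(min(model$history$val_loss), model$best_val_loss)
  expect_equal(model$history$val_loss[model$best_epoch], model$best_val_loss)
})

test_that("configuration and input validation reject bad values", {
  expect_error(mlp_config(hidden_layer_sizes = 0), ">= 1")
  expect_error(mlp_config(learning_rate = -1), "> 0")
  expect_error(mlp_config(max_epochs = 0), ">= 1")
  expect_error(mlp_config(activation = "sigmoid"), "should be one of")
  d <- linear_problem(n = 20)
  expect_error(mlp_fit(d$X_train, d$y_train[-1], d$X_val, d$y_val, fast_config()),
               "sizes differ")
  expect_error(mlp_fit(d$X_train, d$y_train + 5, d$X_val, d$y_val, fast_config()),
               "\\[0, 1\\]")
  expect_error(mlp_fit(d$X_train, d$y_train, d$X_val[, 1:2], d$y_val,
                       fast_config()), "width")
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(max_epochs = 5))
  expect_error(predict(m, d$X_val[, 1:2]), "width")
})

test_that("training is bit-identical under a fixed seed", {
  d <- linear_problem(n = 60)
  cfg <- fast_config(max_epochs = 40)
  m1 <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val, cfg)
  m2 <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val, cfg)
  expect_identical(m1$weights, m2$weights)
  expect_identical(predict(m1, d$X_val), predict(m2, d$X_val))
  m3 <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
                fast_config(max_epochs = 40, seed = 99))
  expect_false(identical(m1$weights, m3$weights))
})

test_that("zeroed weights give a constant output equal to the output bias", {
  d <- linear_problem(n = 40)
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(max_epochs = 3))
  m$weights <- lapply(m$weights, function(w) w * 0)
  m$biases <- lapply(m$biases, function(b) b * 0)
  m$biases[[length(m$biases)]] <- 0.42
  expect_equal(predict(m, d$X_val), rep(0.42, nrow(d$X_val)))
})

test_that("the forward pass is equivariant to input-column permutation", {
  d <- linear_problem(n = 60)
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(max_epochs = 20))
  perm <- c(3, 1, 4, 2)
  mp <- m
  mp$weights[[1]] <- m$weights[[1]][perm, , drop = FALSE]
  mp$x_center <- m$x_center[perm]
  mp$x_scale <- m$x_scale[perm]
  expect_equal(predict(mp, d$X_val[, perm]), predict(m, d$X_val),
               tolerance = 1e-12)
})

test_that("predictions are clipped to the Qi range only when asked", {
  d <- linear_problem(n = 60)
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(max_epochs = 3))
  m$biases[[length(m$biases)]] <- 50   # force out-of-range raw output
  expect_true(all(predict(m, d$X_val) <= 1))
  expect_true(all(predict(m, d$X_val, clip = FALSE) > 1))
})

test_that("a model round-trips through JSON with identical predictions", {
  d <- linear_problem(n = 60)
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(max_epochs = 30))
  path <- withr::local_tempfile(fileext = ".json")
  write_mlp_model(m, path)
  r <- read_mlp_model(path)
  expect_equal(predict(r, d$X_val), predict(m, d$X_val), tolerance = 1e-12)
  expect_equal(r$best_epoch, m$best_epoch)
  expect_equal(r$config$hidden_layer_sizes, m$config$hidden_layer_sizes)
  expect_equal(nrow(r$history), nrow(m$history))
})

test_that("relu activation also trains, and tidier/plot accessors work", {
  d <- linear_problem()
  m <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val,
               fast_config(activation = "relu"))
  yhat <- predict(m, d$X_val, clip = FALSE)
  r2 <- 1 - sum((d$y_val - yhat)^2) / sum((d$y_val - mean(d$y_val))^2)
  expect_gt(r2, 0.95)
  gl <- glance(m)
  expect_named(gl, c("best_epoch", "best_val_loss", "epochs_run", "hidden"))
  expect_s3_class(autoplot(m), "ggplot")
  expect_output(print(m), "Feed-forward")
})

test_that("on a noisy linear generator the network approaches the PLSR error", {
  d <- linear_problem(n = 200, sd_noise = 0.02, seed = 53)
  set.seed(54)
  X_new <- matrix(rnorm(50 * 4), 50, 4)
  y_new <- 0.5 + drop(X_new %*% c(0.1, -0.08, 0.05, 0.02)) +
    rnorm(50, 0, 0.02)
  pls <- plsr_fit(d$X_train, d$y_train, n_components = 4)
  nn <- mlp_fit(d$X_train, d$y_train, d$X_val, d$y_val, fast_config())
  rmse <- function(y, yhat) sqrt(mean((y - yhat)^2))
  rmse_pls <- rmse(y_new, predict(pls, X_new))
  rmse_nn <- rmse(y_new, predict(nn, X_new, clip = FALSE))
  expect_lt(rmse_nn, 1.5 * rmse_pls)
})
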