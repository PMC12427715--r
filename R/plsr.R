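#' NIPALS partial least squares regression
#'
#' Fits a single-response PLSR model by NIPALS deflation: latent variables
#' (orthogonal score vectors) are extracted sequentially in the directions
#' of maximal X-y covariance. Predictors and response are mean-centred, with
#' no variance scaling (all predictors share the absorbance-derivative
#' scale). The inner weight iteration stops when the weight vector changes
#' by less than `tol` or after `max_iter` iterations.
#'
#' @param X Numeric predictor matrix (samples x wavelengths). Column names
#'   are retained and checked at prediction time.
#' @param y Numeric response vector.
#' @param n_components Number of latent variables, at most
#'   `min(nrow(X) - 1, ncol(X))`.
#' @param tol,max_iter Inner NIPALS convergence controls.
#' @return A `plsr_model`: centring vectors, per-component weights `W`,
#'   X-loadings `P`, y-loadings `q`, scores `T` (training), and the
#'   regression coefficient vector at `n_components`.
#' @export
plsr_fit <- function(X, y, n_components, tol = 1e-10, max_iter = 500) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) abort("X and y sizes differ")
  if (sd(y) == 0) abort("degenerate response: y has zero variance")
  a_max <- min(nrow(X) - 1, ncol(X))
  if (n_components < 1 || n_components > a_max) {
    abort(sprintf("n_components must be in [1, %d]", a_max))
  }

  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean

  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  Tm <- matrix(0, nrow(X), n_components)
  q <- numeric(n_components)

  for (a in seq_len(n_components)) {
    u <- yc
    w_old <- rep(0, p)
    for (iter in seq_len(max_iter)) {
      w <- drop(crossprod(Xc, u)) / drop(crossprod(u))
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) abort("NIPALS collapsed: zero weight vector (X deflated to noise)")
      w <- w / nw
      t_score <- drop(Xc %*% w)
      qa <- drop(crossprod(yc, t_score)) / drop(crossprod(t_score))
      u <- yc * qa
      if (sqrt(sum((w - w_old)^2)) < tol) break
      w_old <- w
    }
    p_load <- drop(crossprod(Xc, t_score)) / drop(crossprod(t_score))
    Xc <- Xc - tcrossprod(t_score, p_load)
    yc <- yc - qa * t_score
    W[, a] <- w
    P[, a] <- p_load
    Tm[, a] <- t_score
    q[a] <- qa
  }

  structure(list(
    n_components = n_components,
    x_mean = x_mean, y_mean = y_mean,
    weights = W, x_loadings = P, y_loadings = q, scores = Tm,
    coefficients = plsr_coefficients(W, P, q, n_components),
    wavelengths = colnames(X)
  ), class = "plsr_model")
}

# Regression coefficients at `a` components: B = W_a (P_a' W_a)^-1 q_a
plsr_coefficients <- function(W, P, q, a) {
  Wa <- W[, seq_len(a), drop = FALSE]
  Pa <- P[, seq_len(a), drop = FALSE]
  drop(Wa %*% solve(crossprod(Pa, Wa), q[seq_len(a)]))
}

#' Predict from a PLSR model
#'
#' \eqn{\hat y = (X - \bar x) B + \bar y}. The predictor columns must match
#' the training wavelength grid.
#'
#' @param object A `plsr_model`.
#' @param X New predictor matrix.
#' @param n_components Optional reduced component count (defaults to the
#'   fitted count).
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.plsr_model <- function(object, X, n_components = object$n_components, ...) {
  X <- as.matrix(X)
  if (ncol(X) != length(object$x_mean)) {
    abort("predictor width does not match the training grid")
  }
  if (!is.null(object$wavelengths) && !is.null(colnames(X)) &&
      !identical(colnames(X), object$wavelengths)) {
    abort("predictor wavelength grid does not match the training grid")
  }
  B <- if (n_components == object$n_components) object$coefficients else
    plsr_coefficients(object$weights, object$x_loadings, object$y_loadings,
                      n_components)
  drop(sweep(X, 2, object$x_mean) %*% B) + object$y_mean
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("NIPALS PLSR model: %d latent variable(s), %d predictor(s)\n",
              x$n_components, length(x$x_mean)))
  invisible(x)
}

#' @export
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(
    wavelength = x$wavelengths %||% paste0("x", seq_along(x$coefficients)),
    coefficient = x$coefficients
  )
}

#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(n_components = x$n_components,
                 n_predictors = length(x$x_mean))
}

#' Grouped cross-validation for latent-variable selection
#'
#' Splits replicate groups across `k_folds` folds (seeded shuffle,
#' round-robin assignment so fold sizes stay balanced), fits PLSR with up to
#' `max_components` latent variables on each training complement, and scores
#' every component count on the held-out fold. The selected component count
#' minimizes RMSECV; exact ties break toward fewer components. An optional
#' one-standard-error rule instead picks the smallest count whose RMSECV is
#' within one SE (across folds) of the minimum.
#'
#' @param X,y Training predictors and response.
#' @param groups Replicate-group IDs, one per row of `X`; all rows of a
#'   group land in one fold. With `k_folds` equal to the number of singleton
#'   groups this reduces to leave-one-out.
#' @param max_components Largest component count to score.
#' @param k_folds Number of folds (default 10).
#' @param seed Shuffle seed.
#' @param one_se Use the one-standard-error rule (default `FALSE`).
#' @return A list: `per_component` tibble (`n_components`, `rmsecv`),
#'   `selected`, `predictions_cv` (cross-validated predictions at the
#'   selected count), and `folds`.
#' @export
cross_validate_lv <- function(X, y, groups, max_components, k_folds = 10,
                              seed = 1, one_se = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(groups) != n) abort("`groups` must have one entry per row of X")
  if (k_folds < 2) abort("k_folds must be >= 2")
  ug <- unique(as.character(groups))
  if (length(ug) < k_folds) {
    abort(sprintf("fewer replicate groups (%d) than folds (%d)", length(ug), k_folds))
  }
  set.seed(seed)
  ug <- sample(ug)
  fold_of_group <- setNames(rep(seq_len(k_folds), length.out = length(ug)), ug)
  fold <- unname(fold_of_group[as.character(groups)])

  sq_err <- matrix(NA_real_, n, max_components)
  fold_rmse <- matrix(NA_real_, k_folds, max_components)
  pred_all <- matrix(NA_real_, n, max_components)
  for (f in seq_len(k_folds)) {
    hold <- fold == f
    a_max <- min(max_components, sum(!hold) - 1, ncol(X))
    model <- plsr_fit(X[!hold, , drop = FALSE], y[!hold], n_components = a_max)
    for (a in seq_len(a_max)) {
      pr <- predict(model, X[hold, , drop = FALSE], n_components = a)
      pred_all[hold, a] <- pr
      sq_err[hold, a] <- (y[hold] - pr)^2
      fold_rmse[f, a] <- sqrt(mean(sq_err[hold, a]))
    }
  }
  rmsecv <- sqrt(colMeans(sq_err))
  selected <- which.min(rmsecv)   # first minimum = fewest components on ties
  if (one_se) {
    se <- apply(fold_rmse, 2, function(v) sd(v, na.rm = TRUE)) / sqrt(k_folds)
    within <- which(rmsecv <= rmsecv[selected] + se[selected])
    selected <- min(within)
  }
  list(
    per_component = tibble::tibble(n_components = seq_len(max_components),
                                   rmsecv = rmsecv),
    selected = as.integer(selected),
    predictions_cv = pred_all[, selected],
    folds = fold
  )
}
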