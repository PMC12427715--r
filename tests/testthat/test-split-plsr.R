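singleton_df <- function(n) {
  tibble::tibble(sample_id = sprintf("s%05d", seq_len(n)),
                 replicate_group_id = sprintf("s%05d", seq_len(n)))
}

test_that("70/20/10 split sizes are exact for singleton groups", {
  plan <- split_dataset(singleton_df(15000), seed = 42)
  expect_length(plan$train_ids, 10500)
  expect_length(plan$test_ids, 3000)
  expect_length(plan$validation_ids, 1500)
  expect_setequal(c(plan$train_ids, plan$test_ids, plan$validation_ids),
                  sprintf("s%05d", 1:15000))

  # non-divisible n: largest-remainder targets still partition n
  plan2 <- split_dataset(singleton_df(101), seed = 1)
  sizes <- lengths(plan2[c("train_ids", "test_ids", "validation_ids")])
  expect_equal(sum(sizes), 101)
  expect_true(all(abs(sizes - 101 * c(0.7, 0.2, 0.1)) < 1))
})

test_that("replicate groups are never separated, across many seeds", {
  df <- tibble::tibble(
    sample_id = sprintf("s%03d", 1:120),
    replicate_group_id = rep(sprintf("g%02d", 1:40), each = 3))
  for (seed in 1:100) {
    plan <- split_dataset(df, seed = seed)
    per_group <- tapply(plan$assignments$subset,
                        plan$assignments$replicate_group_id,
                        function(s) length(unique(s)))
    expect_true(all(per_group == 1))
  }
})

test_that("split is deterministic in the seed and validates its inputs", {
  df <- singleton_df(50)
  expect_identical(split_dataset(df, seed = 7), split_dataset(df, seed = 7))
  expect_false(identical(split_dataset(df, seed = 7)$train_ids,
                         split_dataset(df, seed = 8)$train_ids))
  expect_error(split_dataset(df, fractions = c(train = 0.7, test = 0.4,
                                               validation = 0.1)), "sum to 1")
  expect_error(split_dataset(dplyr::mutate(df, sample_id = "dup")), "unique")
  # a group bigger than the smallest partition target cannot be placed
  big <- tibble::tibble(sample_id = sprintf("s%02d", 1:20),
                        replicate_group_id = c(rep("g1", 10), sprintf("h%02d", 1:10)))
  expect_error(split_dataset(big), "infeasible")
})

test_that("full-rank NIPALS PLSR equals the OLS oracle", {
  set.seed(31)
  n <- 20; p <- 5
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  beta <- c(2, -1, 0.5, 0, 3)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.1)
  model <- plsr_fit(X, y, n_components = p)
  ols <- lm(y ~ X)
  expect_equal(unname(model$coefficients), unname(coef(ols)[-1]), tolerance = 1e-6)
  expect_equal(predict(model, X), unname(fitted(ols)), tolerance = 1e-6)
})

test_that("PLSR scores are mutually orthogonal", {
  set.seed(32)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- rnorm(30)
  model <- plsr_fit(X, y, n_components = 5)
  G <- crossprod(model$scores)
  off_diag <- G - diag(diag(G))
  expect_lt(max(abs(off_diag)), 1e-8)
})

test_that("a single informative column yields the closed-form one-LV solution", {
  set.seed(33)
  n <- 25
  x <- rnorm(n)
  X <- cbind(signal = x, dead1 = 0 * x, dead2 = 0 * x)
  # a zero column makes NIPALS weights trivially concentrate on `signal`
  X[, 2:3] <- 1e-14 * matrix(rnorm(2 * n), n)
  y <- 3 * x + 5
  model <- plsr_fit(X, y, n_components = 1)
  expect_equal(unname(model$coefficients[1]), 3, tolerance = 1e-6)
  expect_equal(predict(model, X), y, tolerance = 1e-6)
})

test_that("grouped CV with singleton groups reproduces the brute-force LOO oracle", {
  set.seed(34)
  n <- 12; p <- 4
  X <- matrix(rnorm(n * p), n, p)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + rnorm(n, 0, 0.05)
  cv <- cross_validate_lv(X, y, groups = as.character(1:n),
                          max_components = 3, k_folds = n, seed = 2)
  for (a in 1:3) {
    expect_equal(cv$per_component$rmsecv[a], loo_rmsecv_oracle(X, y, a),
                 tolerance = 1e-10)
  }
})

test_that("CV selects the generating rank on noiseless rank-2 data", {
  set.seed(35)
  n <- 40; p <- 10
  scores <- matrix(rnorm(n * 2), n, 2)
  loadings <- matrix(rnorm(2 * p), 2, p)
  X <- scores %*% loadings
  y <- drop(scores %*% c(1.5, -2))
  cv <- cross_validate_lv(X, y, groups = as.character(1:n),
                          max_components = 5, k_folds = 5, seed = 3)
  expect_equal(cv$selected, 2L)
  expect_lt(cv$per_component$rmsecv[2], 1e-8)
})

test_that("LV selection recovers the generating rank in >= 95 of 100 noisy runs", {
  hits <- vapply(1:100, function(r) {
    set.seed(1000 + r)
    n <- 60; p <- 12; rank <- 3
    scores <- matrix(rnorm(n * rank), n, rank)
    loadings <- matrix(rnorm(rank * p), rank, p)
    X <- scores %*% loadings + matrix(rnorm(n * p, 0, 0.01), n, p)
    y <- drop(scores %*% c(2, -1.5, 1)) + rnorm(n, 0, 0.01)
    # one-SE rule guards against spending a component on noise
    cv <- cross_validate_lv(X, y, groups = as.character(1:n),
                            max_components = 6, k_folds = 5, seed = r,
                            one_se = TRUE)
    cv$selected == rank
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("PLSR and CV guard against misuse", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(plsr_fit(X, rep(1, 10), 1), "zero variance")
  expect_error(plsr_fit(X, rnorm(10), 5), "n_components")
  m <- plsr_fit(X, rnorm(10), 2)
  expect_error(predict(m, matrix(0, 2, 3)), "width")
  expect_error(cross_validate_lv(X, rnorm(10), groups = as.character(1:10),
                                 max_components = 2, k_folds = 1), ">= 2")
  expect_error(cross_validate_lv(X, rnorm(10), groups = rep("g", 10),
                                 max_components = 2, k_folds = 5), "fewer")
})
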