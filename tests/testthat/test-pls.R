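test_that("an exact rank-1 latent relation is learned with one component", {
  # X and Y driven by one shared latent score: one component suffices
  set.seed(11)
  t0 <- rnorm(10)
  X <- outer(t0, rnorm(4))
  Y <- outer(t0, rnorm(2))
  fit <- fit_pls2(X, Y, A = 1)
  resid <- predict(fit, X) - Y
  expect_lt(norm(resid, "F"), 1e-8 * norm(Y, "F"))
  # a rank-1 coefficient map through full-rank X needs the full rank
  X2 <- matrix(rnorm(10 * 4), 10, 4)
  Y2 <- X2 %*% outer(rnorm(4), rnorm(2))
  fit2 <- fit_pls2(X2, Y2, A = 4)
  expect_lt(norm(predict(fit2, X2) - Y2, "F"), 1e-8 * norm(Y2, "F"))
})

test_that("full-rank PLS2 predictions match the least-squares oracle", {
  # oracle: minimum-norm least squares through the QR of [1 | X]
  for (seed in 1:25) {
    set.seed(seed)
    X <- matrix(rnorm(8 * 5), 8, 5)
    Y <- matrix(rnorm(8 * 3), 8, 3)
    fit <- fit_pls2(X, Y, A = 5)
    ols <- qr.fitted(qr(cbind(1, X)), Y)
    expect_lt(max(abs(predict(fit, X) - ols)),
              1e-6 * max(abs(Y)), label = paste("seed", seed))
  }
})

test_that("training Y-residual norm is non-increasing in A", {
  set.seed(3)
  X <- matrix(rnorm(20 * 12), 20, 12)
  Y <- X %*% matrix(rnorm(12 * 6), 12, 6) + matrix(rnorm(20 * 6), 20, 6)
  fits <- lapply(1:8, function(a) fit_pls2(X, Y, a))
  fnorm <- vapply(fits, function(f) norm(predict(f, X) - Y, "F"), 0)
  expect_true(all(diff(fnorm) <= 1e-10))
})

test_that("X-score columns are orthogonal", {
  set.seed(5)
  X <- matrix(rnorm(15 * 10), 15, 10)
  Y <- matrix(rnorm(15 * 4), 15, 4)
  fit <- fit_pls2(X, Y, A = 6)
  G <- crossprod(fit$scores)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)), 1e-8 * max(diag(G)))
})

test_that("shifting Y changes only the intercept; scaling Y scales B and b0", {
  set.seed(6)
  X <- matrix(rnorm(12 * 7), 12, 7)
  Y <- matrix(rnorm(12 * 3), 12, 3)
  fit <- fit_pls2(X, Y, A = 4)
  shift <- c(2, -1, 0.5)
  fit_sh <- fit_pls2(X, sweep(Y, 2, shift, `+`), A = 4)
  expect_equal(fit_sh$coefficients, fit$coefficients, tolerance = 1e-8)
  expect_equal(fit_sh$b0, fit$b0 + shift, tolerance = 1e-8)
  fit_sc <- fit_pls2(X, 3 * Y, A = 4)
  expect_equal(fit_sc$coefficients, 3 * fit$coefficients,
               tolerance = 1e-8)
  expect_equal(fit_sc$b0, 3 * fit$b0, tolerance = 1e-8)
})

test_that("prediction identities hold", {
  set.seed(7)
  X <- matrix(rnorm(10 * 6), 10, 6)
  Y <- matrix(rnorm(10 * 2), 10, 2)
  fit <- fit_pls2(X, Y, A = 3)
  # centering identity: the training X mean predicts the training Y mean
  expect_equal(as.numeric(predict(fit, fit$x_mean)), fit$y_mean,
               tolerance = 1e-10)
  # B_tilde structure: row 0 is b0, the rest is B
  expect_equal(fit$B_tilde[1, ], fit$b0)
  expect_equal(fit$B_tilde[-1, ], fit$coefficients)
  expect_equal(fit$b0,
               as.numeric(fit$y_mean - crossprod(fit$coefficients,
                                                 fit$x_mean)),
               tolerance = 1e-10)
  # internal consistency: predictions on X_train equal scores x loadings
  fitted_sl <- fit$scores %*% t(fit$y_loadings) +
    matrix(fit$y_mean, 10, 2, byrow = TRUE)
  expect_equal(predict(fit, X), fitted_sl, tolerance = 1e-8,
               ignore_attr = TRUE)
  # intercept-only model
  m0 <- structure(list(x_mean = rep(0, 6), y_mean = c(1, 2),
                       B_tilde = rbind(c(1, 2), matrix(0, 6, 2))),
                  class = "pls_model")
  expect_equal(predict(m0, X), matrix(c(1, 2), 10, 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(predict(fit, matrix(0, 2, 5)), "columns")
})

test_that("degenerate predictors are handled loudly, never as NaN", {
  set.seed(8)
  X <- cbind(matrix(rnorm(10 * 4), 10, 4), 7)  # constant fifth column
  Y <- matrix(rnorm(10 * 2), 10, 2)
  expect_warning(fit <- fit_pls2(X, Y, A = 3), "zero-variance")
  expect_true(all(is.finite(predict(fit, X))))
  expect_equal(fit$coefficients[5, ], c(0, 0))
  expect_error(fit_pls2(matrix(1, 6, 3), Y[1:6, ], A = 1),
               "zero variance")
  expect_error(fit_pls2(X, Y, A = 20), "A must satisfy")
})

test_that("NIPALS agrees with SIMPLS for a single response", {
  for (seed in 1:10) {
    set.seed(seed)
    X <- matrix(rnorm(14 * 9), 14, 9)
    y <- X %*% rnorm(9) + rnorm(14)
    a <- sample(1:5, 1)
    f1 <- fit_pls2(X, y, a, algorithm = "simpls")
    f2 <- fit_pls2(X, y, a, algorithm = "nipals")
    expect_equal(predict(f1, X), predict(f2, X), tolerance = 1e-8)
  }
})

test_that("grouped CV identifies an exact latent rank and never splits subjects", {
  set.seed(9)
  n_subj <- 10
  T0 <- matrix(rnorm(3 * n_subj * 2), 3 * n_subj, 2)
  X <- T0 %*% matrix(rnorm(2 * 10), 2, 10)
  Y <- T0 %*% matrix(rnorm(2 * 4), 2, 4)
  groups <- rep(paste0("s", 1:n_subj), each = 3)
  # candidate ranks above the true rank trigger the early-termination
  # guard, which warns by design
  sel <- suppressWarnings(
    select_components(X, Y, groups, ranks = 1:5, k_folds = 5))
  expect_equal(sel$chosen, 2)  # rank 2 is exact; ties break downward
  # fold structure: every subject sits in exactly one fold
  expect_setequal(names(sel$folds), unique(groups))
  expect_true(all(table(sel$folds) >= 1))
})

test_that("duplicate rank candidates are evaluated once", {
  set.seed(10)
  X <- matrix(rnorm(24 * 6), 24, 6)
  Y <- matrix(rnorm(24 * 2), 24, 2)
  groups <- rep(paste0("s", 1:8), each = 3)
  s1 <- select_components(X, Y, groups, ranks = c(3, 3, 5), k_folds = 4)
  s2 <- select_components(X, Y, groups, ranks = c(3, 5), k_folds = 4)
  expect_identical(s1$ranks, s2$ranks)
  expect_identical(s1$cv_rmse, s2$cv_rmse)
  expect_identical(s1$chosen, s2$chosen)
  expect_error(select_components(X, Y, groups, 1:2, k_folds = 9),
               "fewer distinct subjects")
})

test_that("a fitted model survives JSON serialization", {
  set.seed(12)
  X <- matrix(rnorm(10 * 6), 10, 6)
  Y <- matrix(rnorm(10 * 3), 10, 3)
  fit <- fit_pls2(X, Y, A = 4)
  path <- withr::local_tempfile(fileext = ".json")
  save_pls_model(fit, path)
  back <- load_pls_model(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
})
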