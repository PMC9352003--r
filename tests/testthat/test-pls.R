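test_that("PLS fits an exact low-rank linear system to machine precision", {
  set.seed(21)
  n <- 30; w <- 40
  scores <- matrix(rnorm(n * 3), n, 3)
  loadings <- matrix(rnorm(3 * w), 3, w)
  X <- scores %*% loadings
  y <- drop(scores %*% c(1, -2, 0.5))
  fit <- pls_fit(X, y, 3)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-8)
})

test_that("full-component PLS reproduces ordinary least squares", {
  set.seed(22)
  n <- 40; w <- 6
  X <- matrix(rnorm(n * w), n, w)
  y <- drop(X %*% rnorm(w)) + rnorm(n, sd = 0.3)
  fit <- pls_fit(X, y, w)

  Xc <- sweep(X, 2, colMeans(X)); yc <- y - mean(y)
  beta_ols <- solve(crossprod(Xc), crossprod(Xc, yc))   # normal equations oracle
  expect_equal(unname(fit$regression_coefficients), drop(beta_ols),
               tolerance = 1e-6)
})

test_that("the first PLS weight vector is the cross-covariance direction", {
  set.seed(23)
  X <- matrix(rnorm(50 * 8), 50, 8)
  y <- X[, 2] + rnorm(50, sd = 0.1)
  fit <- pls_fit(X, y, 1)
  Xc <- sweep(X, 2, colMeans(X))
  covxy <- drop(crossprod(Xc, y - mean(y)))
  expect_equal(unname(fit$x_weights[, 1]), covxy / sqrt(sum(covxy^2)),
               tolerance = 1e-10)
})

test_that("predictions agree with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(24)
  n <- 35; w <- 20
  X <- matrix(rnorm(n * w), n, w)
  colnames(X) <- paste0("v", seq_len(w))
  y <- drop(X %*% c(rep(1, 4), rep(0, w - 4))) + rnorm(n, sd = 0.2)
  ours <- pls_fit(X, y, 5)
  theirs <- mixOmics::pls(X, y, ncomp = 5, scale = FALSE, mode = "regression")
  pred_theirs <- predict(theirs, X)$predict[, 1, 5]
  expect_equal(unname(predict(ours, X)), unname(pred_theirs), tolerance = 1e-6)
})

test_that("cross-validated component selection plateaus at the true rank", {
  set.seed(25)
  n <- 60; w <- 30
  scores <- matrix(rnorm(n * 3), n, 3)
  X <- scores %*% matrix(rnorm(3 * w), 3, w)
  X <- X + matrix(rnorm(n * w, sd = 1e-6), n, w)   # break exact rank deficiency
  y <- drop(scores %*% c(2, -1, 1))
  sel <- select_ncomp_cv(X, y, max_components = 8, n_folds = 5, seed = 7)
  expect_lte(sel$n_components, 3)
  expect_lt(sel$rmsecv_trace[3], 1e-4)
  expect_true(all(is.finite(sel$rmsecv_trace)) && all(sel$rmsecv_trace >= 0))

  sel2 <- select_ncomp_cv(X, y, max_components = 8, n_folds = 5, seed = 7)
  expect_identical(sel$rmsecv_trace, sel2$rmsecv_trace)   # deterministic folds

  expect_error(select_ncomp_cv(X, y, 8, n_folds = 100),
               class = "fujigrade_invalid_parameter")
})

test_that("model metrics match their defining formulas", {
  # affine model predicting x + 1 through the pls_model predict method
  plus_one <- structure(list(regression_coefficients = 1, x_mean = 0,
                             y_mean = 1, n_components = 1),
                        class = "pls_model")
  ident <- structure(list(regression_coefficients = 1, x_mean = 0,
                          y_mean = 0, n_components = 1),
                     class = "pls_model")

  X <- matrix(c(1, 2, 3), ncol = 1)
  m <- evaluate_model(plus_one, X - 1, c(1, 2, 3), X, c(1, 2, 3))
  expect_equal(m$r_c, 1)
  expect_equal(m$rmsec, 0)
  expect_equal(m$r_p, 1)        # predictions (2,3,4) vs truth (1,2,3)
  expect_equal(m$rmsep, 1)

  set.seed(26)
  yc <- rnorm(12); yp <- rnorm(7)
  Xc <- matrix(rnorm(12), ncol = 1); Xp <- matrix(rnorm(7), ncol = 1)
  m2 <- evaluate_model(ident, Xc, yc, Xp, yp)
  expect_equal(m2$r_c, cor(drop(Xc), yc), tolerance = 1e-10)
  expect_equal(m2$rmsep, sqrt(mean((drop(Xp) - yp)^2)), tolerance = 1e-10)

  expect_warning(m3 <- evaluate_model(ident, Xc, rep(1, 12), Xp, yp),
                 "correlation undefined")
  expect_true(is.na(m3$r_c))
  expect_equal(m3$rmsec, sqrt(mean((drop(Xc) - 1)^2)), tolerance = 1e-10)
})

test_that("degenerate PLS inputs raise typed errors", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(pls_fit(X, rep(1, 10), 1), class = "fujigrade_degenerate_response")
  expect_error(pls_fit(X, rnorm(10), 5), class = "fujigrade_invalid_parameter")
  expect_error(pls_fit(X, rnorm(3), 1), class = "fujigrade_invalid_parameter")
})
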