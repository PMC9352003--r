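# NIPALS PLS1 work-horse. Returns weights/loadings for up to `ncomp`
# components and the regression coefficient vector for EVERY truncation
# 1..ncomp (cheap, and lets cross-validation score all component counts
# from a single fit per fold).
pls_nipals <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); w <- ncol(X)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean)
  yc <- y - y_mean
  A <- min(ncomp, n - 1, w)
  W <- matrix(0, w, A); P <- matrix(0, w, A); q <- numeric(A)
  for (a in seq_len(A)) {
    wv <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(wv^2))
    if (nw < 1e-12) { A <- a - 1L; break }
    wv <- wv / nw
    t_sc <- drop(Xc %*% wv)
    tt <- sum(t_sc^2)
    p <- drop(crossprod(Xc, t_sc)) / tt
    qa <- sum(yc * t_sc) / tt
    Xc <- Xc - tcrossprod(t_sc, p)
    yc <- yc - qa * t_sc
    W[, a] <- wv; P[, a] <- p; q[a] <- qa
  }
  if (A == 0) {
    coefs <- matrix(0, w, 1)
  } else {
    W <- W[, seq_len(A), drop = FALSE]
    P <- P[, seq_len(A), drop = FALSE]
    q <- q[seq_len(A)]
    # B_a = W_a (P_a' W_a)^{-1} q_a ; P'W is upper triangular with unit-ish diag
    PtW <- crossprod(P, W)
    coefs <- sapply(seq_len(A), function(a) {
      drop(W[, 1:a, drop = FALSE] %*%
             solve(PtW[1:a, 1:a, drop = FALSE], q[1:a]))
    })
    coefs <- matrix(coefs, nrow = w)
  }
  list(x_weights = W, x_loadings = P, y_loadings = q,
       coef_path = coefs, n_components = ncol(coefs),
       x_mean = x_mean, y_mean = y_mean)
}

#' Fit a partial least squares (PLS1) regression
#'
#' NIPALS single-response PLS with mean-centering (no variable scaling —
#' MSC/SNV preprocessing already normalizes the spectra). Prediction is
#' affine in the input spectrum:
#' `yhat = (x - x_mean) %*% coefficients + y_mean`.
#'
#' @param X `N x W` numeric predictor matrix (spectra in rows).
#' @param y Length-N numeric response (°Brix).
#' @param n_components Number of latent variables,
#'   `1 <= n_components <= min(N - 1, W)`.
#' @return An object of class `pls_model` with elements
#'   `regression_coefficients`, `x_mean`, `y_mean`, `n_components`,
#'   `x_weights`, `x_loadings`, `y_loadings`. Has `predict()`, [tidy()]
#'   and [glance()] methods.
#' @examples
#' X <- matrix(rnorm(200), 20, 10)
#' y <- X[, 1] - 2 * X[, 2] + rnorm(20, sd = 0.01)
#' fit <- pls_fit(X, y, 3)
#' cor(predict(fit, X), y)
#' @export
pls_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) {
    abort("`y` must have one value per row of `X`.", class = "fujigrade_invalid_parameter")
  }
  if (sd(y) == 0) {
    abort("Response has zero variance.", class = "fujigrade_degenerate_response")
  }
  if (n_components < 1 || n_components > min(nrow(X) - 1, ncol(X))) {
    abort("`n_components` must lie in [1, min(N - 1, W)].",
          class = "fujigrade_invalid_parameter")
  }
  fit <- pls_nipals(X, y, n_components)
  structure(
    list(
      n_components = fit$n_components,
      regression_coefficients = fit$coef_path[, fit$n_components],
      coef_path = fit$coef_path,
      x_weights = fit$x_weights, x_loadings = fit$x_loadings,
      y_loadings = fit$y_loadings,
      x_mean = fit$x_mean, y_mean = fit$y_mean
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat("<pls_model> ", x$n_components, " latent components, ",
      length(x$regression_coefficients), " predictors\n", sep = "")
  invisible(x)
}

#' @rdname pls_fit
#' @param object,newdata A `pls_model` and an `N x W` matrix (or
#'   `spectra_set`) to predict for.
#' @param ... Unused.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) newdata <- newdata$reflectance
  newdata <- if (is.vector(newdata)) matrix(newdata, nrow = 1) else as.matrix(newdata)
  drop(sweep(newdata, 2, object$x_mean) %*% object$regression_coefficients +
         object$y_mean)
}

#' @rdname pls_fit
#' @param x A `pls_model`.
#' @method tidy pls_model
#' @export
tidy.pls_model <- function(x, ...) {
  tibble(term = seq_along(x$regression_coefficients),
         estimate = unname(x$regression_coefficients))
}

#' @rdname pls_fit
#' @method glance pls_model
#' @export
glance.pls_model <- function(x, ...) {
  tibble(n_components = x$n_components,
         n_predictors = length(x$regression_coefficients),
         y_mean = x$y_mean)
}

# deterministic shuffled k-fold assignment
make_folds <- function(n, n_folds, seed) {
  with_local_seed(seed, {
    sample(rep(seq_len(n_folds), length.out = n))
  })
}

# RMSECV trace for component counts 1..max_components given fold labels
rmsecv_trace <- function(X, y, max_components, folds) {
  X <- as.matrix(X)
  A <- min(max_components, ncol(X))
  press <- matrix(NA_real_, nrow = length(y), ncol = A)
  for (f in sort(unique(folds))) {
    hold <- folds == f
    fit <- pls_nipals(X[!hold, , drop = FALSE], y[!hold], A)
    Af <- fit$n_components
    pred <- sweep(X[hold, , drop = FALSE], 2, fit$x_mean) %*% fit$coef_path +
      fit$y_mean
    press[hold, seq_len(Af)] <- (pred - y[hold])^2
    if (Af < A) press[hold, (Af + 1):A] <- press[hold, Af]
  }
  sqrt(colMeans(press))
}

#' Choose the PLS component count by cross-validation
#'
#' k-fold cross-validated root-mean-square error (RMSECV) for each latent
#' component count up to `max_components`; the count minimizing RMSECV is
#' returned. Folds are shuffled once, deterministically for a given seed.
#'
#' @inheritParams pls_fit
#' @param max_components Largest component count to score (capped at
#'   `min(N - N/n_folds - 1, W)`).
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed controlling the fold shuffle.
#' @return A list with `n_components` (the minimizer) and `rmsecv_trace`
#'   (numeric vector indexed by component count).
#' @export
select_ncomp_cv <- function(X, y, max_components = 20, n_folds = 10, seed = 1) {
  X <- as.matrix(X)
  if (n_folds < 2 || n_folds > nrow(X)) {
    abort("`n_folds` must lie in [2, N].", class = "fujigrade_invalid_parameter")
  }
  if (max_components < 1) {
    abort("`max_components` must be >= 1.", class = "fujigrade_invalid_parameter")
  }
  folds <- make_folds(nrow(X), n_folds, seed)
  max_hold <- max(table(folds))
  A <- min(max_components, nrow(X) - max_hold - 1, ncol(X))
  trace <- rmsecv_trace(X, y, A, folds)
  list(n_components = which.min(trace), rmsecv_trace = trace)
}

#' Calibration and prediction metrics of a fitted model
#'
#' Pearson correlation coefficient and root-mean-square error on the
#' calibration set (`R_c`, RMSEC) and the prediction set (`R_p`, RMSEP).
#'
#' @param model A `pls_model` (or any object with a `predict` method
#'   accepting a matrix).
#' @param x_cal,y_cal Calibration predictors and reference values.
#' @param x_pred,y_pred Prediction-set predictors and reference values
#'   (non-empty).
#' @return A one-row tibble with columns `r_c`, `rmsec`, `r_p`, `rmsep`.
#'   If truth or predictions have zero variance the corresponding
#'   correlation is `NA` with a warning; the RMSE is still returned.
#' @export
evaluate_model <- function(model, x_cal, y_cal, x_pred, y_pred) {
  if (length(y_pred) == 0) {
    abort("Prediction set is empty.", class = "fujigrade_invalid_parameter")
  }
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) {
      warning("Zero variance; correlation undefined.", call. = FALSE)
      return(NA_real_)
    }
    cor(a, b)
  }
  p_cal <- predict(model, x_cal)
  p_pred <- predict(model, x_pred)
  tibble(
    r_c = safe_cor(p_cal, y_cal),
    rmsec = sqrt(mean((p_cal - y_cal)^2)),
    r_p = safe_cor(p_pred, y_pred),
    rmsep = sqrt(mean((p_pred - y_pred)^2))
  )
}
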