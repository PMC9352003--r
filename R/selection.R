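new_selection_result <- function(method, selected, trace, best_iteration,
                                 extra = list()) {
  structure(
    c(list(method = method,
           selected_indices = sort(unique(as.integer(selected))),
           criterion_trace = trace,
           best_iteration = as.integer(best_iteration)),
      extra),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> method = ", x$method, ": ",
      length(x$selected_indices), " wavelengths selected (best iteration ",
      x$best_iteration, ", criterion ",
      format(min(x$criterion_trace, na.rm = TRUE), digits = 4), ")\n", sep = "")
  invisible(x)
}

#' @method tidy selection_result
#' @export
tidy.selection_result <- function(x, ...) {
  tibble(index = x$selected_indices)
}

#' @method glance selection_result
#' @export
glance.selection_result <- function(x, ...) {
  tibble(method = x$method, n_selected = length(x$selected_indices),
         best_iteration = x$best_iteration,
         best_criterion = min(x$criterion_trace, na.rm = TRUE))
}

# exponentially decreasing forced-retention schedule: keeps all W variables
# at run 1 and 2 variables at run n_runs (two-point calibration)
cars_retention_schedule <- function(w, n_runs) {
  a <- (w / 2)^(1 / (n_runs - 1))
  k <- log(w / 2) / (n_runs - 1)
  pmax(2L, pmin(w, round(w * a * exp(-k * seq_len(n_runs)))))
}

#' Competitive adaptive reweighted sampling (CARS) wavelength selection
#'
#' Monte-Carlo wrapper around PLS that competitively shrinks the
#' wavelength set. Each run: (1) a random fraction of the calibration
#' samples is drawn and a PLS model fitted on the current subset, taking
#' absolute regression coefficients as variable weights; (2) an
#' exponentially decreasing schedule forces retention of the
#' top-weighted variables (all W at run 1 down to 2 at run `n_runs`);
#' (3) adaptive reweighted sampling (weighted roulette draws) picks the
#' surviving subset for the next run; (4) the subset's k-fold RMSECV is
#' recorded. The subset with the minimal RMSECV over all runs is
#' returned.
#'
#' @param X `N x W` predictor matrix (`W >= 10`).
#' @param y Length-N response.
#' @param n_runs Number of Monte-Carlo runs (`>= 2`, default 50).
#' @param n_folds Folds for the RMSECV criterion (default 10).
#' @param seed Integer seed; the whole trajectory is reproducible.
#' @param mc_fraction Fraction of samples drawn per run (default 0.8).
#' @param max_components Cap on PLS components inside the runs.
#' @return A `selection_result` (method `"CARS"`) with the selected
#'   indices, the per-run RMSECV trace, the best run, and the per-run
#'   subset sizes (`n_variables_trace`).
#' @export
cars_select <- function(X, y, n_runs = 50, n_folds = 10, seed = 1,
                        mc_fraction = 0.8, max_components = 15) {
  X <- as.matrix(X)
  n <- nrow(X); w <- ncol(X)
  if (w < 10) abort("CARS needs at least 10 variables.", class = "fujigrade_invalid_parameter")
  if (n_runs < 2) abort("`n_runs` must be >= 2.", class = "fujigrade_invalid_parameter")
  schedule <- cars_retention_schedule(w, n_runs)
  folds <- make_folds(n, n_folds, seed)
  with_local_seed(seed + 1L, {
    current <- seq_len(w)
    trace <- rep(NA_real_, n_runs)
    sizes <- rep(NA_integer_, n_runs)
    subsets <- vector("list", n_runs)
    for (i in seq_len(n_runs)) {
      samp <- sample(n, size = max(2L, round(mc_fraction * n)))
      A <- min(max_components, length(samp) - 1, length(current))
      fit <- pls_nipals(X[samp, current, drop = FALSE], y[samp], A)
      wt <- abs(fit$coef_path[, fit$n_components])
      if (all(wt == 0)) wt <- wt + 1
      keep_n <- min(schedule[i], length(current))
      ord <- order(wt, decreasing = TRUE)
      # forced retention (EDF): the top-weighted half survives outright;
      # adaptive reweighted sampling fills the rest by weight-proportional
      # draws without replacement from the remaining variables
      n_forced <- ceiling(keep_n / 2)
      forced <- ord[seq_len(n_forced)]
      pool <- setdiff(ord, forced)
      n_ars <- keep_n - n_forced
      ars <- if (n_ars > 0 && length(pool) > 0) {
        pool[sample.int(length(pool), size = min(n_ars, length(pool)),
                        prob = wt[pool] + 1e-12)]
      } else integer(0)
      current <- sort(current[c(forced, ars)])
      subsets[[i]] <- current
      sizes[i] <- length(current)
      Acv <- min(max_components, length(current))
      trace[i] <- min(rmsecv_trace(X[, current, drop = FALSE], y, Acv, folds))
      if (length(current) <= 2) { trace <- trace[seq_len(i)]; sizes <- sizes[seq_len(i)]; break }
    }
    best <- which.min(trace)
    new_selection_result("CARS", subsets[[best]], trace, best,
                         extra = list(n_variables_trace = sizes,
                                      retention_schedule = schedule))
  })
}

#' Successive projections chain from a fixed start column
#'
#' Grows a variable chain by successive orthogonal projection: starting
#' from `start`, each step adds the column with the largest Euclidean
#' norm after projection onto the orthogonal complement of the span of
#' the columns already chosen (so each new variable is maximally
#' non-collinear with the chain). Columns are autoscaled before the
#' projections so the criterion compares direction, not raw variance.
#'
#' @param X `N x W` predictor matrix (columns are autoscaled
#'   internally).
#' @param start Index of the first column in the chain.
#' @param k Chain length (`<= W`).
#' @return Integer vector of `k` column indices in selection order (may
#'   be shorter if all remaining residuals vanish, e.g. duplicated
#'   columns).
#' @export
spa_chain <- function(X, start, k) {
  X <- as.matrix(X)
  Xr <- scale(X)   # autoscale: projections compare direction, not variance
  Xr[, attr(Xr, "scaled:scale") == 0] <- 0
  if (k > ncol(Xr)) abort("`k` cannot exceed the number of columns.",
                          class = "fujigrade_invalid_parameter")
  spa_chain_impl(Xr, start, k)
}

# worker on an already-scaled matrix (spa_select scales once for all starts)
spa_chain_impl <- function(Xr, start, k) {
  chain <- integer(0)
  pick <- as.integer(start)
  for (step in seq_len(k)) {
    nrm <- sqrt(sum(Xr[, pick]^2))
    if (nrm < 1e-10) break
    chain <- c(chain, pick)
    qv <- Xr[, pick] / nrm
    Xr <- Xr - qv %*% crossprod(qv, Xr)   # project out the chosen direction
    if (length(chain) == k) break
    norms <- colSums(Xr^2)
    norms[chain] <- -Inf
    pick <- which.max(norms)
    if (norms[pick] < 1e-20) break
  }
  chain
}

# cross-validated RMSE of ordinary multiple linear regression on a column
# subset (the scorer used to compare SPA subsets)
cv_mlr_rmse <- function(X, y, cols, folds) {
  press <- numeric(length(y))
  for (f in sort(unique(folds))) {
    hold <- folds == f
    Xtr <- cbind(1, X[!hold, cols, drop = FALSE])
    beta <- qr.coef(qr(Xtr), y[!hold])
    beta[is.na(beta)] <- 0
    press[hold] <- (cbind(1, X[hold, cols, drop = FALSE]) %*% beta - y[hold])^2
  }
  sqrt(mean(press))
}

#' Successive projections algorithm (SPA) wavelength selection
#'
#' Forward selection by successive orthogonal projections, which yields
#' characteristic wavelengths with minimal collinearity. A candidate
#' chain of length `k_max` is grown from every possible start column
#' ([spa_chain()]); chains are compared by the cross-validated RMSE of a
#' multiple linear regression on their columns, and along the winning
#' chain every subset size `k` in `[k_min, k_max]` is scored the same
#' way. The size (and prefix subset) with minimal RMSE is returned.
#'
#' @inheritParams cars_select
#' @param k_min,k_max Range of subset sizes considered (defaults 30-50).
#' @return A `selection_result` (method `"SPA"`) whose `criterion_trace`
#'   is the RMSE per subset size `k_min:k_max` (`trace_sizes` attribute
#'   gives the sizes; `best_iteration` indexes into the trace).
#' @export
spa_select <- function(X, y, k_min = 30, k_max = 50, n_folds = 10, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X); w <- ncol(X)
  if (k_max > w) abort("`k_max` cannot exceed the number of variables.",
                       class = "fujigrade_invalid_parameter")
  if (k_min < 1 || k_min > k_max) {
    abort("Need 1 <= k_min <= k_max.", class = "fujigrade_invalid_parameter")
  }
  k_max_eff <- min(k_max, n - ceiling(n / n_folds) - 2)
  folds <- make_folds(n, n_folds, seed)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  chains <- lapply(seq_len(w), function(s) spa_chain_impl(Xs, s, k_max_eff))
  scores <- vapply(chains, function(ch) cv_mlr_rmse(X, y, ch, folds), numeric(1))
  best_chain <- chains[[which.min(scores)]]
  sizes <- seq(min(k_min, length(best_chain)), length(best_chain))
  trace <- vapply(sizes, function(k) cv_mlr_rmse(X, y, best_chain[seq_len(k)], folds),
                  numeric(1))
  best <- which.min(trace)
  new_selection_result("SPA", best_chain[seq_len(sizes[best])], trace, best,
                       extra = list(trace_sizes = sizes,
                                    chain = best_chain))
}
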