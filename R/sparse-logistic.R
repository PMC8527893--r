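# L1-penalized logistic regression: the classifier core.
#
# The solver minimizes the penalized deviance objective
#   J(w) = -(1/n) sum_i log P(y_i | x_i; w, b) + lambda * ||w||_1
# with an unpenalized intercept, over a grid of 25 penalties spaced linearly
# on (0, lambda_max].  lambda_max is the smallest penalty at which the only
# solution is the all-zero weight vector.  The penalty is tuned by inner
# 10-fold cross-validation with the one-standard-error rule.

#' Build a standardized training matrix
#'
#' Z-scores every feature using the training rows only; the stored center and
#' scale are later applied to test subjects.  Features that are constant in
#' the training rows cannot be standardized and are dropped with a warning.
#'
#' @param X numeric matrix, subjects x features.
#' @param y binary labels (0 = control, 1 = patient).
#' @return object of class `training_matrix` with elements `X` (standardized),
#'   `y`, `center`, `scale`, `kept` (retained column indices), `p_full`.
#' @export
training_matrix <- function(X, y) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(y %in% c(0, 1)))
  if (length(unique(y)) < 2) stop("labels must contain both classes")
  ctr <- colMeans(X)
  sc <- col_sds(X)
  kept <- which(sc > 1e-12)
  if (length(kept) < ncol(X)) {
    warning(sprintf("dropping %d constant feature(s)", ncol(X) - length(kept)))
  }
  Xs <- sweep(sweep(X[, kept, drop = FALSE], 2, ctr[kept], "-"),
              2, sc[kept], "/")
  structure(list(X = Xs, y = y, center = ctr, scale = sc,
                 kept = kept, p_full = ncol(X)),
            class = "training_matrix")
}

#' Smallest penalty yielding the all-zero solution
#'
#' For the logistic lasso with unpenalized intercept this is
#' `max_j |(1/n) sum_i x_ij (y_i - ybar)|`: at the all-zero weight vector the
#' intercept-only fit predicts `ybar` for everyone, and the KKT conditions
#' hold iff every feature's score gradient is below the penalty.
#'
#' @param data a [training_matrix()].
#' @return scalar `lambda_max`.
#' @export
compute_lambda_max <- function(data) {
  stopifnot(inherits(data, "training_matrix"))
  n <- nrow(data$X)
  max(abs(crossprod(data$X, data$y - mean(data$y)))) / n
}

#' Build the penalty grid
#'
#' `n_lambda` values spaced on `(0, lambda_max]`: linearly by default
#' (`k * lambda_max / n_lambda`), or geometrically (the spacing common in
#' lasso software) for sensitivity analysis.  Zero itself is excluded — the
#' unpenalized fit is never part of the path.
#'
#' @param lambda_max positive scalar from [compute_lambda_max()].
#' @param n_lambda number of penalties (default 25).
#' @param spacing `"linear"` (default) or `"geometric"`.
#' @param min_ratio smallest penalty as a fraction of `lambda_max` when
#'   `spacing = "geometric"`.
#' @return object of class `lambda_path`: ascending `values`, `lambda_max`.
#' @export
build_lambda_grid <- function(lambda_max, n_lambda = 25,
                              spacing = c("linear", "geometric"),
                              min_ratio = 0.01) {
  spacing <- match.arg(spacing)
  if (!is.finite(lambda_max) || lambda_max <= 0) {
    stop("degenerate grid: lambda_max must be > 0 ",
         "(features carry no signal about the labels)")
  }
  if (n_lambda < 2) stop("n_lambda must be >= 2")
  values <- switch(spacing,
    linear = seq_len(n_lambda) * lambda_max / n_lambda,
    geometric = lambda_max * min_ratio^((n_lambda - seq_len(n_lambda)) /
                                          (n_lambda - 1))
  )
  structure(list(values = values, lambda_max = lambda_max, spacing = spacing),
            class = "lambda_path")
}

fit_from_path <- function(data, path_fit, l, lambda) {
  w <- path_fit$weights[, l]
  structure(list(
    weights = w, intercept = path_fit$intercept[l], lambda = lambda,
    n_nonzero = path_fit$n_nonzero[l],
    converged = path_fit$converged[l],
    center = data$center, scale = data$scale, kept = data$kept,
    p_full = data$p_full
  ), class = "lasso_fit")
}

#' Fit the penalized logistic model at one penalty
#'
#' Minimizes `J(w, b) = -(1/n) sum_i log P(y_i|x_i; w, b) + lambda ||w||_1`
#' (intercept unpenalized) by iteratively reweighted least squares with cyclic
#' coordinate descent, safeguarded so the objective never increases across
#' iterations.  At `lambda >= lambda_max` the returned weights are exactly
#' zero and the intercept is `log(ybar / (1 - ybar))`.
#'
#' @param data a [training_matrix()].
#' @param lambda penalty, `>= 0`.
#' @param tol convergence tolerance on the objective (default `1e-9`,
#'   comfortably inside the `1e-7` contract).
#' @param max_outer iteration cap; non-convergence is flagged, not fatal.
#' @return object of class `lasso_fit`: `weights` (standardized scale),
#'   `intercept`, `lambda`, `n_nonzero`, `converged`, plus the training
#'   standardization parameters.
#' @export
fit_penalized_logistic <- function(data, lambda, tol = 1e-9, max_outer = 100) {
  stopifnot(inherits(data, "training_matrix"), lambda >= 0)
  pf <- cd_lasso_path(data$X, data$y, lambda, tol = tol,
                      max_outer = max_outer)
  fit_from_path(data, pf, 1L, lambda)
}

#' Fit the full penalty path (warm-started)
#' @param data a [training_matrix()].
#' @param path a [build_lambda_grid()] result or numeric vector of penalties.
#' @inheritParams fit_penalized_logistic
#' @return list of `lasso_fit` objects, one per penalty in `path` order.
#' @export
fit_lasso_path <- function(data, path, tol = 1e-9, max_outer = 100) {
  lambdas <- if (inherits(path, "lambda_path")) path$values else path
  pf <- cd_lasso_path(data$X, data$y, lambdas, tol = tol,
                      max_outer = max_outer)
  lapply(seq_along(lambdas), function(l) fit_from_path(data, pf, l, lambdas[l]))
}

# stratified fold labels for a binary response
stratified_binary_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    if (length(idx) < k) {
      stop(sprintf("class %s has %d members, fewer than %d folds",
                   format(cls), length(idx), k))
    }
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(sample.int(k), length.out = length(idx))
  }
  fold
}

#' Pure one-standard-error selection rule
#'
#' Given per-penalty mean cross-validated deviances and their dispersion at
#' the minimizer, selects the largest (sparsest) penalty whose mean deviance
#' is within one band of the minimum.  Ties and flat curves resolve toward
#' the largest penalty.
#'
#' @param lambda ascending penalties.
#' @param mean_dev per-penalty mean deviance.
#' @param band_at_min dispersion (SE or SD) of the fold deviances at the
#'   minimizing penalty.
#' @return the selected penalty.
#' @export
one_se_select <- function(lambda, mean_dev, band_at_min) {
  stopifnot(length(lambda) == length(mean_dev), band_at_min >= 0)
  i_min <- which.min(mean_dev)
  eligible <- mean_dev <= mean_dev[i_min] + band_at_min
  max(lambda[eligible])
}

#' Tune the penalty by inner cross-validation with the one-SE rule
#'
#' Runs stratified k-fold cross-validation over the penalty grid, scoring each
#' held-in fold model by mean binomial deviance on its held-out fold, and
#' selects the largest penalty whose mean deviance is within one standard
#' error (`SD / sqrt(k)`, the rule's standard definition; `band = "sd"` uses
#' the raw SD instead) of the minimum.
#'
#' @param data a [training_matrix()].
#' @param path a [build_lambda_grid()] result.
#' @param k_inner number of inner folds (default 10).
#' @param seed fold-assignment seed.
#' @param band `"se"` (default) or `"sd"`.
#' @return object of class `cv_error_curve`: `lambda`, `mean_deviance`,
#'   `se_deviance`, `fold_deviance` (k x L), `selected_lambda`,
#'   `selected_index`.
#' @export
select_lambda_one_se <- function(data, path, k_inner = 10, seed = 1L,
                                 band = c("se", "sd")) {
  stopifnot(inherits(data, "training_matrix"), inherits(path, "lambda_path"))
  band <- match.arg(band)
  fold <- stratified_binary_folds(data$y, k_inner, seed)
  dev <- cv_deviance_path(data$X, data$y, path$values, fold, k_inner)
  mean_dev <- colMeans(dev)
  sd_dev <- col_sds(dev)
  se_dev <- sd_dev / sqrt(k_inner)
  i_min <- which.min(mean_dev)
  band_val <- if (band == "se") se_dev[i_min] else sd_dev[i_min]
  sel <- one_se_select(path$values, mean_dev, band_val)
  structure(list(lambda = path$values, mean_deviance = mean_dev,
                 se_deviance = se_dev, fold_deviance = dev,
                 selected_lambda = sel,
                 selected_index = match(sel, path$values), band = band),
            class = "cv_error_curve")
}

#' Predicted diagnostic probability
#'
#' The logistic function of the linear predictor.  Raw-scale features are
#' standardized with the fit's training parameters before scoring.
#'
#' @param fit a `lasso_fit`.
#' @param X feature matrix on the raw scale (columns as at training).
#' @param standardized set `TRUE` if `X` is already on the training
#'   standardized scale (and restricted to the fit's kept columns).
#' @return probabilities in `(0, 1)`.
#' @export
predict_probability <- function(fit, X, standardized = FALSE) {
  stopifnot(inherits(fit, "lasso_fit"))
  X <- as.matrix(X)
  if (!standardized) {
    if (ncol(X) != fit$p_full) {
      stop(sprintf("expected %d features, got %d", fit$p_full, ncol(X)))
    }
    X <- sweep(sweep(X[, fit$kept, drop = FALSE], 2, fit$center[fit$kept],
                     "-"), 2, fit$scale[fit$kept], "/")
  } else if (ncol(X) != length(fit$weights)) {
    stop(sprintf("expected %d standardized features, got %d",
                 length(fit$weights), ncol(X)))
  }
  stats::plogis(drop(X %*% fit$weights) + fit$intercept)
}

#' Maximum KKT violation of a fit
#'
#' Optimality certificate for the convex objective: for zero weights the score
#' gradient must lie within `[-lambda, lambda]`; for active weights it must
#' equal `lambda * sign(w_j)`; the intercept gradient must vanish.  Returns
#' the largest violation over all coordinates.
#'
#' @param fit a `lasso_fit`.
#' @param data the [training_matrix()] it was fitted on.
#' @return non-negative scalar.
#' @export
kkt_check <- function(fit, data) {
  kkt_max_violation(data$X, data$y, fit$weights, fit$intercept, fit$lambda)
}

#' Penalized objective value of a fit on its training data
#' @param fit a `lasso_fit`.
#' @param data the [training_matrix()] it was fitted on.
#' @return `J(w, b)` at the fit.
#' @export
lasso_objective <- function(fit, data) {
  eta <- drop(data$X %*% fit$weights) + fit$intercept
  nll <- mean(ifelse(eta > 0, eta + log1p(exp(-eta)), log1p(exp(eta))) -
                data$y * eta)
  nll + fit$lambda * sum(abs(fit$weights))
}
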