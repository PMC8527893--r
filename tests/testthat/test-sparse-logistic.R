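test_that("lambda_max is zero for a feature uncorrelated with the labels", {
  X <- matrix(c(1, -1, 1, -1), ncol = 1)
  y <- c(1, 1, 0, 0)
  tm <- training_matrix(X, y)
  expect_equal(compute_lambda_max(tm), 0)
  expect_error(build_lambda_grid(0), "degenerate")
})

test_that("lambda_max matches its closed form and survives row duplication", {
  inst <- random_instance(11, 30, 6)
  tm <- training_matrix(inst$X, inst$y)
  n <- nrow(tm$X)
  expect_equal(compute_lambda_max(tm),
               max(abs(crossprod(tm$X, tm$y - mean(tm$y)))) / n)
  # duplicating every subject leaves the mean score gradient unchanged
  tm2 <- structure(list(X = rbind(tm$X, tm$X), y = c(tm$y, tm$y),
                        center = tm$center, scale = tm$scale, kept = tm$kept,
                        p_full = tm$p_full), class = "training_matrix")
  expect_equal(compute_lambda_max(tm2), compute_lambda_max(tm))
})

test_that("the penalty grid is linear on (0, lambda_max]", {
  expect_equal(build_lambda_grid(25, 25)$values, as.numeric(1:25))
  expect_equal(build_lambda_grid(1, 4)$values, c(0.25, 0.5, 0.75, 1))
  g <- build_lambda_grid(0.37, 25)
  expect_length(g$values, 25)
  expect_equal(max(g$values), 0.37)
  expect_true(all(g$values > 0))
  gg <- build_lambda_grid(1, 5, spacing = "geometric")
  expect_equal(max(gg$values), 1)
  expect_equal(gg$values[1], 0.01)
})

test_that("fitting at or above lambda_max returns the intercept-only model", {
  for (s in 1:10) {
    inst <- random_instance(100 + s, 24, 8)
    tm <- training_matrix(inst$X, inst$y)
    lmax <- compute_lambda_max(tm)
    fit <- fit_penalized_logistic(tm, lmax)
    expect_identical(fit$n_nonzero, 0L)
    expect_equal(fit$intercept, qlogis(mean(tm$y)), tolerance = 1e-8)
    fit2 <- fit_penalized_logistic(tm, lmax * 1.5)
    expect_identical(fit2$n_nonzero, 0L)
  }
})

test_that("solver matches the dense-grid oracle on tiny instances", {
  set.seed(20)
  for (s in 1:6) {
    p <- if (s %% 2) 1 else 2
    inst <- random_instance(300 + s, 10, p)
    tm <- training_matrix(inst$X, inst$y)
    lam <- 0.3 * max(compute_lambda_max(tm), 0.1)
    fit <- fit_penalized_logistic(tm, lam)
    oracle <- grid_oracle_objective(tm$X, tm$y, lam)
    expect_lt(abs(lasso_objective(fit, tm) - oracle), 1e-4)
  }
})

test_that("KKT stationarity certificate holds at returned fits", {
  for (s in 1:8) {
    inst <- random_instance(400 + s, 40, 12)
    tm <- training_matrix(inst$X, inst$y)
    lmax <- compute_lambda_max(tm)
    for (frac in c(0.8, 0.4, 0.1)) {
      fit <- fit_penalized_logistic(tm, frac * lmax)
      expect_lt(kkt_check(fit, tm), 1e-5)
      expect_true(fit$converged)
    }
  }
})

test_that("solver agrees with glmnet at matched penalties", {
  for (s in 1:5) {
    inst <- random_instance(500 + s, 50, 15)
    tm <- training_matrix(inst$X, inst$y)
    lam <- 0.25 * compute_lambda_max(tm)
    fit <- fit_penalized_logistic(tm, lam)
    g <- glmnet::glmnet(tm$X, tm$y, family = "binomial", lambda = lam,
                        standardize = FALSE, thresh = 1e-12)
    gw <- as.numeric(g$beta)
    eta <- drop(tm$X %*% gw) + as.numeric(g$a0)
    obj_ref <- mean(log1p(exp(eta)) - tm$y * eta) + lam * sum(abs(gw))
    expect_lt(abs(lasso_objective(fit, tm) - obj_ref), 1e-7)
    expect_equal(fit$n_nonzero, sum(gw != 0))
  }
})

test_that("negating a feature flips only that weight's sign", {
  inst <- random_instance(42, 30, 4)
  tm <- training_matrix(inst$X, inst$y)
  lam <- 0.3 * compute_lambda_max(tm)
  f1 <- fit_penalized_logistic(tm, lam)
  X2 <- inst$X
  X2[, 2] <- -X2[, 2]
  tm2 <- training_matrix(X2, inst$y)
  f2 <- fit_penalized_logistic(tm2, lam)
  expect_equal(f2$weights[2], -f1$weights[2], tolerance = 1e-7)
  expect_equal(f2$weights[-2], f1$weights[-2], tolerance = 1e-7)
})

test_that("objective is non-increasing across solver iterations", {
  inst <- random_instance(7, 40, 10)
  tm <- training_matrix(inst$X, inst$y)
  lam <- 0.2 * compute_lambda_max(tm)
  pf <- ctensemble:::cd_lasso_path(tm$X, tm$y, lam, trace_objective = TRUE)
  trace <- pf$objective_trace[[1]]
  expect_true(all(diff(trace) <= 1e-12))
})

test_that("sparsity weakly decreases along descending penalties on average", {
  nnz_by_lambda <- 0
  for (s in 1:5) {
    inst <- random_instance(600 + s, 40, 12)
    tm <- training_matrix(inst$X, inst$y)
    grid <- build_lambda_grid(compute_lambda_max(tm), 10)
    fits <- fit_lasso_path(tm, grid)
    nnz_by_lambda <- nnz_by_lambda + vapply(fits, `[[`, 0L, "n_nonzero")
  }
  expect_identical(nnz_by_lambda[10], 0)            # all-zero at lambda_max
  expect_true(all(diff(nnz_by_lambda) <= 2))        # non-increasing in aggregate
  expect_gt(nnz_by_lambda[1], nnz_by_lambda[10])
})

test_that("one-SE rule selects the largest penalty within the band", {
  lambda <- 1:5
  dev <- c(0.50, 0.40, 0.30, 0.35, 0.45)
  expect_equal(one_se_select(lambda, dev, 0.06), 4)  # 0.35 <= 0.36 < 0.45
  expect_equal(one_se_select(lambda, dev, 0), 3)
  expect_equal(one_se_select(lambda, rep(0.4, 5), 0), 5)  # flat -> sparsest
})

test_that("inner-CV tuning returns a valid curve and a plausibly sparse model", {
  set.seed(30)
  n <- 60; p <- 50
  X <- matrix(rnorm(n * p), n, p)
  y <- rep(0:1, each = n / 2)
  X[y == 1, 1:5] <- X[y == 1, 1:5] + 2   # d = 2 at 5 informative features
  tm <- training_matrix(X, y)
  path <- build_lambda_grid(compute_lambda_max(tm), 25)
  curve <- select_lambda_one_se(tm, path, k_inner = 10, seed = 4)
  expect_true(curve$selected_lambda %in% path$values)
  expect_true(all(curve$se_deviance >= 0))
  expect_equal(dim(curve$fold_deviance), c(10, 25))
  fit <- fit_penalized_logistic(tm, curve$selected_lambda)
  expect_gte(fit$n_nonzero, 1)
  expect_lte(fit$n_nonzero, 15)
})

test_that("predicted probabilities are logistic in the linear predictor", {
  fit <- structure(list(weights = c(1, 0), intercept = -1, lambda = 0.1,
                        n_nonzero = 1L, converged = TRUE,
                        center = c(0, 0), scale = c(1, 1), kept = 1:2,
                        p_full = 2L), class = "lasso_fit")
  expect_equal(predict_probability(fit, matrix(c(1, 0), 1), standardized = TRUE),
               0.5)
  fit$weights <- c(0, 0)
  fit$intercept <- 0
  expect_equal(predict_probability(fit, matrix(rnorm(10), 5),
                                   standardized = TRUE),
               rep(0.5, 5))
  fit$intercept <- 50
  expect_equal(predict_probability(fit, matrix(0, 1, 2), standardized = TRUE),
               1, tolerance = 1e-10)
  expect_error(predict_probability(fit, matrix(0, 1, 3), standardized = TRUE),
               "features")
})

test_that("constant features are dropped with a warning; single class errors", {
  X <- cbind(rnorm(20), rep(1, 20))
  y <- rep(0:1, 10)
  expect_warning(tm <- training_matrix(X, y), "constant")
  expect_equal(tm$kept, 1L)
  expect_error(training_matrix(X, rep(1, 20)), "both classes")
})
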