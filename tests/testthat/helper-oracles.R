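# Independent oracles kept deliberately naive: they never share code with the
# implementation paths they check.

# exhaustive pair-counting AUC (ties count one half)
auc_pair_counting <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  s <- 0
  for (a in pos) s <- s + sum(a > neg) + 0.5 * sum(a == neg)
  s / (length(pos) * length(neg))
}

# Dense grid search over the weights with the (unpenalized) intercept profiled
# out by per-point Newton steps; returns the minimal penalized objective over
# the grid.  Only feasible for p <= 2.
grid_oracle_objective <- function(X, y, lambda, lim = 3, step = 0.01) {
  p <- ncol(X)
  stopifnot(p <= 2)
  g <- seq(-lim, lim, by = step)
  W <- if (p == 1) matrix(g, ncol = 1) else as.matrix(expand.grid(g, g))
  eta0 <- X %*% t(W)
  b <- numeric(ncol(eta0))
  ybar <- mean(y)
  for (it in 1:30) {
    P <- stats::plogis(sweep(eta0, 2, b, "+"))
    grad <- colMeans(P) - ybar
    hess <- colMeans(P * (1 - P))
    b <- b - grad / pmax(hess, 1e-10)
    if (max(abs(grad)) < 1e-11) break
  }
  eta <- sweep(eta0, 2, b, "+")
  obj <- colMeans(log1p(exp(eta)) - y * eta) + lambda * rowSums(abs(W))
  min(obj)
}

# one-way ANOVA F recomputed longhand from raw data (oracle for f_from_summary)
anova_f_raw <- function(values, groups) {
  unname(summary(stats::aov(values ~ factor(groups)))[[1]]$`F value`[1])
}
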