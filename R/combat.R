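# Empirical-Bayes location/scale harmonization of ROI features across sites,
# in the parametric formulation of Johnson, Li & Rabinovic (2007): per-ROI
# linear model with site and biological covariates, standardization by the
# covariate-adjusted pooled SD, method-of-moments hyperpriors, and iterative
# EB shrinkage of per-site location (gamma*) and scale (delta*) effects.
#
# The fit is split from the transform so that the per-site parameters can be
# audited, serialized, and applied to compatible tables; an unseen site has no
# parameters and is refused.

combat_design <- function(table, group_coding, sites = NULL) {
  site <- factor(table$site, levels = sites %||% sort(unique(table$site)))
  if (anyNA(site)) stop("table contains a site absent from the model: ",
                        paste(setdiff(unique(table$site), levels(site)),
                              collapse = ", "))
  B <- vapply(levels(site), function(s) as.numeric(site == s),
              numeric(length(site)))
  group <- factor(table$group, levels = GROUP_LEVELS)
  if (group_coding == "three") {
    Mg <- cbind(group_NTRS = as.numeric(group == "NTRS"),
                group_TRS  = as.numeric(group == "TRS"))
  } else {
    Mg <- cbind(group_SCZ = as.numeric(group != "HC"))
  }
  M <- cbind(Mg,
             age = table$age,
             sex = as.numeric(table$sex == "F"),
             education = table$education)
  list(B = B, M = M, site = site)
}

#' Fit a ComBat-style harmonization model
#'
#' Estimates, per ROI, a grand intercept, biological covariate coefficients
#' (diagnostic group, age, sex, education), and per-site location/scale
#' effects shrunk by parametric empirical Bayes.  Diagnostic status enters the
#' design as a three-level factor (HC / NTRS / TRS, two indicator columns) by
#' default: collapsing the two patient groups into one column would let the
#' harmonization absorb the very between-patient-group differences the
#' downstream classifiers are asked about, an information leak.  The collapsed
#' coding is available only behind the explicit `group_coding = "two"`
#' override.
#'
#' @param table cohort table (all sites, >= 2 sites with >= 3 subjects each).
#' @param group_coding `"three"` (default, leakage-safe) or `"two"`.
#' @param eb apply empirical-Bayes shrinkage of site parameters (default
#'   `TRUE`); `FALSE` uses the raw per-site estimates.
#' @param single_site_ok if `TRUE`, a single-site table yields a pass-through
#'   model (gamma* = 0, delta* = 1); otherwise a single site is refused.
#' @return an object of class `combat_model`.
#' @references Johnson WE, Li C, Rabinovic A (2007) Adjusting batch effects in
#'   microarray expression data using empirical Bayes methods. Biostatistics
#'   8(1):118-127.
#' @export
fit_combat <- function(table, group_coding = c("three", "two"), eb = TRUE,
                       single_site_ok = FALSE) {
  group_coding <- match.arg(group_coding)
  sites <- sort(unique(table$site))
  n_site <- table(table$site)
  if (length(sites) < 2 && !single_site_ok) {
    stop("only one site present; nothing to harmonize ",
         "(use single_site_ok = TRUE for a pass-through model)")
  }
  if (any(n_site < 3)) {
    stop("every site needs >= 3 subjects; too small: ",
         paste(names(n_site)[n_site < 3], collapse = ", "))
  }
  Y <- thickness_matrix(table)
  n <- nrow(Y); p <- ncol(Y)
  d <- combat_design(table, group_coding, sites)
  D <- cbind(d$B, d$M)
  qrD <- qr(D)
  if (qrD$rank < ncol(D)) {
    bad <- colnames(D)[qrD$pivot[seq(qrD$rank + 1, ncol(D))]]
    stop("rank-deficient harmonization design; collinear columns: ",
         paste(bad, collapse = ", "))
  }

  beta <- qr.coef(qrD, Y)                       # (S + q) x p
  S <- ncol(d$B)
  beta_site <- beta[seq_len(S), , drop = FALSE]
  beta_cov <- beta[-seq_len(S), , drop = FALSE]
  w_site <- as.numeric(n_site[sites]) / n
  alpha <- drop(crossprod(beta_site, w_site))   # weighted grand intercept, p

  fitted <- D %*% beta
  sigma2 <- colMeans((Y - fitted)^2)            # pooled variance, /n
  if (any(sigma2 <= 0)) {
    stop("zero residual variance at ROI(s): ",
         paste(which(sigma2 <= 0), collapse = ", "))
  }
  sigma <- sqrt(sigma2)

  # standardized, covariate- and grand-mean-adjusted data
  Z <- sweep(sweep(Y - d$M %*% beta_cov, 2, alpha, "-"), 2, sigma, "/")

  gamma_hat <- matrix(0, S, p, dimnames = list(sites, colnames(Y)))
  delta_hat <- matrix(1, S, p, dimnames = list(sites, colnames(Y)))
  for (s in seq_along(sites)) {
    Zi <- Z[d$site == sites[s], , drop = FALSE]
    gamma_hat[s, ] <- colMeans(Zi)
    delta_hat[s, ] <- col_sds(Zi)^2
  }

  if (eb && length(sites) > 1) {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
    for (s in seq_along(sites)) {
      g_bar <- mean(gamma_hat[s, ])
      t2 <- stats::var(gamma_hat[s, ])
      m <- mean(delta_hat[s, ]); v <- stats::var(delta_hat[s, ])
      a_prior <- (2 * v + m^2) / v
      b_prior <- (m * v + m^3) / v
      ns <- sum(d$site == sites[s])
      Zi <- Z[d$site == sites[s], , drop = FALSE]
      g_old <- gamma_hat[s, ]; d_old <- delta_hat[s, ]
      repeat {
        g_new <- (ns * t2 * gamma_hat[s, ] + d_old * g_bar) / (ns * t2 + d_old)
        ss <- colSums(sweep(Zi, 2, g_new, "-")^2)
        d_new <- (b_prior + 0.5 * ss) / (ns / 2 + a_prior - 1)
        change <- max(abs(g_new - g_old) / pmax(abs(g_old), 1e-12),
                      abs(d_new - d_old) / pmax(abs(d_old), 1e-12))
        g_old <- g_new; d_old <- d_new
        if (change < 1e-4) break
      }
      gamma_star[s, ] <- g_old
      delta_star[s, ] <- d_old
    }
  } else {
    gamma_star <- gamma_hat
    delta_star <- delta_hat
  }
  if (length(sites) == 1) {
    gamma_star[] <- 0
    delta_star[] <- 1
  }
  if (any(delta_star <= 0)) stop("non-positive shrunk scale estimate")

  structure(list(
    sites = sites, n_site = as.integer(n_site[sites]),
    group_coding = group_coding, eb = eb,
    covariates = colnames(d$M),
    alpha = alpha, beta_cov = beta_cov, sigma = sigma,
    gamma_star = gamma_star, delta_star = delta_star,
    gamma_hat = gamma_hat, delta_hat = delta_hat,
    roi_names = colnames(Y)
  ), class = "combat_model")
}

#' Apply a fitted harmonization model
#'
#' Transforms each value to
#' `(z - gamma*_site) / sqrt(delta*_site) * sigma + alpha + covariate mean`,
#' where `z` is the standardized covariate-adjusted residual.  Site effects
#' are removed; modeled biological covariate effects (group, age, sex,
#' education) are retained.  Shape and metadata are preserved.
#'
#' @param model a `combat_model` from [fit_combat()].
#' @param table cohort table whose sites and ROI set the model has seen.
#' @return the harmonized cohort table.
#' @export
apply_combat <- function(model, table) {
  stopifnot(inherits(model, "combat_model"))
  Y <- thickness_matrix(table)
  if (!identical(colnames(Y), model$roi_names)) {
    stop("ROI columns do not match the fitted model")
  }
  unseen <- setdiff(unique(table$site), model$sites)
  if (length(unseen)) {
    stop("no harmonization parameters for site(s): ",
         paste(unseen, collapse = ", "))
  }
  d <- combat_design(table, model$group_coding, model$sites)
  covmean <- d$M %*% model$beta_cov
  Z <- sweep(sweep(Y - covmean, 2, model$alpha, "-"), 2, model$sigma, "/")
  s_idx <- match(table$site, model$sites)
  Zadj <- (Z - model$gamma_star[s_idx, , drop = FALSE]) /
    sqrt(model$delta_star[s_idx, , drop = FALSE])
  Yadj <- sweep(Zadj, 2, model$sigma, "*") + covmean
  Yadj <- sweep(Yadj, 2, model$alpha, "+")
  out <- table
  out[, model$roi_names] <- Yadj
  out
}

#' @export
print.combat_model <- function(x, ...) {
  cat("ComBat harmonization model\n")
  cat("  sites:", paste(sprintf("%s (n=%d)", x$sites, x$n_site),
                        collapse = ", "), "\n")
  cat("  ROIs:", length(x$roi_names), "\n")
  cat("  covariates:", paste(x$covariates, collapse = ", "),
      sprintf("[group coding: %s]", x$group_coding), "\n")
  cat("  EB shrinkage:", x$eb, "\n")
  for (s in seq_along(x$sites)) {
    cat(sprintf("  %s: mean gamma* = %+.4f, mean delta* = %.4f\n",
                x$sites[s], mean(x$gamma_star[s, ]), mean(x$delta_star[s, ])))
  }
  invisible(x)
}

#' Serialize a harmonization model to JSON
#'
#' @param model a `combat_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
combat_to_json <- function(model, path) {
  stopifnot(inherits(model, "combat_model"))
  jsonlite::write_json(unclass(model), path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
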