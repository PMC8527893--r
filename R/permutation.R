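# Permutation max-statistic inference for classification AUC and for
# region-selection frequency, plus effect-size characterization and
# summary-statistic demographic tests.
#
# Each permutation iteration shuffles the diagnosis labels of the whole
# cohort (harmonization is not refit: it precedes classification in the
# procedure) and reruns the complete nested-CV / undersampling / soft-vote
# pipeline for both contrasts through the same engine as the observed
# analysis.  Family-wise error is controlled by the distribution of the
# maximum statistic across the tested family: the two contrasts for AUC, and
# all ROIs x both contrasts for selection counts.

perm_p <- function(observed, null) (1 + sum(null >= observed)) / (1 + length(null))

run_both_contrasts <- function(X, group, subject_id, config, folds,
                               keep_sets = FALSE) {
  list(NTRS = nested_cv_engine(X, group, subject_id, "NTRS", config, folds,
                               keep_sets),
       TRS = nested_cv_engine(X, group, subject_id, "TRS", config, folds,
                              keep_sets))
}

#' Permutation max-null for the full pipeline
#'
#' Runs the observed two-contrast analysis, then `B` label-permuted reruns of
#' the identical pipeline, recording per iteration (i) the maximum of the two
#' contrasts' out-of-fold AUCs and (ii) the per-ROI selection counts of both
#' contrasts.  Both null distributions come from the same reruns.  One-sided
#' p-values use the add-one estimator `(1 + #{null >= observed}) / (1 + B)`,
#' so no p-value is ever exactly zero.
#'
#' @param table harmonized cohort table with all three groups.
#' @param config a [pipeline_config()].
#' @param B number of permutations (default `config$n_permutations`).
#' @param seed master seed (default `config$seed`).
#' @param progress print a dot every 10 iterations.
#' @return object of class `perm_null`: `results` (observed `nested_cv` per
#'   contrast, with classifier sets), `observed_auc` (direct and
#'   cross-applied), `observed_counts` (2 x ROIs), `null_auc_max` (length B),
#'   `null_count_max` (length B), `null_count_roi` (B x ROIs, per-ROI max
#'   over contrasts), `auc_p` (one-sided max-null p per observed AUC), `B`.
#' @export
permutation_null <- function(table, config, B = config$n_permutations,
                             seed = config$seed, progress = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  X <- thickness_matrix(table)
  group <- table$group
  sid <- table$subject_id
  folds <- assign_stratified_folds(group, config$k_outer,
                                   derive_seed(seed, 99L))
  obs <- run_both_contrasts(X, group, sid, config, folds, keep_sets = TRUE)
  observed_auc <- c(
    NTRS = compute_metrics(obs$NTRS)$auc,
    TRS = compute_metrics(obs$TRS)$auc,
    TRS_via_NTRS = compute_metrics(cross_apply(obs$NTRS))$auc,
    NTRS_via_TRS = compute_metrics(cross_apply(obs$TRS))$auc)
  observed_counts <- rbind(NTRS = obs$NTRS$selection_counts,
                           TRS = obs$TRS$selection_counts)

  null_auc_max <- numeric(B)
  null_count_max <- numeric(B)
  null_count_roi <- matrix(0L, B, ncol(X))
  for (b in seq_len(B)) {
    seed_b <- derive_seed(seed, 1000L, b)
    set.seed(seed_b)
    gperm <- group[sample.int(length(group))]
    cfg_b <- config
    cfg_b$seed <- seed_b
    folds_b <- assign_stratified_folds(gperm, config$k_outer,
                                       derive_seed(seed_b, 99L))
    pr <- run_both_contrasts(X, gperm, sid, cfg_b, folds_b, keep_sets = FALSE)
    null_auc_max[b] <- max(compute_metrics(pr$NTRS)$auc,
                           compute_metrics(pr$TRS)$auc)
    cmax <- pmax(pr$NTRS$selection_counts, pr$TRS$selection_counts)
    null_count_roi[b, ] <- cmax
    null_count_max[b] <- max(cmax)
    if (progress && b %% 10 == 0) cat(".")
  }
  if (progress) cat("\n")
  auc_p <- vapply(observed_auc, perm_p, numeric(1), null = null_auc_max)
  structure(list(results = obs, observed_auc = observed_auc,
                 observed_counts = observed_counts,
                 null_auc_max = null_auc_max,
                 null_count_max = null_count_max,
                 null_count_roi = null_count_roi,
                 auc_p = auc_p, B = B, config = config, folds = folds),
            class = "perm_null")
}

#' Permutation max-null significance of classification AUC
#'
#' Convenience wrapper around [permutation_null()]: the null distribution is
#' the per-iteration maximum of the two permuted contrasts' AUCs, and every
#' observed AUC (direct and cross-applied) is tested one-sided against it.
#'
#' @inheritParams permutation_null
#' @return see [permutation_null()]; p-values are in `$auc_p`.
#' @export
permutation_null_auc <- function(table, config, B = config$n_permutations,
                                 seed = config$seed, progress = FALSE) {
  permutation_null(table, config, B = B, seed = seed, progress = progress)
}

#' Permutation max-null for region-selection counts
#'
#' Convenience wrapper around [permutation_null()]: the default null
#' distribution is the per-iteration maximum selection count over all ROIs
#' and both contrasts, controlling the family-wise error across the whole
#' region family.  Use [region_importance()] to threshold it.
#'
#' @inheritParams permutation_null
#' @return see [permutation_null()].
#' @export
selection_null <- function(table, config, B = config$n_permutations,
                           seed = config$seed, progress = FALSE) {
  permutation_null(table, config, B = B, seed = seed, progress = progress)
}

#' @export
print.perm_null <- function(x, ...) {
  cat(sprintf("Permutation max-null (%d iterations)\n", x$B))
  for (nm in names(x$observed_auc)) {
    cat(sprintf("  AUC %-14s %.3f  (p = %.4g, max-null corrected)\n",
                nm, x$observed_auc[nm], x$auc_p[nm]))
  }
  cat(sprintf("  selection-count null: max %.0f, 95%% quantile %.0f\n",
              max(x$null_count_max),
              stats::quantile(x$null_count_max, 0.95, type = 1)))
  invisible(x)
}

#' Per-ROI selection frequency
#'
#' How many of the `k_outer * n_subsamples` fitted classifiers gave an ROI a
#' nonzero weight (at the default design, out of 100).
#'
#' @param x a `nested_cv` result, or a list of `classifier_set`s.
#' @param n_rois required when `x` is a list of sets.
#' @return integer counts, one per ROI.
#' @export
selection_frequency <- function(x, n_rois = NULL) {
  if (inherits(x, "nested_cv")) return(x$selection_counts)
  fits <- unlist(lapply(x, function(s) s$fits), recursive = FALSE)
  if (is.null(n_rois)) n_rois <- fits[[1]]$p_full
  selection_counts_from_fits(fits, n_rois)
}

#' Region importance table with max-null thresholds and effect sizes
#'
#' Flags an ROI as important for a contrast when its observed selection count
#' exceeds the `(1 - alpha)` quantile of the permutation null.  The default
#' null is the max over all ROIs and both contrasts (family-wise control over
#' the full region family); `scope = "contrasts"` instead uses each ROI's own
#' null of the per-iteration max over the two contrasts only.  Cohen's d
#' (patient minus control; negative = thinner cortex) is attached per group
#' pair when a cohort table is supplied.
#'
#' @param perm a `perm_null` from [permutation_null()].
#' @param table optional cohort table for effect sizes.
#' @param alpha one-sided level (default the config's).
#' @param scope `"rois_and_contrasts"` (default) or `"contrasts"`.
#' @return data frame: `roi`, `count_NTRS`, `count_TRS`, `threshold`,
#'   `significant_NTRS`, `significant_TRS`, `p_NTRS`, `p_TRS`, and effect
#'   size columns `d_NTRS_HC`, `d_TRS_HC`, `d_TRS_NTRS` when `table` given.
#' @export
region_importance <- function(perm, table = NULL,
                              alpha = perm$config$alpha,
                              scope = c("rois_and_contrasts", "contrasts")) {
  scope <- match.arg(scope)
  stopifnot(inherits(perm, "perm_null"))
  counts <- perm$observed_counts
  p <- ncol(counts)
  if (scope == "rois_and_contrasts") {
    null <- perm$null_count_max
    thr <- rep(stats::quantile(null, 1 - alpha, type = 1, names = FALSE), p)
    p_ntrs <- vapply(counts["NTRS", ], perm_p, numeric(1), null = null)
    p_trs <- vapply(counts["TRS", ], perm_p, numeric(1), null = null)
  } else {
    thr <- apply(perm$null_count_roi, 2, stats::quantile, probs = 1 - alpha,
                 type = 1, names = FALSE)
    p_ntrs <- vapply(seq_len(p), function(r)
      perm_p(counts["NTRS", r], perm$null_count_roi[, r]), numeric(1))
    p_trs <- vapply(seq_len(p), function(r)
      perm_p(counts["TRS", r], perm$null_count_roi[, r]), numeric(1))
  }
  out <- data.frame(roi = seq_len(p),
                    count_NTRS = counts["NTRS", ],
                    count_TRS = counts["TRS", ],
                    threshold = thr,
                    significant_NTRS = counts["NTRS", ] > thr,
                    significant_TRS = counts["TRS", ] > thr,
                    p_NTRS = p_ntrs, p_TRS = p_trs, row.names = NULL)
  if (!is.null(table)) {
    eff <- effect_size_table(table, rois = seq_len(p))
    out$d_NTRS_HC <- eff$d[eff$pair == "NTRS-HC"]
    out$d_TRS_HC <- eff$d[eff$pair == "TRS-HC"]
    out$d_TRS_NTRS <- eff$d[eff$pair == "TRS-NTRS"]
  }
  out
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(a) - mean(b)) / s_pooled`, with
#' `s_pooled = sqrt(((n_a-1)s_a^2 + (n_b-1)s_b^2) / (n_a+n_b-2))`.
#'
#' @param a,b numeric vectors for the two groups.
#' @return scalar d; errors when the pooled variance is zero.
#' @export
cohens_d <- function(a, b) {
  na <- length(a); nb <- length(b)
  if (na < 2 || nb < 2) stop("both groups need >= 2 observations")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("pooled variance is zero; d undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Per-ROI effect sizes between groups
#'
#' Cohen's d (first group minus second; for patient-vs-HC pairs negative
#' means thinner cortex in patients) with pooled two-sample t-test p-values.
#'
#' @param table cohort table.
#' @param rois ROI indices (default all).
#' @param pairs list of group pairs, each `c(group_a, group_b)`.
#' @return data frame `roi`, `pair`, `d`, `t`, `p`.
#' @export
effect_size_table <- function(table, rois = NULL,
                              pairs = list(c("NTRS", "HC"), c("TRS", "HC"),
                                           c("TRS", "NTRS"))) {
  X <- thickness_matrix(table)
  if (is.null(rois)) rois <- seq_len(ncol(X))
  rows <- lapply(pairs, function(pr) {
    a <- X[table$group == pr[1], rois, drop = FALSE]
    b <- X[table$group == pr[2], rois, drop = FALSE]
    na <- nrow(a); nb <- nrow(b)
    sp2 <- ((na - 1) * col_sds(a)^2 + (nb - 1) * col_sds(b)^2) / (na + nb - 2)
    d <- (colMeans(a) - colMeans(b)) / sqrt(sp2)
    tt <- (colMeans(a) - colMeans(b)) / sqrt(sp2 * (1 / na + 1 / nb))
    data.frame(roi = rois, pair = paste(pr, collapse = "-"), d = d, t = tt,
               p = 2 * stats::pt(-abs(tt), na + nb - 2), row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Two-sample pooled t-test from summary statistics
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries.
#' @return list `statistic`, `df`, `p`.
#' @export
t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  tt <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(statistic = tt, df = df, p = 2 * stats::pt(-abs(tt), df))
}

#' One-way ANOVA F from summary statistics
#'
#' @param means,sds,ns per-group summaries (>= 2 groups).
#' @return list `statistic`, `df1`, `df2`, `p`.
#' @export
f_from_summary <- function(means, sds, ns) {
  k <- length(means)
  stopifnot(length(sds) == k, length(ns) == k, k >= 2)
  if (any(sds <= 0)) stop("SDs must be positive")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  msb <- sum(ns * (means - grand)^2) / (k - 1)
  msw <- sum((ns - 1) * sds^2) / (N - k)
  f <- msb / msw
  list(statistic = f, df1 = k - 1, df2 = N - k,
       p = stats::pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-square from a contingency table
#' @param counts matrix of counts (groups x categories).
#' @return list `statistic`, `df`, `p`.
#' @export
chisq_from_counts <- function(counts) {
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}

#' Demographic test statistic from a per-group summary
#'
#' Two groups give a pooled two-sample t; three or more give a one-way ANOVA
#' F — both computable from the printed means, SDs and group sizes alone, as
#' in a standard participants table.
#'
#' @param summary data frame with columns `mean`, `sd`, `n` (one row per
#'   group).
#' @return list with `statistic`, degrees of freedom, `p`, and `test`.
#' @export
demographic_stats <- function(summary) {
  stopifnot(all(c("mean", "sd", "n") %in% names(summary)), nrow(summary) >= 2)
  if (nrow(summary) == 2) {
    out <- t_from_summary(summary$mean[1], summary$sd[1], summary$n[1],
                          summary$mean[2], summary$sd[2], summary$n[2])
    c(out, test = "t")
  } else {
    out <- f_from_summary(summary$mean, summary$sd, summary$n)
    c(out, test = "F")
  }
}
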