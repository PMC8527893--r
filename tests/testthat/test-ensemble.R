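test_that("stratified folds balance every group to within one subject", {
  group <- rep(c("HC", "NTRS", "TRS"), c(52, 46, 64))
  folds <- assign_stratified_folds(group, 10, seed = 3)
  for (g in unique(group)) {
    per_fold <- tabulate(folds[group == g], 10)
    expect_lte(diff(range(per_fold)), 1)
  }
  expect_identical(folds, assign_stratified_folds(group, 10, seed = 3))
  expect_false(identical(folds, assign_stratified_folds(group, 10, seed = 4)))
  expect_error(assign_stratified_folds(group, 1), ">= 2")
  expect_error(assign_stratified_folds(rep(c("HC", "NTRS", "TRS"),
                                           c(5, 3, 9)), 4, 1), "NTRS")
})

test_that("undersampling equalizes class sizes without replacement", {
  tab <- one_site_cohort(5, 3, seed = 1)
  tab <- tab[tab$group != "TRS", ]
  extra <- one_site_cohort(50, 3, seed = 2)
  hc_extra <- extra[extra$group == "HC", ][1:42, ]
  hc_extra$subject_id <- paste0("X", seq_len(nrow(hc_extra)))
  big <- rbind(tab, hc_extra)   # 47 HC vs 5 NTRS
  bal <- undersample_balance(big, "NTRS", seed = 9)
  expect_equal(as.integer(table(bal$group)[c("HC", "NTRS")]), c(5L, 5L))
  expect_true(all(bal$subject_id %in% big$subject_id))
  expect_false(any(duplicated(bal$subject_id)))

  even <- one_site_cohort(8, 3, seed = 4)
  bal2 <- undersample_balance(even, "TRS", seed = 1)
  expect_setequal(bal2$subject_id,
                  even$subject_id[even$group %in% c("HC", "TRS")])

  picks <- vapply(1:10, function(s) {
    paste(undersample_balance(big, "NTRS", seed = s)$subject_id,
          collapse = ",")
  }, "")
  expect_gt(length(unique(picks)), 1)
})

test_that("soft voting averages member probabilities", {
  mkfit <- function(b) structure(
    list(weights = 0, intercept = b, lambda = 1, n_nonzero = 0L,
         converged = TRUE, center = 0, scale = 1, kept = 1L, p_full = 1L),
    class = "lasso_fit")
  X <- matrix(0, 3, 1)
  fits <- list(mkfit(qlogis(0.2)), mkfit(qlogis(0.8)))
  expect_equal(soft_vote_predict(fits, X), rep(0.5, 3))
  expect_equal(soft_vote_predict(list(fits[[1]], fits[[1]]), X),
               rep(0.2, 3))
  p <- soft_vote_predict(fits, X, members = TRUE)
  m <- attr(p, "members")
  expect_true(all(p >= apply(m, 1, min) & p <= apply(m, 1, max)))
  expect_error(soft_vote_predict(list(), X), "empty")
})

test_that("metrics match hand-counted confusion and pairwise AUC", {
  res <- list(cv = data.frame(
    group = c("TRS", "TRS", "TRS", "HC", "HC"),
    probability = c(0.9, 0.2, 0.6, 0.4, 0.3)))
  m <- compute_metrics(res, threshold = 0.5)
  expect_equal(m$auc, 4 / 6, tolerance = 1e-12)
  expect_equal(m$accuracy, 100 * 4 / 5)
  expect_equal(m$sensitivity, 100 * 2 / 3)
  expect_equal(m$specificity, 100)

  perfect <- list(cv = data.frame(group = rep(c("TRS", "HC"), each = 4),
                                  probability = c(.9, .8, .95, .7, .1, .2, .3, .4)))
  mp <- compute_metrics(perfect, threshold = 0.5)
  expect_equal(mp$auc, 1)
  expect_equal(mp$accuracy, 100)

  ties <- list(cv = data.frame(group = rep(c("TRS", "HC"), 5),
                               probability = rep(0.4, 10)))
  expect_equal(compute_metrics(ties, 0.5)$auc, 0.5)
  # a tie at the threshold classifies as control
  expect_equal(compute_metrics(ties, 0.4)$sensitivity, 0)
  expect_error(compute_metrics(list(cv = data.frame(group = "HC",
                                                    probability = 0.2))),
               "both")
})

test_that("nested CV scores every eligible subject exactly once, out of fold", {
  tab <- one_site_cohort(12, 15, seed = 21)
  cfg <- quick_config(seed = 5)
  res <- run_nested_cv(tab, "NTRS", cfg)

  eligible <- tab$subject_id[tab$group %in% c("HC", "NTRS")]
  expect_setequal(res$cv$subject_id, eligible)
  expect_false(any(duplicated(res$cv$subject_id)))
  expect_setequal(res$other_scores$subject_id,
                  tab$subject_id[tab$group == "TRS"])
  expect_true(all(res$cv$probability > 0 & res$cv$probability < 1))

  # leakage guard: no scored subject sat in its scorer's training data
  for (f in seq_along(res$sets)) {
    scored <- c(res$cv$subject_id[res$cv$fold == f],
                res$other_scores$subject_id[res$other_scores$fold == f])
    expect_length(intersect(scored, res$sets[[f]]$train_ids), 0)
  }

  # full determinism given (data, seed)
  res2 <- run_nested_cv(tab, "NTRS", cfg)
  expect_identical(res$cv, res2$cv)
  expect_identical(res$selection_counts, res2$selection_counts)
})

test_that("classifier sets hold n_subsamples tuned members", {
  tab <- one_site_cohort(12, 10, seed = 3)
  cfg <- quick_config(seed = 2)
  cs <- train_classifier_set(tab, "TRS", cfg, seed = 10, fold_index = 1L)
  expect_s3_class(cs, "classifier_set")
  expect_length(cs$fits, cfg$n_subsamples)
  expect_true(all(vapply(cs$fits, inherits, TRUE, "lasso_fit")))
  cs2 <- train_classifier_set(tab, "TRS", cfg, seed = 10, fold_index = 1L)
  expect_identical(cs$fits, cs2$fits)
})

test_that("a strong planted signal is classified accurately", {
  em <- data.frame(roi = 1:5, group = "TRS", d = 1.5)
  tab <- one_site_cohort(25, 60, effect_map = em, seed = 31)
  res <- run_nested_cv(tab, "TRS", quick_config(seed = 8))
  m <- compute_metrics(res)
  expect_gt(m$auc, 0.8)

  # bagging sanity: the soft-vote ensemble is not systematically worse
  # than its average member
  pos <- res$cv$group != "HC"
  member_auc <- apply(res$member_probs, 2, auc_rank, positive = pos)
  expect_gte(m$auc, mean(member_auc) - 0.05)
})

test_that("cross-application reuses held-out scores and never leaks", {
  em <- rbind(data.frame(roi = 1:4, group = "NTRS", d = 1.2),
              data.frame(roi = 1:4, group = "TRS", d = 1.2))
  tab <- one_site_cohort(15, 20, effect_map = em, seed = 41)
  res <- run_nested_cv(tab, "NTRS", quick_config(seed = 6))
  xa <- cross_apply(res)
  expect_s3_class(xa, "cv_result")
  expect_equal(xa$contrast, "TRS")
  expect_equal(xa$classifier_contrast, "NTRS")
  expect_setequal(xa$cv$subject_id,
                  tab$subject_id[tab$group %in% c("HC", "TRS")])
  for (f in seq_along(res$sets)) {
    scored <- xa$cv$subject_id[xa$cv$fold == f]
    expect_length(intersect(scored, res$sets[[f]]$train_ids), 0)
  }
  m <- compute_metrics(xa)
  expect_true(m$auc >= 0 && m$auc <= 1)

  res$other_scores <- res$other_scores[0, ]
  expect_error(cross_apply(res), "no stored")
})
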