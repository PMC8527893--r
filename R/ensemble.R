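# The outer machinery: stratified nested cross-validation, per-fold
# undersampling ensembles with soft voting, performance metrics, and the
# cross-application (exchangeability) analysis.
#
# Training inside an outer loop uses only controls plus the contrast's own
# patient group; the held-out fold is scored for controls and BOTH patient
# groups, so each fold ensemble's scores for the other group are available
# for cross-application without ever touching its training subjects.

#' Pipeline configuration
#'
#' Every procedural constant of the classification pipeline, defaulting to
#' the canonical design: nested 10-fold cross-validation, ten undersampling
#' subsamples per outer fold (so 100 classifiers per contrast), 25 penalties,
#' a 0.5 decision threshold, and 1000 permutations at alpha 0.05.
#'
#' @param k_outer,k_inner outer/inner fold counts (>= 2).
#' @param n_subsamples undersampling repetitions per outer fold (>= 1).
#' @param n_lambda penalties in the grid.
#' @param decision_threshold probability above which a subject is called a
#'   patient (ties classify as control).
#' @param n_permutations permutation iterations for null distributions.
#' @param alpha one-sided significance level.
#' @param seed master seed; all randomness in the pipeline derives from it.
#' @param lambda_spacing `"linear"` (default) or `"geometric"` penalty grid.
#' @param one_se_band `"se"` (default) or `"sd"` in the one-SE rule.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(k_outer = 10, k_inner = 10, n_subsamples = 10,
                            n_lambda = 25, decision_threshold = 0.5,
                            n_permutations = 1000, alpha = 0.05, seed = 1L,
                            lambda_spacing = c("linear", "geometric"),
                            one_se_band = c("se", "sd")) {
  stopifnot(k_outer >= 2, k_inner >= 2, n_subsamples >= 1, n_lambda >= 2,
            decision_threshold > 0, decision_threshold < 1,
            n_permutations >= 1, alpha > 0, alpha < 1)
  structure(list(k_outer = as.integer(k_outer), k_inner = as.integer(k_inner),
                 n_subsamples = as.integer(n_subsamples),
                 n_lambda = as.integer(n_lambda),
                 decision_threshold = decision_threshold,
                 n_permutations = as.integer(n_permutations), alpha = alpha,
                 seed = as.integer(seed),
                 lambda_spacing = match.arg(lambda_spacing),
                 one_se_band = match.arg(one_se_band)),
            class = "pipeline_config")
}

#' Stratified fold assignment
#'
#' Assigns each subject to one of `k` folds so that within every diagnostic
#' group the per-fold counts differ by at most one.  Deterministic given the
#' seed.
#'
#' @param table cohort table (or a factor/character group vector).
#' @param k number of folds (>= 2).
#' @param seed assignment seed.
#' @return integer fold labels in `1..k`, one per subject.
#' @export
assign_stratified_folds <- function(table, k, seed = 1L) {
  group <- if (is.data.frame(table)) table$group else table
  if (k < 2) stop("k must be >= 2: a single fold leaves no held-out data")
  set.seed(seed)
  folds <- integer(length(group))
  for (g in unique(group)) {
    idx <- which(group == g)
    if (length(idx) < k) {
      stop(sprintf("group %s has %d members, fewer than %d folds",
                   g, length(idx), k))
    }
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep(sample.int(k), length.out = length(idx))
  }
  folds
}

# indices (into y) retained after undersampling the majority class
undersample_idx <- function(y, seed) {
  set.seed(seed)
  pos <- which(y == 1); neg <- which(y == 0)
  if (!length(pos) || !length(neg)) stop("both classes must be present")
  if (length(pos) > length(neg)) {
    pos <- sort(pos[sample.int(length(pos), length(neg))])
  } else if (length(neg) > length(pos)) {
    neg <- sort(neg[sample.int(length(neg), length(pos))])
  }
  sort(c(pos, neg))
}

#' Undersample a training subset to class balance
#'
#' Restricts a cohort table to controls plus the contrast's patient group and
#' randomly reduces whichever class is larger (without replacement) to the
#' size of the smaller, removing the class-imbalance bias before fitting.
#'
#' @param table cohort table (training subjects).
#' @param contrast `"NTRS"` or `"TRS"`: the patient group of the contrast.
#' @param seed sampling seed.
#' @return the balanced subset of `table`.
#' @export
undersample_balance <- function(table, contrast = c("NTRS", "TRS"),
                                seed = 1L) {
  contrast <- match.arg(contrast)
  sub <- table[table$group %in% c("HC", contrast), , drop = FALSE]
  y <- as.numeric(sub$group == contrast)
  sub[undersample_idx(y, seed), , drop = FALSE]
}

# zero-weight fallback fit used when a subsample carries no signal at all
zero_fit <- function(data) {
  ybar <- mean(data$y)
  structure(list(weights = numeric(ncol(data$X)),
                 intercept = log(ybar / (1 - ybar)), lambda = Inf,
                 n_nonzero = 0L, converged = TRUE,
                 center = data$center, scale = data$scale,
                 kept = data$kept, p_full = data$p_full),
            class = "lasso_fit")
}

# Train one ensemble (n_subsamples tuned fits) on a training matrix.
# Single code path used for observed and permuted runs alike.
train_set_internal <- function(X, y, config, seed) {
  fits <- vector("list", config$n_subsamples)
  for (s in seq_len(config$n_subsamples)) {
    seed_s <- derive_seed(seed, s)
    keep <- undersample_idx(y, seed_s)
    tm <- suppressWarnings(training_matrix(X[keep, , drop = FALSE], y[keep]))
    lmax <- compute_lambda_max(tm)
    if (!is.finite(lmax) || lmax <= 0) {
      fits[[s]] <- zero_fit(tm)
      next
    }
    grid <- build_lambda_grid(lmax, config$n_lambda, config$lambda_spacing)
    pf <- cd_lasso_path(tm$X, tm$y, grid$values, tol = 1e-6, max_outer = 20)
    fold <- stratified_binary_folds(tm$y, config$k_inner,
                                    derive_seed(seed_s, 7L))
    dev <- cv_deviance_path(tm$X, tm$y, grid$values, fold, config$k_inner,
                            tol = 1e-4, max_outer = 6)
    mean_dev <- colMeans(dev)
    band <- col_sds(dev)[which.min(mean_dev)]
    if (config$one_se_band == "se") band <- band / sqrt(config$k_inner)
    sel <- one_se_select(grid$values, mean_dev, band)
    l <- match(sel, grid$values)
    fits[[s]] <- fit_from_path(tm, pf, l, sel)
  }
  fits
}

#' Train the classifier set for one outer fold
#'
#' Repeats the undersample-standardize-tune-fit procedure `n_subsamples`
#' times, each repetition drawing its own balanced subsample and tuning its
#' own penalty by inner cross-validation with the one-SE rule.
#'
#' @param table training subjects (cohort table rows; controls plus patients).
#' @param contrast `"NTRS"` or `"TRS"`.
#' @param config a [pipeline_config()].
#' @param seed master seed for this set's subsampling and inner folds.
#' @param fold_index outer-fold index recorded on the set (bookkeeping only).
#' @return object of class `classifier_set`: `fits` (list of `lasso_fit`),
#'   `contrast`, `fold_index`, `train_ids`.
#' @export
train_classifier_set <- function(table, contrast = c("NTRS", "TRS"), config,
                                 seed = config$seed, fold_index = NA_integer_) {
  contrast <- match.arg(contrast)
  sub <- table[table$group %in% c("HC", contrast), , drop = FALSE]
  X <- thickness_matrix(sub)
  y <- as.numeric(sub$group == contrast)
  fits <- train_set_internal(X, y, config, seed)
  structure(list(fits = fits, contrast = contrast,
                 fold_index = fold_index, train_ids = sub$subject_id),
            class = "classifier_set")
}

#' Soft-vote ensemble prediction
#'
#' The ensemble's diagnostic probability for each subject is the arithmetic
#' mean of the member classifiers' predicted probabilities (bagging by soft
#' voting).
#'
#' @param set a `classifier_set` (or bare list of `lasso_fit`s).
#' @param X raw-scale feature matrix for the subjects to score.
#' @param members return the per-member probability matrix as attribute
#'   `"members"` (default `FALSE`).
#' @return mean probabilities, one per row of `X`.
#' @export
soft_vote_predict <- function(set, X, members = FALSE) {
  fits <- if (inherits(set, "classifier_set")) set$fits else set
  if (!length(fits)) stop("empty classifier set")
  P <- vapply(fits, function(f) predict_probability(f, X),
              numeric(nrow(X)))
  P <- matrix(P, nrow = nrow(X))
  out <- rowMeans(P)
  if (members) attr(out, "members") <- P
  out
}

selection_counts_from_fits <- function(fits, p_full) {
  counts <- integer(p_full)
  for (f in fits) {
    w <- numeric(p_full)
    w[f$kept] <- f$weights
    counts <- counts + (w != 0)
  }
  counts
}

# Core nested-CV engine on bare matrices; the permutation null reuses this
# exact code path with permuted group labels.
nested_cv_engine <- function(X, group, subject_id, contrast, config, folds,
                             keep_sets = TRUE) {
  contrast_id <- match(contrast, c("NTRS", "TRS"))
  other <- setdiff(c("NTRS", "TRS"), contrast)
  p <- ncol(X)
  sets <- if (keep_sets) vector("list", config$k_outer) else NULL
  counts <- integer(p)
  cv_rows <- vector("list", config$k_outer)
  other_rows <- vector("list", config$k_outer)

  for (f in seq_len(config$k_outer)) {
    tr <- which(folds != f & group %in% c("HC", contrast))
    te <- which(folds == f)
    y_tr <- as.numeric(group[tr] == contrast)
    fits <- train_set_internal(X[tr, , drop = FALSE], y_tr, config,
                               derive_seed(config$seed, contrast_id, f))
    counts <- counts + selection_counts_from_fits(fits, p)
    prob <- soft_vote_predict(fits, X[te, , drop = FALSE], members = TRUE)
    members <- attr(prob, "members")
    attr(prob, "members") <- NULL

    is_main <- group[te] %in% c("HC", contrast)
    cv_rows[[f]] <- data.frame(
      subject_id = subject_id[te[is_main]], group = group[te[is_main]],
      fold = f, probability = prob[is_main],
      predicted = ifelse(prob[is_main] > config$decision_threshold,
                         contrast, "HC"),
      stringsAsFactors = FALSE)
    cv_rows[[f]]$member_probs <- members[is_main, , drop = FALSE]
    is_other <- group[te] == other
    other_rows[[f]] <- data.frame(
      subject_id = subject_id[te[is_other]], group = group[te[is_other]],
      fold = f, probability = prob[is_other],
      predicted = ifelse(prob[is_other] > config$decision_threshold,
                         contrast, "HC"),
      stringsAsFactors = FALSE)
    if (keep_sets) {
      sets[[f]] <- structure(list(fits = fits, contrast = contrast,
                                  fold_index = f,
                                  train_ids = subject_id[tr]),
                             class = "classifier_set")
    }
  }
  cv <- do.call(rbind, cv_rows)
  member_probs <- cv$member_probs
  cv$member_probs <- NULL
  structure(list(contrast = contrast, cv = cv,
                 other_scores = do.call(rbind, other_rows),
                 member_probs = member_probs,
                 selection_counts = counts, folds = folds,
                 subject_id = subject_id, group = group,
                 sets = sets, config = config),
            class = "nested_cv")
}

#' Run the nested cross-validated ensemble for one contrast
#'
#' For each outer fold: train on the other folds' controls and contrast-group
#' patients (ten undersampled, inner-CV-tuned sparse-logistic fits), then
#' score every subject of the held-out fold — controls and both patient
#' groups — by soft vote.  Contrast-group and control scores form the primary
#' out-of-fold result; the other patient group's scores are stored for
#' [cross_apply()].
#'
#' @param table harmonized cohort table containing all three groups.
#' @param contrast `"NTRS"` or `"TRS"`.
#' @param config a [pipeline_config()].
#' @param folds optional precomputed fold labels (shared between contrasts);
#'   derived deterministically from `config$seed` when `NULL`.
#' @return object of class `nested_cv` with elements `cv` (per-subject
#'   out-of-fold probability and predicted label), `other_scores`,
#'   `selection_counts`, `sets`, `folds`, `member_probs`, `config`.
#' @export
run_nested_cv <- function(table, contrast = c("NTRS", "TRS"), config,
                          folds = NULL) {
  contrast <- match.arg(contrast)
  stopifnot(inherits(config, "pipeline_config"))
  if (!all(GROUP_LEVELS %in% table$group)) {
    stop("table must contain HC, NTRS and TRS subjects")
  }
  if (is.null(folds)) {
    folds <- assign_stratified_folds(table, config$k_outer,
                                     derive_seed(config$seed, 99L))
  }
  nested_cv_engine(thickness_matrix(table), table$group, table$subject_id,
                   contrast, config, folds)
}

#' Classification performance metrics
#'
#' AUC is the rank probability that a randomly drawn patient's diagnostic
#' probability exceeds a randomly drawn control's (ties one half); accuracy,
#' sensitivity and specificity come from the confusion matrix at the decision
#' threshold, with patients as the positive class.
#'
#' @param result a `nested_cv` or `cv_result` object (anything with a `cv`
#'   data frame of `group` and `probability`).
#' @param threshold decision threshold (default the config's, else 0.5).
#' @return object of class `metrics`: `auc` in `[0,1]`; `accuracy`,
#'   `sensitivity`, `specificity` in percent; confusion counts.
#' @export
compute_metrics <- function(result, threshold = NULL) {
  cv <- result$cv
  threshold <- threshold %||% result$config$decision_threshold %||% 0.5
  positive <- cv$group != "HC"
  if (!any(positive) || all(positive)) {
    stop("metrics need both patients and controls in the result")
  }
  auc <- auc_rank(cv$probability, positive)
  pred_pos <- cv$probability > threshold
  tp <- sum(pred_pos & positive); fn <- sum(!pred_pos & positive)
  tn <- sum(!pred_pos & !positive); fp <- sum(pred_pos & !positive)
  structure(list(auc = auc,
                 accuracy = 100 * (tp + tn) / length(positive),
                 sensitivity = 100 * tp / (tp + fn),
                 specificity = 100 * tn / (tn + fp),
                 confusion = c(tp = tp, fp = fp, tn = tn, fn = fn),
                 threshold = threshold),
            class = "metrics")
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf("AUC %.3f | accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
              x$auc, x$accuracy, x$sensitivity, x$specificity))
  invisible(x)
}

#' @export
print.nested_cv <- function(x, ...) {
  m <- compute_metrics(x)
  cat(sprintf("Nested-CV ensemble, contrast %s vs HC (%d folds x %d subsamples)\n",
              x$contrast, x$config$k_outer, x$config$n_subsamples))
  print(m)
  invisible(x)
}

#' Cross-apply a contrast's classifiers to the other patient group
#'
#' The exchangeability readout: each outer fold's ensemble (trained on
#' controls and contrast-A patients) already scored its held-out fold's
#' controls and the other group's patients; those scores are aggregated into
#' an out-of-fold result for "other group vs HC".  No subject is ever scored
#' by an ensemble trained on data that included it.
#'
#' @param result a `nested_cv` from [run_nested_cv()].
#' @return object of class `cv_result` with the cross-applied `cv` table,
#'   `contrast` (the scored group), `classifier_contrast` (the trained one).
#' @export
cross_apply <- function(result) {
  stopifnot(inherits(result, "nested_cv"))
  if (is.null(result$other_scores) || !nrow(result$other_scores)) {
    stop("no stored cross-application scores in this result")
  }
  hc <- result$cv[result$cv$group == "HC", , drop = FALSE]
  cv <- rbind(hc, result$other_scores)
  structure(list(cv = cv,
                 contrast = unique(result$other_scores$group),
                 classifier_contrast = result$contrast,
                 config = result$config),
            class = "cv_result")
}
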