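# Internal helpers shared across modules.

GROUP_LEVELS <- c("HC", "NTRS", "TRS")

#' Derive a reproducible child seed from a master seed
#'
#' Mixes a master seed with a sequence of integer indices (fold, subsample,
#' permutation, ...) into a new seed below 2^31, so that every random draw in
#' the pipeline is a pure function of the master seed and its position in the
#' procedure.
#'
#' @param seed master seed (integer).
#' @param ... integer indices identifying the consumer (e.g. fold, subsample).
#' @return a single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  ids <- c(...)
  s <- as.double(abs(as.integer(seed))) %% 2147483647
  for (id in ids) {
    s <- (s * 69069 + as.double(id) * 2654435761 + 1013904223) %% 2147483647
  }
  as.integer(s)
}

# column means / sds without apply() overhead
col_sds <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(NA_real_, ncol(X)))
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  sqrt(pmax(v, 0))
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney rank statistic: the
#' probability that a randomly chosen positive scores higher than a randomly
#' chosen negative, with ties counting one half.
#'
#' @param scores numeric scores (higher = more positive).
#' @param positive logical vector, `TRUE` for the positive class.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(scores, positive) {
  positive <- as.logical(positive)
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need both positive and negative scores")
  }
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# extract the ROI matrix from a cohort table (rows named by subject)
thickness_matrix <- function(table) {
  roi_cols <- grep("^ROI_", names(table), value = TRUE)
  X <- as.matrix(table[, roi_cols, drop = FALSE])
  rownames(X) <- table$subject_id
  X
}

roi_col_names <- function(n_rois) sprintf("ROI_%04d", seq_len(n_rois))

`%||%` <- function(a, b) if (is.null(a)) b else a
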