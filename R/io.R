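# Readers, writers and the end-to-end report.

required_meta_cols <- c("subject_id", "site", "group", "age", "sex",
                        "education")

#' Read a cohort table from CSV/TSV
#'
#' Validates the schema: metadata columns `subject_id`, `site`, `group`,
#' `age`, `sex`, `education`, then a contiguous block `ROI_0001 ...` of
#' numeric thickness values.  Group labels must be HC / NTRS / TRS; a missing
#' or non-numeric column is reported by name.
#'
#' @param path file path; tab-separated when the extension is `.tsv`,
#'   comma-separated otherwise.
#' @return a validated cohort table (`data.frame`).
#' @export
read_cohort_table <- function(path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required_meta_cols, names(tab))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  roi_cols <- grep("^ROI_", names(tab), value = TRUE)
  if (!length(roi_cols)) stop("no ROI_* thickness columns found")
  n_rois <- max(as.integer(sub("^ROI_", "", roi_cols)))
  expected <- roi_col_names(n_rois)
  absent <- setdiff(expected, roi_cols)
  if (length(absent)) {
    stop("missing ROI column(s): ", paste(absent, collapse = ", "))
  }
  tab <- tab[, c(required_meta_cols, expected)]
  bad_group <- setdiff(unique(tab$group), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group label(s): ", paste(bad_group, collapse = ", "),
         " (expected ", paste(GROUP_LEVELS, collapse = "/"), ")")
  }
  for (cn in expected) {
    v <- tab[[cn]]
    if (!is.numeric(v)) {
      bad_row <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric thickness in column %s (row %d)", cn,
                   bad_row %||% 1L))
    }
    if (anyNA(v)) {
      stop(sprintf("missing thickness value in column %s (row %d)", cn,
                   which(is.na(v))[1]))
    }
  }
  if (anyNA(tab$age) || anyNA(tab$education) || anyNA(tab$sex)) {
    stop("missing covariate values are not supported")
  }
  tab
}

#' Write a cohort table to CSV/TSV
#' @param table cohort table.
#' @param path output path; `.tsv` writes tab-separated.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(table, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Synthetic region-label lookup
#'
#' Maps ROI indices to the anatomical labels used by the default planted
#' effect map.  The mapping is synthetic (shipped with the package for report
#' readability); indices without an entry are plain `ROI_x`.
#'
#' @return data frame `roi`, `label`.
#' @export
roi_labels <- function() {
  utils::read.csv(system.file("extdata", "roi_labels_synthetic.csv",
                              package = "ctensemble"),
                  stringsAsFactors = FALSE)
}

#' Write the end-to-end analysis report
#'
#' Emits the result structure of the analysis as plain CSV/JSON under `dir`:
#' `metrics.csv` (contrast x direct/cross-applied rows of AUC, accuracy,
#' sensitivity, specificity, and max-null p), `importance.csv`,
#' `effect_sizes.csv`, `demographics.csv`, `probabilities.csv` (per-subject
#' diagnostic probabilities per contrast), and `manifest.json` (config echo,
#' seed, package version, timestamp).  Stages not supplied are written as
#' explicit gaps (`NA` rows) and flagged in the return value.
#'
#' @param dir output directory (created if needed).
#' @param perm a `perm_null` from [permutation_null()] (carries the observed
#'   results, AUC p-values and selection nulls).
#' @param importance optional [region_importance()] table.
#' @param effects optional [effect_size_table()] output.
#' @param demographics optional demographics table.
#' @return invisibly, a list with `complete` (logical) and the paths written.
#' @export
write_report <- function(dir, perm, importance = NULL, effects = NULL,
                         demographics = NULL) {
  stopifnot(inherits(perm, "perm_null"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  gaps <- character()

  direct <- lapply(perm$results, compute_metrics)
  crossed <- lapply(perm$results, function(r) compute_metrics(cross_apply(r)))
  rows <- list(
    c(contrast = "NTRS", mode = "direct"),
    c(contrast = "TRS", mode = "direct"),
    c(contrast = "TRS", mode = "cross-applied"),
    c(contrast = "NTRS", mode = "cross-applied"))
  mets <- list(direct$NTRS, direct$TRS, crossed$NTRS, crossed$TRS)
  pvals <- perm$auc_p[c("NTRS", "TRS", "TRS_via_NTRS", "NTRS_via_TRS")]
  metrics <- data.frame(
    contrast = vapply(rows, `[[`, "", "contrast"),
    mode = vapply(rows, `[[`, "", "mode"),
    auc = vapply(mets, `[[`, 0, "auc"),
    accuracy = vapply(mets, `[[`, 0, "accuracy"),
    sensitivity = vapply(mets, `[[`, 0, "sensitivity"),
    specificity = vapply(mets, `[[`, 0, "specificity"),
    p_corrected = unname(pvals))
  f <- file.path(dir, "metrics.csv")
  utils::write.csv(metrics, f, row.names = FALSE)
  paths <- c(paths, f)

  probs <- rbind(
    cbind(contrast = "NTRS", perm$results$NTRS$cv),
    cbind(contrast = "TRS", perm$results$TRS$cv),
    cbind(contrast = "NTRS->TRS", perm$results$NTRS$other_scores),
    cbind(contrast = "TRS->NTRS", perm$results$TRS$other_scores))
  f <- file.path(dir, "probabilities.csv")
  utils::write.csv(probs, f, row.names = FALSE)
  paths <- c(paths, f)

  for (nm in c("importance", "effect_sizes", "demographics")) {
    obj <- switch(nm, importance = importance, effect_sizes = effects,
                  demographics = demographics)
    f <- file.path(dir, paste0(nm, ".csv"))
    if (is.null(obj)) {
      utils::write.csv(data.frame(status = NA_character_), f,
                       row.names = FALSE)
      gaps <- c(gaps, nm)
    } else {
      utils::write.csv(obj, f, row.names = FALSE)
    }
    paths <- c(paths, f)
  }

  manifest <- list(
    package = "ctensemble",
    version = as.character(utils::packageVersion("ctensemble")),
    seed = perm$config$seed,
    n_permutations = perm$B,
    config = unclass(perm$config),
    gaps = gaps,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  f <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, f)

  if (length(gaps)) {
    warning("report written with gaps: ", paste(gaps, collapse = ", "))
  }
  invisible(list(complete = !length(gaps), paths = paths))
}
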