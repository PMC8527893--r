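# Shared fixture builders (all data generated in code at test time).

# balanced single-site cohort: the simplest playground for the pipeline
one_site_cohort <- function(n_per_group, n_rois, effect_map = NULL, seed = 1) {
  generate_cohort(cohort_spec(
    n_per_group_site = list(siteA = c(HC = n_per_group, NTRS = n_per_group,
                                      TRS = n_per_group)),
    n_rois = n_rois, site_shift = c(siteA = 0), site_scale = c(siteA = 1),
    site_roi_sd = 0, effect_map = effect_map, seed = seed))
}

two_site_cohort <- function(n_per_group, n_rois, shift_b = 0.2,
                            scale_b = 1, effect_map = NULL, seed = 1,
                            site_roi_sd = 0) {
  generate_cohort(cohort_spec(
    n_per_group_site = list(
      siteA = c(HC = n_per_group, NTRS = n_per_group, TRS = n_per_group),
      siteB = c(HC = n_per_group, NTRS = n_per_group, TRS = n_per_group)),
    n_rois = n_rois, site_shift = c(siteA = 0, siteB = shift_b),
    site_scale = c(siteA = 1, siteB = scale_b), site_roi_sd = site_roi_sd,
    effect_map = effect_map, seed = seed))
}

# a small nested-CV configuration for fast unit tests
quick_config <- function(seed = 1, ...) {
  pipeline_config(k_outer = 3, k_inner = 3, n_subsamples = 2, seed = seed, ...)
}

# random small classification instance (both classes guaranteed)
random_instance <- function(seed, n, p) {
  set.seed(seed)
  X <- matrix(stats::rnorm(n * p), n, p)
  repeat {
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) == 2) break
  }
  list(X = X, y = y)
}
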