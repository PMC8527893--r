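test_that("a no-bias model leaves the data untouched", {
  tab <- two_site_cohort(30, 10, shift_b = 0.1, seed = 4)
  mod <- fit_combat(tab)
  mod$gamma_star[] <- 0
  mod$delta_star[] <- 1
  out <- apply_combat(mod, tab)
  X0 <- as.matrix(tab[, grep("^ROI_", names(tab))])
  X1 <- as.matrix(out[, grep("^ROI_", names(out))])
  expect_equal(X1, X0, tolerance = 1e-10)
})

test_that("identical sites produce near-null site parameters", {
  tab <- two_site_cohort(200, 15, shift_b = 0, scale_b = 1, seed = 8)
  mod <- fit_combat(tab)
  expect_lt(max(abs(mod$gamma_star)), 0.15)
  expect_lt(max(abs(mod$delta_star - 1)), 0.25)
})

test_that("an injected site shift is recovered and removed", {
  tab <- two_site_cohort(100, 20, shift_b = 0.2, scale_b = 1.2, seed = 6,
                         site_roi_sd = 0.05)
  mod <- fit_combat(tab)
  # location effect in standardized units ~ shift / pooled residual SD
  pooled_sd <- mean(mod$sigma)
  gamma_mm <- mean(mod$gamma_star["siteB", ]) * pooled_sd -
    mean(mod$gamma_star["siteA", ]) * pooled_sd
  expect_equal(gamma_mm, 0.2, tolerance = 0.05)

  harm <- apply_combat(mod, tab)
  X <- as.matrix(harm[, grep("^ROI_", names(harm))])
  dmean <- colMeans(X[harm$site == "siteB", ]) -
    colMeans(X[harm$site == "siteA", ])
  expect_lt(max(abs(dmean)), 0.02)
  sdr <- apply(X[harm$site == "siteB", ], 2, sd) /
    apply(X[harm$site == "siteA", ], 2, sd)
  expect_true(all(sdr > 0.9 & sdr < 1.1))
})

test_that("planted group effects survive harmonization", {
  tab <- two_site_cohort(100, 20, shift_b = 0.2, scale_b = 1.1,
                         effect_map = data.frame(roi = 7, group = "TRS",
                                                 d = 0.8), seed = 10)
  harm <- apply_combat(fit_combat(tab), tab)
  d7 <- cohens_d(harm$ROI_0007[harm$group == "TRS"],
                 harm$ROI_0007[harm$group == "HC"])
  expect_lt(d7, -0.6)
  expect_gt(d7, -1.0)
})

test_that("harmonization is approximately idempotent", {
  tab <- two_site_cohort(60, 12, shift_b = 0.2, scale_b = 1.2, seed = 12,
                         site_roi_sd = 0.05)
  h1 <- apply_combat(fit_combat(tab), tab)
  h2 <- apply_combat(fit_combat(h1), h1)
  X1 <- as.matrix(h1[, grep("^ROI_", names(h1))])
  X2 <- as.matrix(h2[, grep("^ROI_", names(h2))])
  expect_lt(mean(abs(X2 - X1)), 0.01 * 0.25)  # typical change < 1% of SD
  expect_lt(max(abs(X2 - X1)), 0.05 * 0.25)
})

test_that("degenerate inputs are refused with informative errors", {
  tab <- one_site_cohort(20, 6, seed = 3)
  expect_error(fit_combat(tab), "one site")
  mod1 <- fit_combat(tab, single_site_ok = TRUE)
  out <- apply_combat(mod1, tab)
  expect_equal(as.matrix(out[, grep("^ROI_", names(out))]),
               as.matrix(tab[, grep("^ROI_", names(tab))]),
               tolerance = 1e-10)

  tab2 <- two_site_cohort(30, 6, seed = 3)
  tab2$education <- 12  # constant -> collinear with the intercept
  expect_error(fit_combat(tab2), "education")

  mod <- fit_combat(two_site_cohort(30, 6, seed = 3))
  tab3 <- one_site_cohort(20, 6, seed = 3)
  tab3$site <- "siteC"
  expect_error(apply_combat(mod, tab3), "siteC")
})

test_that("three-group status coding is the default; two-group needs the override", {
  tab <- two_site_cohort(30, 6, seed = 5)
  mod <- fit_combat(tab)
  expect_true(all(c("group_NTRS", "group_TRS") %in% mod$covariates))
  mod2 <- fit_combat(tab, group_coding = "two")
  expect_true("group_SCZ" %in% mod2$covariates)
  expect_false("group_NTRS" %in% mod2$covariates)
})

test_that("fit+apply matches the reference ComBat implementation", {
  tab <- two_site_cohort(40, 12, shift_b = 0.15, scale_b = 1.2, seed = 9,
                         site_roi_sd = 0.05)
  harm <- apply_combat(fit_combat(tab), tab)
  H <- t(as.matrix(harm[, grep("^ROI_", names(harm))]))

  design <- stats::model.matrix(
    ~ factor(group, levels = c("HC", "NTRS", "TRS")) + age +
      I(sex == "F") + education, data = tab)
  ref <- suppressMessages(sva::ComBat(
    dat = t(as.matrix(tab[, grep("^ROI_", names(tab))])),
    batch = tab$site, mod = design[, -1, drop = FALSE]))
  expect_lt(max(abs(H - ref)), 1e-8)
})

test_that("model serializes to JSON and prints", {
  tab <- two_site_cohort(20, 4, seed = 2)
  mod <- fit_combat(tab)
  f <- withr::local_tempfile(fileext = ".json")
  combat_to_json(mod, f)
  parsed <- jsonlite::read_json(f)
  expect_equal(unlist(parsed$sites), c("siteA", "siteB"))
  expect_output(print(mod), "ComBat")
})

test_that("three-group coding preserves patient-group contrasts that the
           collapsed coding attenuates under site confounding", {
  # TRS concentrated at the thicker-shifted site masks its deficit; both
  # codings recover most of it, but collapsing NTRS and TRS into one column
  # lets harmonization absorb part of the between-patient-group difference.
  spec <- cohort_spec(
    n_per_group_site = list(siteA = c(HC = 40, NTRS = 60, TRS = 15),
                            siteB = c(HC = 40, NTRS = 15, TRS = 60)),
    n_rois = 40, site_shift = c(siteA = 0, siteB = 0.25),
    site_scale = c(siteA = 1, siteB = 1), site_roi_sd = 0,
    effect_map = data.frame(roi = 7, group = "TRS", d = 1.0), seed = 9)
  tab <- generate_cohort(spec)
  d_of <- function(h) cohens_d(h$ROI_0007[h$group == "TRS"],
                               h$ROI_0007[h$group == "NTRS"])
  d_pre <- d_of(tab)
  d3 <- d_of(apply_combat(fit_combat(tab, "three"), tab))
  d2 <- d_of(apply_combat(fit_combat(tab, "two"), tab))
  expect_lt(abs(d_pre), 0.5)       # confound masks the planted deficit
  expect_lt(d3, -0.7)              # three-group coding restores it
  expect_lt(d3, d2)                # collapsed coding attenuates relative to it
})
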