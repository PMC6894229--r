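# Cohort generator: libraries, spectrum forward model, clinical covariates,
# survival outcomes.

test_that("default serum library matches the published panel", {
  lib <- build_default_serum_library()
  mets <- library_metabolites(lib)
  expect_length(mets, 28)
  per <- lib[!duplicated(lib$name), ]
  rownames(per) <- per$name
  expect_equal(per["Lactate", "fold_change"], 1.36)
  expect_equal(per["Valine", "fold_change"], -1.31)
  expect_true(all(lib$center_ppm >= 0.1 & lib$center_ppm <= 4.2))
  sums <- tapply(lib$rel_area, lib$name, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("default tissue library matches the published panel", {
  lib <- build_default_tissue_library()
  mets <- library_metabolites(lib)
  expect_length(mets, 20)
  per <- lib[!duplicated(lib$name), ]
  rownames(per) <- per$name
  expect_equal(per["Glutathione", "fold_change"], 1.103)
  expect_true("Glutamate" %in% mets)
  expect_true(all(lib$center_ppm >= 1.4 & lib$center_ppm <= 4.7))
  excl <- tissue_exclusion_windows()
  for (k in seq_len(nrow(excl))) {
    expect_false(any(lib$center_ppm >= excl[k, 1] &
                       lib$center_ppm <= excl[k, 2]),
                 info = sprintf("window %.2f-%.2f", excl[k, 1], excl[k, 2]))
  }
})

test_that("synthesized peaks carry unit-normalized Lorentzian areas", {
  lib <- data.frame(name = "x", center_ppm = 2, halfwidth_ppm = 0.01,
                    rel_area = 1, base_level = 1, fold_change = 1, cv = 0)
  axis <- seq(0, 4, length.out = 2^15)
  sp <- synthesize_spectrum(c(x = 2), lib, axis)
  # trapezoid over a wide window vs. the closed-form arctan integral
  win_quad <- function(k) {
    sel <- abs(axis - 2) <= k * 0.01
    sum(diff(axis[sel]) * (sp$intensity[sel][-sum(sel)] +
                             sp$intensity[sel][-1]) / 2)
  }
  analytic <- function(k) 2 * (2 / pi) * atan(k)
  expect_equal(win_quad(20), analytic(20), tolerance = 1e-3)
  # capture converges to the full concentration as the window widens
  expect_equal(win_quad(600), 2, tolerance = 0.01)
})

test_that("zero-concentration spectra are pure noise at the requested SD", {
  lib <- build_default_serum_library()
  conc <- setNames(rep(0, 28), library_metabolites(lib))
  axis <- seq(0, 4.4, length.out = 4096)
  sp <- synthesize_spectrum(conc, lib, axis, noise_sd = 0.3, seed = 4)
  expect_equal(sd(sp$intensity), 0.3, tolerance = 0.05)
  sp2 <- synthesize_spectrum(conc, lib, axis, noise_sd = 0.3, seed = 4)
  expect_identical(sp$intensity, sp2$intensity)
  expect_error(synthesize_spectrum(c(Nope = 1), lib, axis), "Nope")
})

test_that("group-mean ratios reproduce the configured fold changes", {
  cfg <- cohort_config(n_carbohydrate = 2000, n_fasting = 2000,
                       axis_points = 256)
  co <- generate_serum_cohort(cfg, seed = 42)
  g <- co$metadata$group
  ratio <- mean(co$truth_concentrations[g == "carbohydrate", "Lactate"]) /
    mean(co$truth_concentrations[g == "fasting", "Lactate"])
  expect_gt(ratio, 1.33)
  expect_lt(ratio, 1.39)
  # inverted fold change too (Valine -1.31)
  rv <- mean(co$truth_concentrations[g == "carbohydrate", "Valine"]) /
    mean(co$truth_concentrations[g == "fasting", "Valine"])
  expect_equal(rv, 1 / 1.31, tolerance = 0.02)
})

test_that("degenerate noise gives exact group means and seeds reproduce", {
  lib <- build_default_serum_library(cv = 0)
  cfg <- cohort_config(n_carbohydrate = 3, n_fasting = 3, library = lib,
                       noise_sd = 0, shift_jitter_sd = 0, axis_points = 256)
  co <- generate_serum_cohort(cfg, seed = 9)
  g <- co$metadata$group
  expect_true(all(co$truth_concentrations[g == "carbohydrate", "Lactate"] ==
                    1.36 * 5.0))
  co2 <- generate_serum_cohort(cfg, seed = 9)
  expect_identical(co$truth_concentrations, co2$truth_concentrations)
  expect_identical(co$metadata, co2$metadata)
  expect_identical(co$spectra[[1]]$intensity, co2$spectra[[1]]$intensity)
  expect_error(cohort_config(n_carbohydrate = 1), "at least 2")
})

test_that("tissue glutathione effect is gated on ER status", {
  lib <- build_default_tissue_library(cv = 0)
  cfg <- tissue_cohort_config(library = lib, noise_sd = 0,
                              shift_jitter_sd = 0, axis_points = 256)
  co <- generate_tissue_cohort(cfg, seed = 5)
  md <- co$metadata
  g <- co$truth_concentrations[, "Glutathione"]
  ch <- md$group == "carbohydrate"; er <- md$er_status == "positive"
  base <- 1.0
  expect_true(all(g[ch & er] == base * 1.103))
  expect_true(all(g[ch & !er] == base))
  expect_true(all(g[!ch] == base))
  # keyed structures share one sample-id set
  expect_identical(names(co$spectra), md$sample_id)
  expect_identical(rownames(co$truth_concentrations), md$sample_id)
  # ER counts follow the study's tissue-arm frequencies
  expect_equal(sum(er & ch), 11)
  expect_equal(sum(er & !ch), 9)
})

test_that("insulin calibration hits the target correlations and means", {
  cfg <- cohort_config(n_carbohydrate = 4300, n_fasting = 5700,
                       axis_points = 256)
  co <- generate_serum_cohort(cfg, seed = 11)
  md <- generate_clinical_covariates(co, seed = 12)
  r_l <- cor(md$insulin_mIU, co$truth_concentrations[, "Lactate"])
  expect_gt(r_l, 0.54); expect_lt(r_l, 0.60)
  mu <- tapply(md$insulin_mIU, md$group, mean)
  expect_equal(unname(mu["carbohydrate"]), 35.6, tolerance = 0.05)
  expect_equal(unname(mu["fasting"]), 9.1, tolerance = 0.15)
  md0 <- generate_clinical_covariates(
    co, clinical_config(target_r_lactate_insulin = 0,
                        target_r_pyruvate_insulin = 0), seed = 13)
  expect_lt(abs(cor(md0$insulin_mIU, co$truth_concentrations[, "Lactate"])),
            0.05)
  expect_error(clinical_config(target_r_lactate_insulin = 1), "< 1")
})

test_that("survival generator matches the exponential model", {
  md <- data.frame(sample_id = as.character(1:10000), m = 0)
  out <- generate_survival_outcomes(
    md, survival_config(baseline_hazard = 0.2, marker_hrs = c(m = 1),
                        followup_years = 3), seed = 4)
  expect_equal(mean(out$event_rfs), 1 - exp(-0.2 * 3), tolerance = 0.02)
  out0 <- generate_survival_outcomes(
    md, survival_config(marker_hrs = c(m = 1), followup_years = 0), seed = 4)
  expect_true(all(out0$event_rfs == 0))
  expect_true(all(out0$time_rfs_years == 0))
  expect_error(
    generate_survival_outcomes(md, survival_config(), seed = 1),
    "pyruvate_high"
  )
})

test_that("Cox regression recovers the generative hazard ratio", {
  set.seed(31)
  md <- data.frame(sample_id = as.character(1:2000),
                   lactate_high = rbinom(2000, 1, 0.5))
  out <- generate_survival_outcomes(
    md, survival_config(marker_hrs = c(lactate_high = 7.47)), seed = 32)
  f <- cox_fit(survival_records(out, "rfs"),
               data.frame(high = md$lactate_high))
  expect_equal(f$coef[1], log(7.47), tolerance = 0.10)
})
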