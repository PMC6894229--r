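# Spectral preprocessing: referencing, cropping, ALS baseline, exclusion,
# normalization, integration, protocol composition.

one_peak_spectrum <- function(center, axis = seq(1.0, 2.0, by = 0.001),
                              hw = 0.005) {
  nmr_spectrum(axis, (hw / pi) / ((axis - center)^2 + hw^2), "pk")
}

test_that("reference_shift translates the apex onto the target", {
  sp <- one_peak_spectrum(1.50)
  ref <- reference_shift(sp, 1.47, 0.1)
  expect_equal(ref$ppm, sp$ppm - 0.03)
  expect_identical(ref$intensity, sp$intensity)
  # apex already on target: identity
  sp2 <- one_peak_spectrum(1.47)
  expect_equal(reference_shift(sp2, 1.47, 0.1)$ppm, sp2$ppm)
  # idempotence
  expect_equal(reference_shift(ref, 1.47, 0.1)$ppm, ref$ppm)
  # flat window ties are broken toward the target with a warning
  flat <- nmr_spectrum(seq(1.4, 1.6, by = 0.01), rep(1, 21), "flat")
  expect_warning(reference_shift(flat, 1.47, 0.05), "tie")
})

test_that("referencing removes per-sample chemical-shift jitter", {
  cfg <- cohort_config(n_carbohydrate = 5, n_fasting = 5, noise_sd = 0,
                       shift_jitter_sd = 0.005, axis_points = 4096)
  co <- generate_serum_cohort(cfg, seed = 2)
  step <- diff(co$spectra[[1]]$ppm[1:2])
  apexes <- vapply(co$spectra, function(s) {
    r <- reference_shift(s, 1.47, 0.1)
    win <- abs(r$ppm - 1.47) <= 0.05
    r$ppm[win][which.max(r$intensity[win])]
  }, numeric(1))
  expect_lt(sd(apexes), step)
})

test_that("crop_region keeps the closed interval exactly", {
  axis <- seq(0, 4.4, by = 0.01)
  sp <- nmr_spectrum(axis, seq_along(axis), "s")
  cr <- crop_region(sp, 0.1, 4.2)
  expect_length(cr$ppm, 411)
  expect_true(all(cr$ppm >= 0.1 & cr$ppm <= 4.2))
  expect_equal(crop_region(sp, -1, 5)$ppm, sp$ppm)
  expect_error(crop_region(sp, 5.0, 6.0), "no axis points")
  expect_equal(crop_region(cr, 0.1, 4.2)$ppm, cr$ppm)  # idempotent
})

test_that("exclude_regions removes exactly the windowed points", {
  axis <- seq(1.4, 4.7, by = 0.001)
  sp <- nmr_spectrum(axis, rep(1, length(axis)), "s")
  expect_identical(exclude_regions(sp, NULL), sp)
  win <- tissue_exclusion_windows()
  ex <- exclude_regions(sp, win)
  # brute-force membership count
  inside <- rep(FALSE, length(axis))
  for (k in seq_len(nrow(win))) {
    inside <- inside | (axis >= win[k, 1] & axis <= win[k, 2])
  }
  expect_equal(length(sp$ppm) - length(ex$ppm), sum(inside))
  far <- matrix(c(10, 11), 1)
  expect_identical(exclude_regions(sp, far), sp)
})

test_that("ALS baseline matches a dense solve of the converged system", {
  set.seed(8)
  n <- 512
  x <- seq(0, 1, length.out = n)
  y <- 5 + 3 * x - 2 * x^2 +
    0.8 * (0.01 / pi) / ((x - 0.3)^2 + 0.01^2) +
    0.5 * (0.01 / pi) / ((x - 0.7)^2 + 0.01^2)
  sp <- nmr_spectrum(x, y, "s")
  lam <- 1e5
  res <- als_baseline_correct(sp, lam = lam, p = 1e-3, n_iter = 50,
                              anchor_zero = FALSE)
  z <- res$baseline$intensity
  w <- ifelse(y > z, 1e-3, 1 - 1e-3)
  z_dense <- dense_als_solve(y, w, lam)
  expect_lt(max(abs(z - z_dense)) / max(abs(z_dense)), 1e-6)
})

test_that("ALS removes a smooth baseline without touching peak areas", {
  n <- 4096
  x <- seq(1.4, 4.7, length.out = n)
  base <- 2 + 0.5 * x - 0.02 * x^2
  # pure smooth input: corrected is numerically zero before anchoring
  sp0 <- nmr_spectrum(x, base, "b")
  r0 <- als_baseline_correct(sp0, anchor_zero = FALSE)
  expect_lt(max(abs(r0$corrected$intensity)), 1e-3 * max(base))
  # baseline + peaks: injected areas preserved within 2%
  hw <- 0.01
  x2 <- seq(1.4, 4.7, length.out = 2048)
  base2 <- 2 + 0.5 * x2 - 0.08 * x2^2
  peaks <- 1.0 * (hw / pi) / ((x2 - 2.0)^2 + hw^2) +
    2.0 * (hw / pi) / ((x2 - 3.0)^2 + hw^2) +
    1.5 * (hw / pi) / ((x2 - 4.0)^2 + hw^2)
  sp <- nmr_spectrum(x2, base2 + peaks, "s")
  r <- als_baseline_correct(sp, anchor_zero = FALSE)
  win <- data.frame(metabolite = c("a", "b", "c"),
                    lo_ppm = c(2.0, 3.0, 4.0) - 20 * hw,
                    hi_ppm = c(2.0, 3.0, 4.0) + 20 * hw)
  got <- integrate_windows(r$corrected, win)
  want <- integrate_windows(nmr_spectrum(x2, peaks, "p"), win)
  expect_true(all(abs(got - want) / want < 0.02))
  # anchoring puts the minimum exactly at zero
  ra <- als_baseline_correct(sp, anchor_zero = TRUE)
  expect_equal(min(ra$corrected$intensity), 0)
  expect_error(als_baseline_correct(nmr_spectrum(x2, c(NA, base2[-1]), "n")),
               "finite")
})

test_that("stiffer ALS penalties give smoother baselines", {
  set.seed(12)
  n <- 600
  x <- seq(0, 1, length.out = n)
  y <- sin(6 * x) + 0.3 * rnorm(n) +
    2 * (0.01 / pi) / ((x - 0.5)^2 + 0.01^2)
  sp <- nmr_spectrum(x, y, "s")
  rough <- vapply(10^seq(2, 9), function(lam) {
    z <- als_baseline_correct(sp, lam = lam, n_iter = 20,
                              anchor_zero = FALSE)$baseline$intensity
    sum(diff(z, differences = 2)^2)
  }, numeric(1))
  expect_true(all(diff(rough) <= 1e-12))
})

test_that("total-area normalization is exact and scale invariant", {
  axis <- seq(1.4, 4.7, by = 0.002)
  set.seed(3)
  sp <- nmr_spectrum(axis, 1 + abs(rnorm(length(axis))), "s")
  nm <- total_area_normalize(sp)
  expect_equal(.trapz <- sum(diff(nm$ppm) *
                               (nm$intensity[-length(nm$intensity)] +
                                  nm$intensity[-1]) / 2), 1,
               tolerance = 1e-12)
  sp2 <- nmr_spectrum(axis, sp$intensity * 7.3, "s")
  expect_equal(total_area_normalize(sp2)$intensity, nm$intensity)
  expect_error(total_area_normalize(nmr_spectrum(axis, rep(0, length(axis)),
                                                 "z")), "positive")
})

test_that("integrate_windows matches closed-form areas", {
  axis <- seq(0, 2, by = 0.001)
  pulse <- ifelse(axis >= 0.75 & axis <= 1.25, 2, 0)
  win <- data.frame(metabolite = "pulse", lo_ppm = 0.75, hi_ppm = 1.25)
  expect_equal(unname(integrate_windows(nmr_spectrum(axis, pulse, "p"),
                                        win)["pulse"]), 1.0,
               tolerance = 1e-6)
  hw <- 0.01
  lor <- (hw / pi) / ((axis - 1)^2 + hw^2)
  win2 <- data.frame(metabolite = "lor", lo_ppm = 1 - 20 * hw,
                     hi_ppm = 1 + 20 * hw)
  got <- unname(integrate_windows(nmr_spectrum(axis, lor, "l"), win2))
  expect_equal(got, (2 / pi) * atan(20), tolerance = 1e-3)
  expect_equal(unname(integrate_windows(nmr_spectrum(axis, 0 * axis, "z"),
                                        win2)), 0)
  tiny <- data.frame(metabolite = "nopts", lo_ppm = 1.0001, hi_ppm = 1.0002)
  expect_error(integrate_windows(nmr_spectrum(axis, lor, "l"), tiny),
               "nopts")
})

test_that("log10 transform enforces positivity", {
  m <- matrix(c(1, 1000, 10, 100), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_equal(log10_transform(m), log10(m))
  m[1, 1] <- 0
  expect_error(log10_transform(m), "s1.*a|a.*s1")
})

test_that("serum pipeline recovers truth proportionally on noiseless data", {
  cfg <- cohort_config(n_carbohydrate = 20, n_fasting = 20, noise_sd = 0,
                       shift_jitter_sd = 0, axis_points = 4096)
  co <- generate_serum_cohort(cfg, seed = 21)
  q <- preprocess_spectra(co$spectra, "serum")
  cors <- vapply(colnames(q), function(m) {
    cor(q[, m], co$truth_concentrations[, m])
  }, numeric(1))
  expect_true(all(cors > 0.999))
})

test_that("tissue pipeline is invariant to global intensity scale", {
  cfg <- tissue_cohort_config(n_carbohydrate = 2, n_fasting = 2,
                              noise_sd = 0, baseline_amplitude = 0,
                              shift_jitter_sd = 0, axis_points = 4096)
  co <- generate_tissue_cohort(cfg, seed = 6)
  sp <- co$spectra[[1]]
  scaled <- nmr_spectrum(sp$ppm, sp$intensity * 5, sp$sample_id)
  q1 <- preprocess_spectra(list(sp), "tissue")
  q2 <- preprocess_spectra(list(scaled), "tissue")
  expect_equal(q1, q2, tolerance = 1e-6)
  # serum protocol applies no normalization: scaling scales the areas
  s1 <- preprocess_spectra(co$spectra[1], "serum",
                           windows = data.frame(metabolite = "Creatine",
                                                lo_ppm = 3.024,
                                                hi_ppm = 3.036))
  s2 <- preprocess_spectra(list(scaled), "serum",
                           windows = data.frame(metabolite = "Creatine",
                                                lo_ppm = 3.024,
                                                hi_ppm = 3.036))
  expect_equal(unname(s2[1, 1] / s1[1, 1]), 5, tolerance = 1e-9)
})

test_that("default windows reject overlapping layouts", {
  lib <- rbind(
    data.frame(name = "a", center_ppm = 1.00, halfwidth_ppm = 0.01,
               rel_area = 1, base_level = 1, fold_change = 1, cv = 0),
    data.frame(name = "b", center_ppm = 1.02, halfwidth_ppm = 0.01,
               rel_area = 1, base_level = 1, fold_change = 1, cv = 0)
  )
  expect_error(default_windows(lib), "overlap")
  expect_silent(default_windows(build_default_serum_library()))
  expect_silent(default_windows(build_default_tissue_library()))
})
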