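#' Synthetic cohort generation
#'
#' The generator emulates the study design the analysis pipeline assumes:
#' two-arm serum cohorts (carbohydrate loading n = 26 vs preoperative
#' fasting n = 35) and tumor-tissue cohorts (n = 16 vs 13), each sample
#' carrying a frequency-domain 1H-NMR spectrum synthesized from ground-truth
#' metabolite concentrations, clinical covariates calibrated to target
#' insulin correlations, and survival outcomes drawn from an exponential
#' proportional-hazards model.
#'
#' @name synthetic-cohorts
NULL

# run expr with a temporarily seeded RNG, restoring the caller's stream
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# unit-area Lorentzian line shape
.lorentzian <- function(x, center, halfwidth) {
  (halfwidth / pi) / ((x - center)^2 + halfwidth^2)
}

#' Cohort generator configuration
#'
#' @param n_carbohydrate,n_fasting Group sizes (defaults 26 and 35, the
#'   serum study arms).
#' @param library Metabolite library data frame, see
#'   [build_default_serum_library()].
#' @param noise_sd Additive Gaussian spectral noise SD, relative to the
#'   median peak apex height.
#' @param baseline_amplitude Scale of the smooth random baseline, relative
#'   to the median peak apex height.
#' @param shift_jitter_sd SD of the per-sample global chemical-shift jitter
#'   (ppm).
#' @param axis_lo,axis_hi,axis_points The ppm grid (default 0--4.4 ppm at
#'   4096 points, slightly wider than the 0.1--4.2 ppm analysis window so
#'   cropping is exercised).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_carbohydrate = 26, n_fasting = 35,
                          library = build_default_serum_library(),
                          noise_sd = 0.01, baseline_amplitude = 0,
                          shift_jitter_sd = 0.003,
                          axis_lo = 0.0, axis_hi = 4.4, axis_points = 4096) {
  if (n_carbohydrate < 2 || n_fasting < 2) {
    stop("each group needs at least 2 subjects")
  }
  if (axis_lo >= axis_hi) stop("axis_lo must be < axis_hi")
  if (axis_points < 256) stop("axis_points must be >= 256")
  if (noise_sd < 0 || baseline_amplitude < 0 || shift_jitter_sd < 0) {
    stop("noise_sd, baseline_amplitude and shift_jitter_sd must be >= 0")
  }
  validate_library(library)
  structure(
    list(n_carbohydrate = n_carbohydrate, n_fasting = n_fasting,
         library = library, noise_sd = noise_sd,
         baseline_amplitude = baseline_amplitude,
         shift_jitter_sd = shift_jitter_sd,
         axis_lo = axis_lo, axis_hi = axis_hi, axis_points = axis_points),
    class = "cohort_config"
  )
}

#' Tissue cohort configuration
#'
#' [cohort_config()] preset for the tumor-tissue arm: group sizes 16/13,
#' the tissue library, the 1.3--4.8 ppm grid, and a visible random baseline
#' (tissue spectra, unlike the serum ones, are not baseline-corrected
#' upstream of this pipeline).
#'
#' @inheritParams cohort_config
#' @return A list of class `cohort_config`.
#' @export
tissue_cohort_config <- function(n_carbohydrate = 16, n_fasting = 13,
                                 library = build_default_tissue_library(),
                                 noise_sd = 0.01, baseline_amplitude = 0.05,
                                 shift_jitter_sd = 0.003,
                                 axis_lo = 1.3, axis_hi = 4.8,
                                 axis_points = 4096) {
  cohort_config(n_carbohydrate, n_fasting, library, noise_sd,
                baseline_amplitude, shift_jitter_sd,
                axis_lo, axis_hi, axis_points)
}

#' Synthesize one NMR spectrum from metabolite concentrations
#'
#' Forward model: each metabolite contributes its concentration times a sum
#' of unit-area Lorentzian peaks (so that, with noise and baseline off, the
#' integrated area of an isolated metabolite's peaks recovers its
#' concentration up to the finite-window capture fraction).  A smooth
#' random cubic baseline and iid Gaussian noise are added on top, both
#' scaled relative to the median peak apex height (or to 1 when all
#' concentrations are zero).
#'
#' @param concentrations Named numeric vector of metabolite amounts, keyed
#'   by library metabolite names.
#' @param library Metabolite library data frame.
#' @param axis Strictly monotone ppm grid.
#' @param baseline_amplitude,noise_sd Relative baseline and noise scales.
#' @param shift_jitter Global ppm offset added to every peak center.
#' @param seed Optional RNG seed (baseline coefficients, then noise).
#' @param sample_id Sample identifier attached to the spectrum.
#' @return An [nmr_spectrum()].
#' @export
synthesize_spectrum <- function(concentrations, library, axis,
                                baseline_amplitude = 0, noise_sd = 0,
                                shift_jitter = 0, seed = NULL,
                                sample_id = "sample") {
  validate_library(library)
  unknown <- setdiff(names(concentrations), library$name)
  if (length(unknown) > 0) {
    stop("concentrations name metabolites absent from the library: ",
         paste(unknown, collapse = ", "))
  }
  if (is.null(names(concentrations))) {
    stop("concentrations must be a named vector")
  }
  .with_seed(seed, {
    y <- numeric(length(axis))
    conc_per_peak <- concentrations[library$name]
    conc_per_peak[is.na(conc_per_peak)] <- 0
    apex <- conc_per_peak * library$rel_area / (pi * library$halfwidth_ppm)
    for (k in seq_len(nrow(library))) {
      if (conc_per_peak[k] == 0) next
      y <- y + conc_per_peak[k] * library$rel_area[k] *
        .lorentzian(axis, library$center_ppm[k] + shift_jitter,
                    library$halfwidth_ppm[k])
    }
    ref_height <- if (any(apex > 0)) stats::median(apex[apex > 0]) else 1
    if (baseline_amplitude > 0) {
      u <- 2 * (axis - min(axis)) / (max(axis) - min(axis)) - 1
      coef <- stats::rnorm(4) / (1 + 0:3)
      y <- y + baseline_amplitude * ref_height *
        (coef[1] + coef[2] * u + coef[3] * u^2 + coef[4] * u^3)
    }
    if (noise_sd > 0) {
      y <- y + stats::rnorm(length(axis), sd = noise_sd * ref_height)
    }
    nmr_spectrum(axis, y, sample_id)
  })
}

# categorical assignment with the study's per-arm frequencies: the target
# fractions are converted to exact counts for the requested group size
# (rounded), then randomly ordered within the group
.assign_frac <- function(n, fracs, levels) {
  counts <- round(fracs * n)
  while (sum(counts) > n) counts[which.max(counts)] <- counts[which.max(counts)] - 1
  v <- rep(levels, times = c(counts, n - sum(counts)))
  sample(v, n)
}

# group means implied by base level and signed fold change
.group_means <- function(base_level, fold_change) {
  m_f <- base_level
  m_ch <- ifelse(fold_change >= 0, base_level * fold_change,
                 base_level / abs(fold_change))
  list(carbohydrate = m_ch, fasting = m_f)
}

# lognormal draw with given mean and coefficient of variation
.rlnorm_mean_cv <- function(n, mean, cv) {
  if (cv == 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

.generate_cohort <- function(config, seed, protocol, er_gated = NULL,
                             er_fracs = NULL) {
  .with_seed(seed, {
    n_ch <- config$n_carbohydrate
    n_f <- config$n_fasting
    n <- n_ch + n_f
    ids <- sprintf("%s%03d", if (protocol == "serum") "S" else "T", seq_len(n))
    group <- c(rep("carbohydrate", n_ch), rep("fasting", n_f))
    lib <- config$library
    mets <- library_metabolites(lib)
    per_met <- lib[!duplicated(lib$name), ]
    rownames(per_met) <- per_met$name

    # categorical covariates: exact per-group counts from the study's
    # clinical table, randomly ordered within each arm
    if (protocol == "serum") {
      er <- c(.assign_frac(n_ch, 21 / 26, c("positive", "negative")),
              .assign_frac(n_f, 29 / 35, c("positive", "negative")))
      size <- c(.assign_frac(n_ch, 16 / 26, c("T1", "T2")),
                .assign_frac(n_f, 30 / 35, c("T1", "T2")))
      ki <- c(.assign_frac(n_ch, c(12, 5) / 26, c(">=30", "15-30", "<15")),
              .assign_frac(n_f, c(10, 7) / 35, c(">=30", "15-30", "<15")))
      mai <- c(.assign_frac(n_ch, 11 / 26, c(">=10", "<10")),
               .assign_frac(n_f, 8 / 35, c(">=10", "<10")))
      pph3 <- c(.assign_frac(n_ch, 12 / 26, c(">=13", "<13")),
                .assign_frac(n_f, 14 / 35, c(">=13", "<13")))
    } else {
      er <- c(.assign_frac(n_ch, er_fracs[1], c("positive", "negative")),
              .assign_frac(n_f, er_fracs[2], c("positive", "negative")))
      size <- c(.assign_frac(n_ch, 7 / 16, c("T1", "T2")),
                .assign_frac(n_f, 9 / 13, c("T1", "T2")))
      ki <- c(.assign_frac(n_ch, c(6, 0) / 16, c(">=30", "15-30", "<15")),
              .assign_frac(n_f, c(8, 0) / 13, c(">=30", "15-30", "<15")))
      mai <- c(.assign_frac(n_ch, 10 / 16, c(">=10", "<10")),
               .assign_frac(n_f, 3 / 13, c(">=10", "<10")))
      pph3 <- c(.assign_frac(n_ch, 9 / 16, c(">=13", "<13")),
                .assign_frac(n_f, 7 / 13, c(">=13", "<13")))
    }

    truth <- matrix(NA_real_, nrow = n, ncol = length(mets),
                    dimnames = list(ids, mets))
    for (m in mets) {
      gm <- .group_means(per_met[m, "base_level"], per_met[m, "fold_change"])
      mean_i <- ifelse(group == "carbohydrate", gm$carbohydrate, gm$fasting)
      if (!is.null(er_gated) && m %in% er_gated) {
        # effect restricted to ER-positive samples
        mean_i[er == "negative"] <- gm$fasting
      }
      truth[, m] <- .rlnorm_mean_cv(n, 1, per_met[m, "cv"]) * mean_i
    }

    axis <- seq(config$axis_lo, config$axis_hi, length.out = config$axis_points)
    jitter <- stats::rnorm(n, sd = config$shift_jitter_sd)
    spectra <- vector("list", n)
    names(spectra) <- ids
    for (i in seq_len(n)) {
      spectra[[i]] <- synthesize_spectrum(
        truth[i, ], lib, axis,
        baseline_amplitude = config$baseline_amplitude,
        noise_sd = config$noise_sd,
        shift_jitter = jitter[i], sample_id = ids[i]
      )
    }

    metadata <- data.frame(
      sample_id = ids, group = group, er_status = er, tumor_size = size,
      ki67_cat = ki, mai_cat = mai, pph3_cat = pph3,
      stringsAsFactors = FALSE
    )
    structure(
      list(spectra = spectra, truth_concentrations = truth,
           metadata = metadata, library = lib, protocol = protocol,
           config = config, seed = seed),
      class = "simulated_cohort"
    )
  })
}

#' Generate a synthetic serum cohort
#'
#' Draws per-subject metabolite concentrations lognormally around the group
#' means implied by each metabolite's base level and signed fold change,
#' synthesizes a spectrum per subject, and attaches categorical clinical
#' covariates with the study's per-arm frequencies.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed; identical `(config, seed)` pairs give identical
#'   cohorts.
#' @return A `simulated_cohort`: list with `spectra` (named list of
#'   [nmr_spectrum()]), `truth_concentrations` (samples x metabolites
#'   matrix), `metadata` (data frame) and the generating `library`.
#' @export
generate_serum_cohort <- function(config = cohort_config(), seed = 1) {
  .generate_cohort(config, seed, "serum")
}

#' Generate a synthetic tumor-tissue cohort
#'
#' As [generate_serum_cohort()], with the tissue arm sizes (16/13), the
#' 1.3--4.8 ppm grid, and the glutathione group effect applied only to
#' ER-positive samples (ER status assigned with the study's tissue-arm
#' counts, 11 of 16 and 9 of 13 positive).
#'
#' @param config A [tissue_cohort_config()].
#' @param seed RNG seed.
#' @return A `simulated_cohort`.
#' @export
generate_tissue_cohort <- function(config = tissue_cohort_config(), seed = 1) {
  .generate_cohort(config, seed, "tissue",
                   er_gated = "Glutathione", er_fracs = c(11 / 16, 9 / 13))
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("<simulated_cohort> %s: %d samples, %d metabolites\n",
              x$protocol, nrow(x$truth_concentrations),
              ncol(x$truth_concentrations)))
  invisible(x)
}

#' Clinical covariate configuration
#'
#' Targets for the insulin-response generator: per-group insulin and
#' C-peptide means and the population Pearson correlations between insulin
#' and the lactate / pyruvate concentrations.
#'
#' @param insulin_mean_ch,insulin_mean_f Group insulin means (mIU).
#' @param cpeptide_mean_ch,cpeptide_mean_f Group C-peptide means (nmol/L).
#' @param target_r_lactate_insulin,target_r_pyruvate_insulin Population
#'   Pearson correlations to calibrate to (|r| < 1).
#' @param noise_fraction Fraction of the within-group insulin variance left
#'   to metabolite-independent noise.
#' @param glucose_mean_ch,glucose_mean_f,glucose_sd Serum glucose (mmol/L).
#' @param igfbp3_mean,igfbp3_sd IGFBP-3 level (mg/L).
#' @param cpeptide_noise_sd Independent C-peptide noise (nmol/L).
#' @return A list of class `clinical_config`.
#' @export
clinical_config <- function(insulin_mean_ch = 35.6, insulin_mean_f = 9.1,
                            cpeptide_mean_ch = 2.10, cpeptide_mean_f = 0.76,
                            target_r_lactate_insulin = 0.57,
                            target_r_pyruvate_insulin = 0.54,
                            noise_fraction = 0.25,
                            glucose_mean_ch = 6.8, glucose_mean_f = 5.4,
                            glucose_sd = 0.5,
                            igfbp3_mean = 4.5, igfbp3_sd = 0.45,
                            cpeptide_noise_sd = 0.15) {
  if (insulin_mean_ch <= 0 || insulin_mean_f <= 0 ||
      cpeptide_mean_ch <= 0 || cpeptide_mean_f <= 0) {
    stop("group means must be > 0")
  }
  if (abs(target_r_lactate_insulin) >= 1 ||
      abs(target_r_pyruvate_insulin) >= 1) {
    stop("target correlations must satisfy |r| < 1")
  }
  if (noise_fraction <= 0 || noise_fraction >= 1) {
    stop("noise_fraction must be in (0, 1)")
  }
  structure(
    list(insulin_mean_ch = insulin_mean_ch, insulin_mean_f = insulin_mean_f,
         cpeptide_mean_ch = cpeptide_mean_ch,
         cpeptide_mean_f = cpeptide_mean_f,
         target_r_lactate_insulin = target_r_lactate_insulin,
         target_r_pyruvate_insulin = target_r_pyruvate_insulin,
         noise_fraction = noise_fraction,
         glucose_mean_ch = glucose_mean_ch, glucose_mean_f = glucose_mean_f,
         glucose_sd = glucose_sd, igfbp3_mean = igfbp3_mean,
         igfbp3_sd = igfbp3_sd, cpeptide_noise_sd = cpeptide_noise_sd),
    class = "clinical_config"
  )
}

# Solve the insulin model I = mu_g + a zL + b zP + c e for (a, b, c) such
# that the population Pearson correlations r(I, lactate) and r(I, pyruvate)
# hit their targets, where zL, zP are within-group standardized metabolite
# concentrations.  Closed-form population moments (lognormal within groups,
# two-point group mixture) reduce the system to a single root-find in the
# within-group insulin SD W, with c^2 = noise_fraction * W^2.
.solve_insulin_slopes <- function(pi_ch, mu_ch, mu_f, mom_l, mom_p,
                                  r_l, r_p, noise_fraction) {
  v_mu <- pi_ch * (1 - pi_ch) * (mu_ch - mu_f)^2
  stat <- function(mom) {
    # mom: list(m_ch, m_f, s_ch, s_f)
    e_s <- pi_ch * mom$s_ch + (1 - pi_ch) * mom$s_f
    v <- pi_ch * (1 - pi_ch) * (mom$m_ch - mom$m_f)^2 +
      pi_ch * mom$s_ch^2 + (1 - pi_ch) * mom$s_f^2
    cc <- pi_ch * (1 - pi_ch) * (mu_ch - mu_f) * (mom$m_ch - mom$m_f)
    list(e_s = e_s, sd = sqrt(v), c = cc)
  }
  sl <- stat(mom_l); sp <- stat(mom_p)
  if (sl$e_s <= 0 || sp$e_s <= 0) {
    stop("within-group metabolite variance is zero; cannot calibrate insulin")
  }
  slopes <- function(w) {
    s_tot <- sqrt(w^2 + v_mu)
    a <- (r_l * s_tot * sl$sd - sl$c) / sl$e_s
    b <- (r_p * s_tot * sp$sd - sp$c) / sp$e_s
    c(a, b)
  }
  f <- function(w) {
    ab <- slopes(w)
    sum(ab^2) - (1 - noise_fraction) * w^2
  }
  scale0 <- max(1, sqrt(v_mu), abs(mu_ch - mu_f))
  grid <- scale0 * 10^seq(-4, 4, length.out = 400)
  fv <- vapply(grid, f, numeric(1))
  sign_change <- which(fv[-1] * fv[-length(fv)] < 0)
  if (length(sign_change) == 0) {
    stop("target insulin correlations are unattainable under this cohort")
  }
  # largest root: the branch where within-group coupling carries the
  # largest share of the correlation
  k <- sign_change[length(sign_change)]
  w <- stats::uniroot(f, c(grid[k], grid[k + 1]), tol = 1e-10)$root
  ab <- slopes(w)
  list(a = ab[1], b = ab[2], c = sqrt(noise_fraction) * w, w = w)
}

# within-group lognormal moments for one metabolite of a library
.metabolite_moments <- function(per_met, met) {
  gm <- .group_means(per_met[met, "base_level"], per_met[met, "fold_change"])
  cv <- per_met[met, "cv"]
  list(m_ch = gm$carbohydrate, m_f = gm$fasting,
       s_ch = cv * gm$carbohydrate, s_f = cv * gm$fasting)
}

#' Generate clinical covariates for a serum cohort
#'
#' Adds insulin, C-peptide, IGFBP-3 and glucose columns to the cohort
#' metadata.  Insulin is generated as the group mean plus slopes on the
#' within-group standardized lactate and pyruvate concentrations plus
#' noise; the slopes and noise SD are solved in closed form so that the
#' population Pearson correlations between insulin and the lactate /
#' pyruvate concentrations equal the configured targets.  C-peptide is an
#' affine function of insulin (mapping the group insulin means onto the
#' group C-peptide means) plus independent noise.
#'
#' @param cohort A serum `simulated_cohort` (needs `Lactate` and `Pyruvate`
#'   truth columns).
#' @param config A [clinical_config()].
#' @param seed RNG seed.
#' @return The cohort metadata data frame with columns `insulin_mIU`,
#'   `cpeptide_nM`, `igfbp3_mgL`, `glucose_mM` appended.
#' @export
generate_clinical_covariates <- function(cohort, config = clinical_config(),
                                         seed = 1) {
  truth <- cohort$truth_concentrations
  if (!all(c("Lactate", "Pyruvate") %in% colnames(truth))) {
    stop("cohort truth concentrations must include Lactate and Pyruvate")
  }
  md <- cohort$metadata
  per_met <- cohort$library[!duplicated(cohort$library$name), ]
  rownames(per_met) <- per_met$name
  .with_seed(seed, {
    n <- nrow(md)
    is_ch <- md$group == "carbohydrate"
    pi_ch <- mean(is_ch)
    mom_l <- .metabolite_moments(per_met, "Lactate")
    mom_p <- .metabolite_moments(per_met, "Pyruvate")
    sol <- .solve_insulin_slopes(
      pi_ch, config$insulin_mean_ch, config$insulin_mean_f,
      mom_l, mom_p,
      config$target_r_lactate_insulin, config$target_r_pyruvate_insulin,
      config$noise_fraction
    )
    z_of <- function(x, mom) {
      m <- ifelse(is_ch, mom$m_ch, mom$m_f)
      s <- ifelse(is_ch, mom$s_ch, mom$s_f)
      (x - m) / s
    }
    z_l <- z_of(truth[, "Lactate"], mom_l)
    z_p <- z_of(truth[, "Pyruvate"], mom_p)
    mu <- ifelse(is_ch, config$insulin_mean_ch, config$insulin_mean_f)
    insulin <- mu + sol$a * z_l + sol$b * z_p + sol$c * stats::rnorm(n)

    v <- (config$cpeptide_mean_ch - config$cpeptide_mean_f) /
      (config$insulin_mean_ch - config$insulin_mean_f)
    u <- config$cpeptide_mean_f - v * config$insulin_mean_f
    cpep <- u + v * insulin + config$cpeptide_noise_sd * stats::rnorm(n)

    glu <- ifelse(is_ch, config$glucose_mean_ch, config$glucose_mean_f) +
      config$glucose_sd * stats::rnorm(n)
    igfbp3 <- config$igfbp3_mean + config$igfbp3_sd * stats::rnorm(n)

    md$insulin_mIU <- insulin
    md$cpeptide_nM <- cpep
    md$igfbp3_mgL <- igfbp3
    md$glucose_mM <- glu
    md
  })
}

#' Survival outcome configuration
#'
#' @param baseline_hazard Events per year in the reference stratum (all
#'   markers low).  The default 0.0075/year gives roughly a 5% event
#'   fraction over the 7-year horizon in the reference stratum.
#' @param marker_hrs Named vector mapping dichotomized marker columns
#'   (coded 0/1) to hazard ratios.  Defaults are the published
#'   relapse-free-survival hazard ratios for high serum pyruvate (13.59)
#'   and high serum lactate (7.47).
#' @param followup_years Administrative censoring horizon (years).
#' @param p_bcss_death Probability that a relapse progresses to a breast
#'   cancer death within follow-up dynamics.
#' @param bcss_delay_mean Mean relapse-to-death delay (years, exponential).
#' @param other_death_hazard Background (non-breast-cancer) death hazard
#'   per year, used for overall survival.
#' @return A list of class `survival_config`.
#' @export
survival_config <- function(baseline_hazard = 0.0075,
                            marker_hrs = c(pyruvate_high = 13.59,
                                           lactate_high = 7.47),
                            followup_years = 7,
                            p_bcss_death = 0.57,
                            bcss_delay_mean = 1,
                            other_death_hazard = 0.005) {
  if (baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (any(marker_hrs <= 0)) stop("all hazard ratios must be > 0")
  if (followup_years < 0) stop("followup_years must be >= 0")
  structure(
    list(baseline_hazard = baseline_hazard, marker_hrs = marker_hrs,
         followup_years = followup_years, p_bcss_death = p_bcss_death,
         bcss_delay_mean = bcss_delay_mean,
         other_death_hazard = other_death_hazard),
    class = "survival_config"
  )
}

#' Generate survival outcomes from dichotomized markers
#'
#' Relapse times are exponential with hazard
#' `baseline_hazard * prod(HR^marker)`, administratively censored at the
#' follow-up horizon.  Breast-cancer death follows a relapse with
#' probability `p_bcss_death` after an exponential delay; overall survival
#' additionally carries a background death hazard.
#'
#' @param metadata Data frame containing, for every name in
#'   `config$marker_hrs`, a column coded 0/1 (or logical) marking the
#'   high-risk stratum.
#' @param config A [survival_config()].
#' @param seed RNG seed.
#' @return Data frame with `sample_id` and `time_*_years` / `event_*`
#'   columns for the RFS, BCSS and OS endpoints.
#' @export
generate_survival_outcomes <- function(metadata, config = survival_config(),
                                       seed = 1) {
  missing_cols <- setdiff(names(config$marker_hrs), names(metadata))
  if (length(missing_cols) > 0) {
    stop("metadata is missing dichotomized marker column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  .with_seed(seed, {
    n <- nrow(metadata)
    log_h <- rep(log(config$baseline_hazard), n)
    for (m in names(config$marker_hrs)) {
      x <- as.numeric(metadata[[m]])
      if (any(is.na(x)) || !all(x %in% c(0, 1))) {
        stop("marker column '", m, "' must be coded 0/1")
      }
      log_h <- log_h + x * log(config$marker_hrs[[m]])
    }
    horizon <- config$followup_years
    t_rel <- stats::rexp(n, rate = exp(log_h))
    ev_rfs <- as.integer(t_rel <= horizon & horizon > 0)
    time_rfs <- pmin(t_rel, horizon)

    dies_bc <- stats::runif(n) < config$p_bcss_death
    delay <- stats::rexp(n, rate = 1 / config$bcss_delay_mean)
    t_bc_death <- ifelse(ev_rfs == 1 & dies_bc, t_rel + delay, Inf)
    ev_bcss <- as.integer(t_bc_death <= horizon)
    time_bcss <- pmin(t_bc_death, horizon)

    t_other <- stats::rexp(n, rate = config$other_death_hazard)
    t_death <- pmin(t_bc_death, t_other)
    ev_os <- as.integer(t_death <= horizon)
    time_os <- pmin(t_death, horizon)

    data.frame(
      sample_id = metadata$sample_id,
      time_rfs_years = time_rfs, event_rfs = ev_rfs,
      time_bcss_years = time_bcss, event_bcss = ev_bcss,
      time_os_years = time_os, event_os = ev_os,
      stringsAsFactors = FALSE
    )
  })
}

#' Extract one endpoint as survival records
#'
#' @param outcomes Output of [generate_survival_outcomes()] (or a table
#'   with the same column layout).
#' @param endpoint One of `"rfs"`, `"bcss"`, `"os"`.
#' @return Data frame `sample_id`, `time`, `event`.
#' @export
survival_records <- function(outcomes, endpoint = c("rfs", "bcss", "os")) {
  endpoint <- match.arg(endpoint)
  data.frame(
    sample_id = outcomes$sample_id,
    time = outcomes[[paste0("time_", endpoint, "_years")]],
    event = outcomes[[paste0("event_", endpoint)]],
    stringsAsFactors = FALSE
  )
}
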