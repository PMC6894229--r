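# perimetab

Analysis pipeline for ¹H-NMR metabolomics in a perioperative
carbohydrate-loading versus fasting design, as used in explorative breast
cancer studies: serum CPMG and tumor-tissue HR-MAS spectra are quantified,
compared between study arms, and linked to insulin response and clinical
outcome. Because patient-level data from such trials are not public, the
package ships a first-class synthetic cohort generator with the same
statistical structure (arm sizes 26/35 for serum and 16/13 for tissue,
published fold changes, insulin correlations, and hazard ratios), so every
stage of the pipeline is testable end to end.

## What it does

* **Synthetic cohorts** — spectra are sums of unit-area Lorentzian peaks
  from a metabolite library (28 serum / 20 tissue metabolites with
  published carbohydrate-vs-fasting fold changes), with lognormal
  between-subject variation, chemical-shift jitter, smooth random
  baselines and Gaussian noise. Insulin and C-peptide are calibrated in
  closed form so that the population Pearson correlation with lactate and
  pyruvate hits configurable targets (defaults r = 0.57 / 0.54). Survival
  outcomes follow an exponential proportional-hazards model with
  administrative censoring (default hazard ratios 13.59 for high pyruvate,
  7.47 for high lactate).
* **Preprocessing** — serum: referencing to the left alanine line at
  1.47 ppm, cropping to 0.1–4.2 ppm, trapezoid peak-window integration.
  Tissue: cropping to 1.4–4.70 ppm, referencing to creatine at 3.03 ppm,
  asymmetric least squares baseline correction (λ = 1e7, p = 1e-4, lowest
  point anchored to zero), exclusion of lipid/ethanol windows, total-area
  normalization, integration, log10 transform.
* **Univariate statistics** — pooled-variance t-tests, signed fold changes
  (|FC| ≥ 1 convention), Benjamini–Hochberg control, Pearson correlation
  screens by stratum.
* **Chemometrics** — autoscaling, PCA outlier screening, NIPALS PLS and
  PLS-DA with leave-one-out cross-validation, permutation testing
  (p = (1 + #{perm ≥ obs}) / (1 + N), significance via the
  "observed > 95% of permuted" rule) and VIP scores
  (VIP_j = sqrt(V · Σ_a w_aj² SS_a / Σ_a SS_a), so Σ VIP² = V).
* **Outcomes** — ROC curves with Youden-optimal thresholds and
  maximal-Wald Cox confirmation scans, Kaplan–Meier / log-rank, Breslow
  Cox regression with monotone-likelihood detection (reported as HR = ∞
  with a likelihood-ratio p), and forward-Wald covariate selection with a
  backward fallback for unstable models.

## Worked example

```r
library(perimetab)

cohort <- generate_serum_cohort(cohort_config(), seed = 1)
quant  <- preprocess_spectra(cohort$spectra, "serum")
group  <- cohort$metadata$group

tab <- group_comparison_table(quant, group)
subset(tab, metabolite %in% c("Lactate", "Pyruvate", "Valine"))
#>    metabolite      p_value fold_change        p_adj significant
#> 17    Lactate 8.018271e-25    1.347446 2.245116e-23        TRUE
#> 26   Pyruvate 6.440480e-24    1.294251 9.016671e-23        TRUE
#> 28     Valine 2.571057e-23   -1.292620 2.399653e-22        TRUE

pt <- permutation_test(quant, group, n_components = 1,
                       n_perm = 999, seed = 3)
pt
#> <permutation_result> observed accuracy = 1.000, p = 0.001 (999 permutations) *
```

The simulated carbohydrate arm shows the expected elevation of serum
lactate and pyruvate (fold changes near the configured 1.36 and 1.27) and
depression of valine (-1.29 against the configured -1.31), and
the leave-one-out PLS-DA accuracy of 1.00 beats all 999 label
permutations, so the group difference in the metabolic profile is
significant at p = 0.001. The published comparison table bundled for
worked examples reproduces its reported tally:

```r
ref <- load_reference_serum_results()
count_significant(ref$p_value, 0.016)
#> [1] 14
```

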