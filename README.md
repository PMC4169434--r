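# lesionmapr

Population-level analysis of white-matter lesion localization in multiple
sclerosis (MS) cohorts. Given per-subject binary lesion masks registered to a
common template grid, a template white-matter (WM) mask, and a clinical table
(EDSS disability score, age, sex, disease duration), the package provides:

- **Lesion prevalence maps** (3-D lesion histograms): per-voxel counts of
  lesion carriers, and the *analysis mask* of voxels with more than
  `min_subjects` carriers that defines the voxel-wise testing family.
- **GLSR**, the goodness-of-lesion-spatial-registration statistic: the
  proportion of a subject's lesion voxels falling outside template WM
  (0 = perfect, 1 = total failure), with cohort summaries (mean, median, SD,
  MSE against GLSR ≡ 0, mean within-subject rank) for comparing registration
  algorithms.
- **LDI**, the location-discrepancy index: the fraction of a subject's
  lesion voxels shared with at most *k* other subjects — a measure of
  lesion-pattern atypicality in [0, 1].
- **Voxel-wise regressions** of EDSS on lesion presence,
  `Y_i = β0 + β1 x_iv + γ'Z_i + ε_i`, over a confounder ledger
  (M1: none; M2: +TLV; M3: +LDI; M4: +age/sex/duration; M5: all), with
  Bonferroni and Benjamini–Hochberg correction, sample-size extrapolation
  (SE / √(n'/n)), cohort-level EDSS~TLV and EDSS~LDI screens, and a
  proportional-odds ordinal variant (EDSS < 4 / 4–5.5 / ≥ 6).
- **A synthetic cohort generator** (ellipsoid-shell WM template,
  periventricularly clustered spherical lesions, EDSS linked to planted
  effects, misregistration perturbations) so the whole pipeline is testable
  without image data, plus minimal self-contained NIfTI-1 I/O.

See `vignettes/lesionmapr-methods.Rmd` for the statistical details and
design rationale.

## Worked example

```r
library(lesionmapr)

cfg    <- sim_config(n_subjects = 98, seed = 42,
                     effect = list(beta_lesion = 2, n_voxels = 20))
space  <- make_template(cfg)
cohort <- simulate_cohort(space, cfg)                  # 98 subjects, EDSS ~ Table-like marginals
shifted <- perturb_registration(cohort, "translate", c(4, 0, 0))

prev <- lesion_count_map(cohort)
mask <- analysis_mask(prev, min_subjects = 3)
attr(mask, "n_retained")
#> [1] 3408

compare_registrations(rbind(glsr_cohort(cohort), glsr_cohort(shifted)))
#>         registration_label  n  mean median    sd    mse mean_rank
#> 1                simulated 98 0.000  0.000 0.000 0.0000      1.02
#> 2 simulated+translate4,0,0 98 0.206  0.161 0.163 0.0688      1.98

metrics <- ldi(cohort, prev)
fit <- fit_voxelwise(cohort, metrics, model_spec("M2"), mask)
fit
#> stat_map: M2 ( continuous ) | 3408 tests | n = 91 | df = 88 | registration: simulated
correct_pvalues(fit, "bh_fdr", 0.05)
#> correction_result: bh_fdr at alpha = 0.05 | 20 of 3408 tests significant

reg <- cohort_regression(cohort$subjects$edss, metrics$tlv_mm3)
sprintf("EDSS ~ TLV: slope %.4f (p = %.3g, n = %d)", reg$slope, reg$p, reg$n)
#> [1] "EDSS ~ TLV: slope -0.0015 (p = 0.175, n = 91)"
```

Reading the output: the simulated cohort registers perfectly (GLSR 0 — its
lesions are generated inside WM), while the 4-voxel translation pushes ~21%
of lesion volume out of WM and is ranked worse. Seven of 98 subjects have
missing EDSS, so 91 enter the regression (listwise, per model). The
generator planted a 2-point EDSS effect at 20 voxels; BH–FDR at 0.05
recovers exactly those 20 of the 3408 tested voxels, TLV-adjusted.

## Pipeline and CLI

Everything is drivable from one JSON config (all defaults echoed into the
run report; see `default_config()`):

```r
run_pipeline(list(simulate = list(seed = 1),
                  perturbations = list(list(mode = "dilate", magnitude = 1)),
                  models = c("M1", "M2"), ordinal = TRUE),
             out_dir = "results/run1")
```

or from the shell via the installed script
(`system.file("cli", "lesionmap", package = "lesionmapr")`):

```sh
lesionmap run --config config.json --out results/run1
# or staged: simulate | prevalence | glsr | ldi | voxelwise | report
```

Outputs: NIfTI prevalence/analysis-mask/coefficient/p-value maps, CSV metric
tables, and `report.json` tying every number to the echoed configuration.

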