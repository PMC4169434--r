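---
title: "Methods: lesion localization analysis with lesionmapr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion localization analysis with lesionmapr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In multiple sclerosis (MS), white-matter lesions visible on MRI are thought
to drive disability in a location-dependent way. Testing that hypothesis at
the population level requires registering every subject's binary lesion mask
to a common template grid and then relating, voxel by voxel, lesion presence
to a disability score — here the Expanded Disability Status Scale (EDSS), an
ordinal score from 0 to 10 in half points. Two methodological obstacles
dominate: registration algorithms tuned on healthy brains behave erratically
on atrophic, lesioned brains, and the marginal association between lesion
presence and disability is heavily confounded (by total lesion burden,
lesion-pattern atypicality, age, sex, and disease duration).

`lesionmapr` implements the full analysis chain downstream of registration:
lesion prevalence mapping, registration-quality scoring, confounder metrics,
a hierarchy of voxel-wise regressions with multiplicity correction, and a
synthetic cohort generator that makes every stage testable without any image
data.

# Models and statistics

## Prevalence map and analysis mask

The prevalence map (3-D lesion histogram) counts, per voxel $v$, the number
of subjects with a lesion at $v$. Voxel-wise testing is restricted to the
*analysis mask*: voxels where strictly more than `min_subjects` subjects
carry a lesion. The default is `min_subjects = 3`; with fewer carriers the
per-voxel contrast is dominated by a handful of subjects and the t reference
is meaningless. The threshold travels with every output (it determines the
number of simultaneous tests), so no result is interpretable without it.

## GLSR: goodness of lesion spatial registration

MS lesions visible on structural MRI lie in white matter (WM), so after a
correct registration a subject's lesion voxels should still fall inside the
template's WM mask. For subject $i$ under registration $a$,

$$\mathrm{GLSR}_{ia} = \frac{\#\{v : \text{lesion}_{ia}(v)=1,\ \mathrm{WM}(v)=0\}}
                            {\#\{v : \text{lesion}_{ia}(v)=1\}},$$

0 for perfect placement, 1 for total failure. Cohort summaries are the mean,
median, sample SD, the mean squared error against the ideal GLSR $\equiv 0$
(so $\mathrm{MSE} = \overline{\mathrm{GLSR}^2} = \text{mean}^2 +
\text{population variance}$), and the mean within-subject rank across
algorithms (rank 1 = smallest GLSR, average ranks on ties).

**Denominator choice.** A registered-space denominator (the default) is the
only self-contained one: deformable registrations can inflate lesion volume
several-fold, so a native-space lesion count is a different quantity and not
derivable from the registered mask. The native variant is available
(`denominator = "native"`) when native counts are supplied. Subjects whose
registered mask is empty get a *flagged missing* GLSR rather than 0 — an
empty mask carries no placement information and treating it as perfect would
reward total lesion loss.

## LDI: location-discrepancy index

For subject $i$, a lesion voxel is *rare* when at most $k$ **other**
subjects carry a lesion there; with $U_i$ the count of rare voxels and
$\mathrm{TLV}_i$ the subject's total lesion volume in voxels,
$\mathrm{LDI}_i = U_i / \mathrm{TLV}_i \in [0,1]$. Large values flag
atypical lesion patterns (candidate outliers in lesion structure). The
sharing threshold defaults to $k = \lceil 0.05\,(n-1) \rceil$ — "shared with
at most ~5% of the rest of the cohort" — and is recorded on every output;
LDI is monotone non-decreasing in $k$ by construction.

## The voxel-wise model ledger

At every retained voxel $v$ the package fits
$Y_i = \beta_0 + \beta_1 x_{iv} + \gamma' Z_i + \varepsilon_i$ by OLS with
independent homoscedastic errors, where $x_{iv}$ is the binary lesion
indicator and $Z_i$ a model-specific confounder block:

| model | confounders $Z$ |
|-------|-----------------|
| M1    | none |
| M2    | TLV |
| M3    | LDI |
| M4    | age, sex, duration |
| M5    | TLV, LDI, age, sex, duration |

The mapped statistic is always $\hat\beta_1$ with its SE, two-sided t
statistic and p-value (df $= n - p$). M5's exact composition was an open
design point; the full joint-adjustment model is the natural top of the
hierarchy and the set is configurable via `model_spec(covariates = ...)`.

Missing covariates are handled listwise *per model*: a subject is excluded
only from models that use its missing variable, and always contributes to
prevalence, GLSR and LDI. Voxels where all usable subjects share one lesion
status (no contrast), or where the lesion indicator is collinear with the
confounders, are flagged `NaN` and excluded from the test count — they are
not failed tests, they are non-tests.

Computationally the confounder block is projected out once
(Frisch–Waugh–Lovell) and every voxel reduces to a scalar regression on the
residualized lesion indicator; this is algebraically identical to solving
each voxel's normal equations, which is exactly how the test suite verifies
it (an explicit matrix-inversion oracle, agreement to 1e-8).

## Multiplicity

Bonferroni (reject $p \le \alpha/m$) controls the family-wise error rate;
Benjamini–Hochberg step-up (independence variant) controls the false
discovery rate. $m$ counts only non-flagged voxels. The Bonferroni set is
nested in the BH set at equal $\alpha$, and the two can disagree massively
on maps with broad weak signal — which is the substantive point of reporting
both.

## Sample-size extrapolation

`extrapolate_sample_size()` answers "what would these maps look like with
$n'$ subjects?" by holding $\hat\beta$ fixed, dividing SEs by
$\sqrt{n'/n}$, and recomputing p-values at df $= n' - p$. It is a planning
approximation (the design's covariance structure is assumed unchanged), not
an inference.

## Ordinal variant

EDSS is intrinsically ordinal; the package also fits, per voxel, a
proportional-odds cumulative-logit model on the three-level split
EDSS $<4$, $4$–$5.5$, $\ge 6$ (configurable cutpoints):
$P(Y_i \le j \mid x) = \mathrm{logit}^{-1}(\zeta_j - \beta_1 x_{iv} -
\gamma' Z_i)$. The fitter is an authored Newton–Raphson with analytic score,
step-halving, convergence tolerance $10^{-8}$ and at most 100 iterations;
the Hessian is the central-difference Jacobian of the analytic score, and
Wald SEs come from the inverse observed information. Complete separation
(e.g. the category a step function of the lesion indicator) is declared when
the coefficient norm exceeds $10^3$ and the voxel is flagged with its
reason. p-values use the normal Wald reference (`df = Inf` on the map).

# The synthetic cohort generator

The generator is the package's stated world, not a tuning dial. Defaults
emulate the cohort this analysis is designed around:

- **n = 98 subjects**; EDSS built from a linear predictor with intercept 3.9
  and Gaussian noise SD 2.2, clipped to $[0,10]$ and rounded to the
  half-point grid, with 7/98 missing; age $\sim N(43.5, 12.5^2)$ years
  (floored at 18, matching an adult cohort whose observed minimum is ~21);
  duration $\sim N(11.4, 9.2^2)$ truncated at 0, with 3/98 missing.
- **Female fraction 0.7** — the emulated cohort's value is not recoverable,
  so this is an explicit, configurable placeholder.
- **Geometry**: white matter is the shell between two concentric ellipsoids
  (outer = WM envelope, inner = "ventricles") on a 32³, 1 mm grid by
  default (a larger grid is a config field, not a code change).
- **Lesions**: per-subject lesion counts are negative binomial (mean 10,
  size 4 — the overdispersion creates realistic between-subject TLV spread,
  which matters for confounding behaviour); centers are sampled from an
  intensity peaked just outside the ventricle surface
  (`background + peak * exp(-d/decay)`), and lesions grow as spheres
  (radii 1–3 voxels) clipped to WM. This reproduces the periventricular
  concentration characteristic of MS lesion maps.
- **Effects**: when `beta_lesion != 0`, a compact region of `n_voxels` WM
  voxels nearest a periventricular anchor is planted verbatim in a random
  carrier subset (default carrier fraction 0.5) and background lesions are
  kept out of it, so the lesion indicator at every effect voxel equals the
  carrier status driving EDSS — making the per-voxel estimand exactly
  `beta_lesion`. TLV-, age-, sex- and duration-mediated effects are separate
  coefficients on the linear predictor.
- **Misregistration** is emulated directly on masks (`translate`, `dilate`,
  `erode`, `scale`): the package evaluates metrics downstream of
  registration and never registration itself. Translation into the
  ventricles reproduces the "lesions leave WM" failure mode; dilation/scale
  reproduce volume inflation.

What the generator does **not** emulate: MRI intensities, bias fields,
anatomically shaped lesions, spatially varying deformation fields, or
correlation between lesion location and covariates beyond what the effect
specification induces. A green test therefore establishes correctness of
the statistics on masks with the stated structure — not robustness to real
scanner data.

# Numerical and testing choices

- EDSS clipping/rounding makes the generative model slightly non-linear: at
  realistic noise (SD 2.2) the recovered lesion coefficient is attenuated by
  ~2–3%. Recovery criteria therefore judge the *replicate-averaged* estimate
  against a 5% band rather than pretending a single 98-subject draw could be
  that precise.
- Voxel-wise p-values within one map are positively dependent (subjects'
  lesions span many voxels), so null-calibration tests use the
  across-replicate SD of the rejection fraction for their 99% envelope, not
  a pooled binomial count that would assume independent tests.
- Mean GLSR ranks use the average-rank tie convention; the per-subject ranks
  then always sum to $A(A+1)/2$ for $A$ algorithms, which the tests exploit
  as a conservation law.
- Affine agreement on input volumes is required to 1e-4 per element; masks
  are binarized at 0.5 by default (resampled masks can be fractional).
- All randomness flows through explicit integer seeds in configs; reruns of
  `run_pipeline()` from the same config are byte-identical.

# Known limitations

- No spatial inference: no cluster-forming thresholds, permutation FWER,
  or random-field theory; voxels are treated exchangeably given the mask.
- No mixed models and no modelling of inter-voxel covariance.
- The registered-space GLSR denominator is a deliberate departure from a
  native-space reading of the metric's definition; both are available, and
  the choice matters exactly when registration distorts lesion volume.
- Inputs must already share the template grid — there is no resampling,
  registration, or DICOM handling in this package.
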