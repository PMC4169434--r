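#' Model specification for the voxel-wise regression ledger
#'
#' The analysis fits, at every retained voxel v, a regression of EDSS on the
#' binary lesion indicator x_iv plus a model-specific confounder block:
#' \describe{
#'   \item{M1}{lesion only — the unadjusted localization effect.}
#'   \item{M2}{lesion + TLV — adjusts for total lesion burden.}
#'   \item{M3}{lesion + LDI — adjusts for lesion-pattern atypicality.}
#'   \item{M4}{lesion + age + sex + duration — demographic confounders.}
#'   \item{M5}{lesion + TLV + LDI + age + sex + duration — full adjustment.}
#' }
#' The covariate set is configurable; `lesion` is always included and always
#' the tested coefficient.
#'
#' @param name One of `"M1"`..`"M5"`, or any label when `covariates` is given.
#' @param covariates Optional ordered character subset of
#'   `c("lesion","tlv","ldi","age","sex","duration")` overriding the ledger.
#' @param outcome_mode `"continuous"` (EDSS as a numeric score, OLS) or
#'   `"ordinal"` (EDSS cut into ordered categories, proportional odds).
#' @param ordinal_cutpoints Ascending score thresholds for the ordinal mode;
#'   default `c(4, 6)` gives categories EDSS < 4, 4 <= EDSS <= 5.5,
#'   EDSS >= 6.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("M1", "M2", "M3", "M4", "M5"),
                       covariates = NULL,
                       outcome_mode = c("continuous", "ordinal"),
                       ordinal_cutpoints = c(4, 6)) {
  outcome_mode <- match.arg(outcome_mode)
  ledger <- list(M1 = "lesion",
                 M2 = c("lesion", "tlv"),
                 M3 = c("lesion", "ldi"),
                 M4 = c("lesion", "age", "sex", "duration"),
                 M5 = c("lesion", "tlv", "ldi", "age", "sex", "duration"))
  if (is.null(covariates)) {
    name <- match.arg(name)
    covariates <- ledger[[name]]
  } else {
    name <- as.character(name)[1L]
    allowed <- c("lesion", "tlv", "ldi", "age", "sex", "duration")
    if (!all(covariates %in% allowed)) {
      stop("covariates must be a subset of: ", paste(allowed, collapse = ", "))
    }
    if (!"lesion" %in% covariates) covariates <- c("lesion", covariates)
    covariates <- unique(c("lesion", covariates))
  }
  if (is.unsorted(ordinal_cutpoints, strictly = TRUE)) {
    stop("`ordinal_cutpoints` must be strictly ascending")
  }
  structure(list(name = name, covariates = covariates,
                 outcome_mode = outcome_mode,
                 ordinal_cutpoints = as.numeric(ordinal_cutpoints)),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("model_spec", x$name, "(", x$outcome_mode, "): EDSS ~",
      paste(x$covariates, collapse = " + "), "\n")
  invisible(x)
}

# Assemble the per-subject model frame for a spec: outcome + confounders,
# flagging usable (complete-case) subjects. Listwise deletion is per model:
# only variables the model actually uses can exclude a subject.
build_model_frame <- function(cohort, metrics, spec) {
  subj <- cohort$subjects
  confounders <- setdiff(spec$covariates, "lesion")
  df <- data.frame(subject_id = subj$subject_id, edss = subj$edss,
                   stringsAsFactors = FALSE)
  for (v in confounders) {
    df[[v]] <- switch(v,
      tlv = ,
      ldi = {
        if (is.null(metrics)) stop("model ", spec$name, " needs `metrics` (TLV/LDI table)")
        col <- if (v == "tlv") "tlv_mm3" else "ldi"
        metrics[[col]][match(subj$subject_id, metrics$subject_id)]
      },
      subj[[v]])
  }
  df$usable <- stats::complete.cases(df[, c("edss", confounders), drop = FALSE])
  df
}

# Extract the n_used x V lesion-indicator matrix at the retained voxels.
lesion_matrix <- function(cohort, voxel_idx, subject_rows) {
  ids <- cohort$subjects$subject_id[subject_rows]
  L <- vapply(ids, function(id) cohort$masks[[id]][voxel_idx],
              numeric(length(voxel_idx)))
  t(matrix(L, nrow = length(voxel_idx)))
}

#' Voxel-wise linear regression of EDSS on lesion presence
#'
#' At every voxel retained by the analysis mask, fits ordinary least squares
#' of EDSS on `[1, lesion indicator, confounders]` with independent
#' homoscedastic errors, and maps the lesion coefficient, its standard error,
#' the two-sided t statistic and p-value (df = n_used - n_params).
#'
#' Subjects missing the outcome or any modelled confounder are excluded
#' listwise for this model only. Voxels where the usable subjects all share
#' the same lesion status carry no contrast: they are flagged missing (`NaN`
#' in all maps) and excluded from the test count, as are voxels whose lesion
#' indicator is collinear with the confounder block. Voxels with zero
#' residual variance (exact fit) report `se = 0`, `t = Inf`, `p = 0` and are
#' counted in `n_zero_residual`.
#'
#' Internally the confounder block is projected out once (Frisch-Waugh-Lovell)
#' so all voxels reduce to scalar regressions; this is algebraically identical
#' to solving each voxel's normal equations.
#'
#' @param cohort A [lesion_cohort()].
#' @param metrics Per-subject metric table with columns `subject_id`,
#'   `tlv_mm3`, `ldi` (from [ldi()]); only needed when the model uses TLV/LDI.
#' @param spec A [model_spec()] with `outcome_mode = "continuous"`.
#' @param mask Analysis mask from [analysis_mask()] (binary 3-D array).
#' @return An object of class `stat_map`: 3-D arrays `coef`, `se`, `tstat`,
#'   `pvalue` (NA outside the mask, NaN at flagged voxels), plus `df`,
#'   `n_used`, `n_params`, `n_tests`, `n_dropped_voxels`, `n_zero_residual`,
#'   `analysis_mask`, `model`, `registration_label`.
#' @export
fit_voxelwise <- function(cohort, metrics = NULL, spec = model_spec("M1"),
                          mask) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(spec, "model_spec"))
  if (spec$outcome_mode != "continuous") {
    stop("use fit_ordinal_voxelwise() for ordinal outcome mode")
  }
  mask <- check_binary_mask(mask, cohort$space$shape, "analysis mask")
  frame <- build_model_frame(cohort, metrics, spec)
  use <- which(frame$usable)
  confounders <- setdiff(spec$covariates, "lesion")
  n_params <- 2L + length(confounders)  # intercept + lesion + confounders
  if (length(use) < n_params + 2L) {
    stop("only ", length(use), " usable subjects for model ", spec$name,
         "; need at least ", n_params + 2L)
  }
  voxel_idx <- which(mask == 1L)
  if (!length(voxel_idx)) stop("analysis mask retains no voxels")

  y <- frame$edss[use]
  n <- length(y)
  Z <- cbind(`(Intercept)` = rep(1, n))
  for (v in confounders) Z <- cbind(Z, frame[[v]][use])
  L <- lesion_matrix(cohort, voxel_idx, use)

  qrZ <- qr(Z)
  if (qrZ$rank < ncol(Z)) stop("confounder block is rank deficient")
  y_r <- qr.resid(qrZ, y)
  L_r <- qr.resid(qrZ, L)

  carriers <- colSums(L)
  sxx <- colSums(L_r^2)
  syy <- sum(y_r^2)
  # no contrast (all 0 or all 1) or lesion column collinear with confounders
  degenerate <- carriers == 0 | carriers == n | sxx < n * 1e-10
  sxy <- as.numeric(crossprod(L_r, y_r))

  beta <- se <- tval <- pval <- rep(NaN, length(voxel_idx))
  ok <- !degenerate
  df <- n - n_params
  beta[ok] <- sxy[ok] / sxx[ok]
  rss <- pmax(syy - beta[ok]^2 * sxx[ok], 0)
  se[ok] <- sqrt(rss / df / sxx[ok])
  tval[ok] <- beta[ok] / se[ok]
  tval[ok][se[ok] == 0] <- Inf * sign(beta[ok][se[ok] == 0])
  pval[ok] <- 2 * stats::pt(-abs(tval[ok]), df)
  pval[ok][se[ok] == 0] <- 0

  new_stat_map(cohort$space, voxel_idx, beta, se, tval, pval,
               df = df, n_used = n, n_params = n_params,
               n_dropped_voxels = sum(degenerate),
               n_zero_residual = sum(ok & se == 0, na.rm = TRUE),
               analysis_mask = mask, model = spec$name,
               outcome_mode = "continuous",
               registration_label = cohort$registration_label)
}

new_stat_map <- function(space, voxel_idx, beta, se, tval, pval, df, n_used,
                         n_params, n_dropped_voxels, n_zero_residual,
                         analysis_mask, model, outcome_mode,
                         registration_label, flags = NULL) {
  blank <- function(v) {
    a <- array(NA_real_, dim = space$shape)
    a[voxel_idx] <- v
    a
  }
  structure(list(coef = blank(beta), se = blank(se), tstat = blank(tval),
                 pvalue = blank(pval), df = df, n_used = n_used,
                 n_params = n_params,
                 n_tests = sum(!is.na(pval) & !is.nan(pval)),
                 n_dropped_voxels = n_dropped_voxels,
                 n_zero_residual = n_zero_residual,
                 analysis_mask = analysis_mask, model = model,
                 outcome_mode = outcome_mode,
                 registration_label = registration_label,
                 voxel_idx = voxel_idx, flags = flags),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat("stat_map:", x$model, "(", x$outcome_mode, ") |", x$n_tests, "tests |",
      "n =", x$n_used, "| df =", x$df, "| registration:",
      x$registration_label, "\n")
  invisible(x)
}

#' Multiple-testing correction of a voxel-wise p-value map
#'
#' Bonferroni controls the family-wise error rate: reject where
#' `p <= alpha / n_tests`. Benjamini-Hochberg controls the false discovery
#' rate with the step-up rule (independence variant): sort the p-values, find
#' the largest i with `p_(i) <= i * alpha / n_tests`, reject the i smallest.
#' Only non-missing p-values count as tests; flagged voxels are not part of
#' the family. The Bonferroni rejection set is always contained in the BH set
#' at equal alpha.
#'
#' @param stat A [fit_voxelwise()] / [fit_ordinal_voxelwise()] result.
#' @param method `"bonferroni"` or `"bh_fdr"`.
#' @param alpha Significance level, default 0.05.
#' @return An object of class `correction_result`: `method`, `alpha`,
#'   `significant` (binary 3-D array), `n_significant`, `n_tests`.
#' @export
correct_pvalues <- function(stat, method = c("bonferroni", "bh_fdr"),
                            alpha = 0.05) {
  stopifnot(inherits(stat, "stat_map"))
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)")
  p <- stat$pvalue[stat$voxel_idx]
  tested <- !is.na(p) & !is.nan(p)
  m <- sum(tested)
  reject <- logical(length(p))
  if (m > 0L) {
    pv <- p[tested]
    if (method == "bonferroni") {
      reject[tested] <- pv <= alpha / m
    } else {
      o <- order(pv)
      thresh <- seq_len(m) * alpha / m
      passed <- which(pv[o] <= thresh)
      k <- if (length(passed)) max(passed) else 0L
      r <- logical(m)
      if (k > 0L) r[o[seq_len(k)]] <- TRUE
      reject[tested] <- r
    }
  }
  sig <- array(0L, dim = dim(stat$pvalue))
  sig[stat$voxel_idx[reject]] <- 1L
  structure(list(method = method, alpha = alpha, significant = sig,
                 n_significant = sum(reject), n_tests = m,
                 model = stat$model,
                 registration_label = stat$registration_label),
            class = "correction_result")
}

#' @export
print.correction_result <- function(x, ...) {
  cat("correction_result:", x$method, "at alpha =", x$alpha, "|",
      x$n_significant, "of", x$n_tests, "tests significant\n")
  invisible(x)
}

#' Sample-size extrapolation of a voxel-wise statistic map
#'
#' Approximates the p-value map that would be observed with `n_target`
#' subjects instead of `n_actual`, holding the coefficient estimates fixed:
#' standard errors shrink as `se / sqrt(n_target / n_actual)`, t statistics
#' rescale accordingly, and p-values are recomputed against a t reference
#' with `df = n_target - n_params`. This is a planning approximation — it
#' assumes the design's covariance structure is unchanged at the larger n.
#'
#' @param stat A continuous-outcome [fit_voxelwise()] result.
#' @param n_actual The fitted sample size (defaults to `stat$n_used`).
#' @param n_target Hypothetical sample size, `n_target >= n_actual >= 2`.
#' @return A `stat_map` with rescaled `se`, `tstat`, `pvalue`, updated `df`;
#'   returned unchanged when `n_target == n_actual`.
#' @export
extrapolate_sample_size <- function(stat, n_actual = stat$n_used, n_target) {
  stopifnot(inherits(stat, "stat_map"))
  if (n_actual < 2L || n_target < n_actual) {
    stop("need n_target >= n_actual >= 2")
  }
  if (n_target == n_actual) return(stat)
  factor <- sqrt(n_target / n_actual)
  out <- stat
  out$se <- stat$se / factor
  out$tstat <- stat$coef / out$se
  out$df <- n_target - stat$n_params
  out$n_used <- as.integer(n_target)
  p <- 2 * stats::pt(-abs(out$tstat), out$df)
  p[is.na(stat$pvalue)] <- stat$pvalue[is.na(stat$pvalue)]  # keep NA/NaN flags
  zero <- !is.na(stat$se) & stat$se == 0
  p[zero] <- 0
  out$pvalue <- p
  out
}

#' Cohort-level simple linear regression
#'
#' One regression for the whole cohort (no voxels): EDSS on a scalar subject
#' summary such as TLV or LDI. Incomplete pairs are dropped.
#'
#' @param y Outcome vector (e.g. EDSS).
#' @param x Predictor vector of the same length (e.g. TLV in mm^3).
#' @return A list: `slope`, `intercept`, `se`, `tstat`, `p` (two-sided),
#'   `n` (complete pairs used), `df`.
#' @export
cohort_regression <- function(y, x) {
  if (length(y) != length(x)) stop("`y` and `x` lengths differ")
  keep <- stats::complete.cases(y, x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n < 3L) stop("need at least 3 complete pairs")
  sxx <- sum((x - mean(x))^2)
  if (sxx <= 0) stop("`x` has zero variance")
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  df <- n - 2L
  se <- sqrt(rss / df / sxx)
  tstat <- if (se == 0) Inf * sign(slope) else slope / se
  p <- if (se == 0) 0 else 2 * stats::pt(-abs(tstat), df)
  list(slope = slope, intercept = intercept, se = se, tstat = tstat,
       p = p, n = n, df = df)
}
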