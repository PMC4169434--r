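# Voxel-wise OLS, multiplicity corrections, extrapolation, cohort regression.

test_that("noiseless effect is recovered exactly with zero residual variance", {
  space <- toy_space(c(4, 4, 4))
  set.seed(41)
  n <- 12
  x <- rep(c(0L, 1L), each = n / 2)
  masks <- lapply(x, function(xi) {
    m <- array(0L, dim = c(4, 4, 4)); m[2, 2, 2] <- xi; m
  })
  subj <- data.frame(subject_id = sprintf("s%d", 1:n),
                     edss = 2 + 3 * x, age = 40, sex = 1, duration = 5)
  ch <- lesion_cohort(space, subj, masks)
  am <- array(0L, dim = c(4, 4, 4)); am[2, 2, 2] <- 1L
  fit <- fit_voxelwise(ch, NULL, model_spec("M1"), am)
  expect_equal(fit$coef[2, 2, 2], 3)
  expect_equal(fit$se[2, 2, 2], 0)
  expect_equal(fit$pvalue[2, 2, 2], 0)
  expect_identical(fit$n_zero_residual, 1L)
})

test_that("every voxel-wise fit equals the explicit normal-equations oracle", {
  for (seed in c(51, 52)) {
    ch <- toy_cohort(n = 30, shape = c(5, 5, 4), p = 0.35, seed = seed)
    met <- toy_metrics(ch)
    prev <- lesion_count_map(ch)
    am <- analysis_mask(prev, 2)
    for (mname in c("M1", "M4", "M5")) {
      sp <- model_spec(mname)
      fit <- fit_voxelwise(ch, met, sp, am)
      frame <- lesionmapr:::build_model_frame(ch, met, sp)
      y <- frame$edss
      conf <- setdiff(sp$covariates, "lesion")
      for (v in sample(which(am == 1L), 20)) {
        x <- vapply(ch$masks, function(m) m[v], integer(1))
        X <- cbind(1, x)
        for (cv in conf) X <- cbind(X, frame[[cv]])
        if (is.nan(fit$coef[v])) {
          expect_true(all(x == 0) || all(x == 1) || qr(X)$rank < ncol(X))
          next
        }
        o <- oracle_ols(y, X)
        expect_equal(fit$coef[v], o$beta[2], tolerance = 1e-8)
        expect_equal(fit$se[v], o$se[2], tolerance = 1e-8)
        expect_equal(fit$tstat[v], o$t[2], tolerance = 1e-8)
        expect_equal(fit$pvalue[v], o$p[2], tolerance = 1e-8)
        expect_identical(fit$df, o$df)
      }
    }
  }
})

test_that("subjects are dropped listwise per model and contrasts validated", {
  ch <- toy_cohort(n = 20, shape = c(4, 4, 4), p = 0.4, seed = 61)
  ch$subjects$edss[1:3] <- NA
  ch$subjects$duration[4] <- NA
  met <- toy_metrics(ch)
  am <- analysis_mask(lesion_count_map(ch), 1)
  f1 <- fit_voxelwise(ch, met, model_spec("M1"), am)
  expect_identical(f1$n_used, 17L)           # only EDSS missing matters for M1
  f4 <- fit_voxelwise(ch, met, model_spec("M4"), am)
  expect_identical(f4$n_used, 16L)           # duration now also drops s4
  # voxels with all-same lesion status among usable subjects are flagged
  for (i in seq_along(ch$masks)) ch$masks[[i]][1, 1, 1] <- 0L
  am2 <- am; am2[1, 1, 1] <- 1L
  f <- fit_voxelwise(ch, met, model_spec("M1"), am2)
  expect_true(is.nan(f$pvalue[1, 1, 1]))
  expect_identical(f$n_tests, sum(!is.nan(f$pvalue[f$voxel_idx])))
})

test_that("correct_pvalues implements Bonferroni and BH step-up", {
  # hand example: p = (0.001, 0.02, 0.9), alpha = 0.05
  # bonferroni: 0.001 <= 0.05/3 only -> 1 rejection
  # BH: sorted p vs (1/3, 2/3, 3/3)*0.05 -> 0.001 <= 0.0167, 0.02 <= 0.0333 -> 2
  space <- toy_space(c(3, 1, 1))
  stat <- lesionmapr:::new_stat_map(
    space, voxel_idx = 1:3, beta = c(1, 1, 1), se = c(1, 1, 1),
    tval = c(1, 1, 1), pval = c(0.001, 0.02, 0.9), df = 10, n_used = 12,
    n_params = 2, n_dropped_voxels = 0, n_zero_residual = 0,
    analysis_mask = array(1L, dim = c(3, 1, 1)), model = "M1",
    outcome_mode = "continuous", registration_label = "toy")
  bf <- correct_pvalues(stat, "bonferroni", 0.05)
  bh <- correct_pvalues(stat, "bh_fdr", 0.05)
  expect_identical(bf$n_significant, 1L)
  expect_identical(bh$n_significant, 2L)
  expect_identical(which(bf$significant == 1L), 1L)
  expect_identical(which(bh$significant == 1L), 1:2)

  # all p = 1 -> nothing under either method
  stat$pvalue[1:3] <- 1
  expect_identical(correct_pvalues(stat, "bonferroni")$n_significant, 0L)
  expect_identical(correct_pvalues(stat, "bh_fdr")$n_significant, 0L)
})

test_that("Bonferroni rejections are a subset of BH rejections (property)", {
  set.seed(71)
  space <- toy_space(c(10, 10, 1))
  for (rep in 1:10) {
    p <- c(rbeta(50, 0.3, 4), runif(50))  # mix of signal-like and null
    stat <- lesionmapr:::new_stat_map(
      space, voxel_idx = 1:100, beta = rnorm(100), se = rep(1, 100),
      tval = rnorm(100), pval = p, df = 50, n_used = 52, n_params = 2,
      n_dropped_voxels = 0, n_zero_residual = 0,
      analysis_mask = array(1L, dim = c(10, 10, 1)), model = "M1",
      outcome_mode = "continuous", registration_label = "toy")
    bf <- correct_pvalues(stat, "bonferroni", 0.05)
    bh <- correct_pvalues(stat, "bh_fdr", 0.05)
    expect_true(all(bh$significant[bf$significant == 1L] == 1L))
    # BH against the reference implementation
    expect_identical(bh$n_significant, sum(p.adjust(p, "BH") <= 0.05))
  }
})

test_that("sample-size extrapolation rescales SEs and is monotone in n", {
  ch <- toy_cohort(n = 25, shape = c(5, 5, 4), p = 0.35, seed = 81)
  am <- analysis_mask(lesion_count_map(ch), 2)
  fit <- fit_voxelwise(ch, NULL, model_spec("M1"), am)

  expect_identical(extrapolate_sample_size(fit, n_target = fit$n_used), fit)

  e4 <- extrapolate_sample_size(fit, n_actual = 98, n_target = 392)
  idx <- fit$voxel_idx[!is.nan(fit$tstat[fit$voxel_idx])]
  expect_equal(e4$tstat[idx], 2 * fit$tstat[idx])  # sqrt(392/98) = 2
  expect_equal(e4$se[idx], fit$se[idx] / 2)
  expect_equal(e4$coef[idx], fit$coef[idx])

  e2 <- extrapolate_sample_size(fit, n_target = 2L * fit$n_used)
  expect_true(all(e2$pvalue[idx] <= fit$pvalue[idx]))
  expect_identical(e2$df, 2L * fit$n_used - fit$n_params)
  expect_error(extrapolate_sample_size(fit, n_target = fit$n_used - 1),
               "n_target")
})

test_that("cohort_regression: exact fit, degeneracy, oracle equivalence", {
  x <- 1:10
  r <- cohort_regression(2 * x + 1, x)
  expect_equal(r$slope, 2)
  expect_equal(r$p, 0)
  expect_error(cohort_regression(rnorm(5), rep(3, 5)), "zero variance")
  expect_error(cohort_regression(c(1, 2, NA), c(1, NA, 3)), "3 complete pairs")

  set.seed(91)
  x <- rnorm(98); y <- 0.3 * x + rnorm(98, sd = 2)
  r <- cohort_regression(y, x)
  o <- oracle_ols(y, cbind(1, x))
  expect_equal(r$slope, o$beta[2], tolerance = 1e-10)
  expect_equal(r$se, o$se[2], tolerance = 1e-10)
  expect_equal(r$p, o$p[2], tolerance = 1e-10)
})
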