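# Shared fixtures: tiny template spaces and cohorts built in code, plus the
# explicit normal-equations OLS oracle used for dual-route checks.

toy_space <- function(shape = c(6, 6, 6), voxel_dims = c(1, 1, 1), wm = NULL) {
  if (is.null(wm)) wm <- array(1L, dim = shape)
  template_space(shape, voxel_dims, wm)
}

# Random cohort with Bernoulli masks (per-subject rate spread around p, so
# TLV and LDI vary between subjects); no missing data unless asked.
toy_cohort <- function(n = 10, shape = c(6, 6, 6), p = 0.3, seed = 1,
                       space = NULL, edss = NULL, label = "toy") {
  set.seed(seed)
  if (is.null(space)) space <- toy_space(shape)
  rates <- runif(n, 0.5 * p, 1.5 * p)
  masks <- lapply(seq_len(n), function(i) {
    array(rbinom(prod(space$shape), 1L, rates[i]), dim = space$shape)
  })
  if (is.null(edss)) edss <- sample(seq(0, 8, by = 0.5), n, replace = TRUE)
  subjects <- data.frame(
    subject_id = sprintf("t%02d", seq_len(n)),
    edss = edss,
    age = round(rnorm(n, 43.5, 12.5), 1),
    sex = rbinom(n, 1, 0.7),
    duration = round(pmax(rnorm(n, 11.4, 9.2), 0), 1))
  lesion_cohort(space, subjects, masks, registration_label = label)
}

# Independent OLS oracle: explicit normal-equations solve (matrix inversion),
# returning estimate/SE/t/p for every column of X (intercept included by the
# caller). Deliberately not sharing code with fit_voxelwise().
oracle_ols <- function(y, X) {
  XtX_inv <- solve(t(X) %*% X)
  beta <- XtX_inv %*% t(X) %*% y
  resid <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(resid^2) / df
  se <- sqrt(diag(XtX_inv) * sigma2)
  tval <- beta / se
  list(beta = as.numeric(beta), se = as.numeric(se), t = as.numeric(tval),
       p = as.numeric(2 * pt(-abs(tval), df)), df = df)
}

# Per-subject metric table (TLV/LDI) for a cohort, as fit_voxelwise expects.
# rarity_k at the median carrier count makes LDI vary between subjects even
# in small dense toy cohorts (the package default targets sparse real maps).
toy_metrics <- function(cohort) {
  prev <- lesion_count_map(cohort)
  k <- max(1L, as.integer(stats::median(prev$counts[prev$counts > 0L])))
  ldi(cohort, prev, rarity_k = k)
}

# A vector of n values in [0, 1] with exact mean m and exact *population* SD s
# (two-point construction with k "high" values).
two_point_values <- function(n, k, m, s) {
  p <- k / n
  gap <- s / sqrt(p * (1 - p))
  lo <- m - p * gap
  hi <- lo + gap
  stopifnot(lo >= 0, hi <= 1)
  c(rep(hi, k), rep(lo, n - k))
}
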