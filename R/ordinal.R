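#' Cut EDSS into ordered categories
#'
#' EDSS is intrinsically ordinal (0 to 10 in half points). The default
#' three-level split is EDSS < 4, 4 <= EDSS <= 5.5, EDSS >= 6, encoded
#' 0/1/2.
#'
#' @param edss Numeric EDSS vector (may contain `NA`).
#' @param cutpoints Ascending thresholds; category = number of thresholds at
#'   or below the score.
#' @return Integer category vector (0-based), `NA` preserved.
#' @export
edss_category <- function(edss, cutpoints = c(4, 6)) {
  if (is.unsorted(cutpoints, strictly = TRUE)) {
    stop("`cutpoints` must be strictly ascending")
  }
  findInterval(edss, cutpoints)
}

# Negative log-likelihood and analytic gradient of the proportional-odds
# cumulative-logit model. Parameters theta = (zeta_1..zeta_{J-1}, beta);
# P(Y <= j | x) = plogis(zeta_j - x'beta). y is 1..J, X is n x k.
prop_odds_nll <- function(theta, y, X, J) {
  nz <- J - 1L
  zeta <- theta[seq_len(nz)]
  beta <- theta[-seq_len(nz)]
  eta <- as.numeric(X %*% beta)
  Fm <- cbind(0, stats::plogis(outer(-eta, zeta, `+`)), 1)  # F_{j}(zeta_j - eta)
  p <- Fm[cbind(seq_along(y), y + 1L)] - Fm[cbind(seq_along(y), y)]
  -sum(log(pmax(p, 1e-300)))
}

prop_odds_grad <- function(theta, y, X, J) {
  nz <- J - 1L
  zeta <- theta[seq_len(nz)]
  beta <- theta[-seq_len(nz)]
  n <- length(y)
  eta <- as.numeric(X %*% beta)
  Fin <- stats::plogis(outer(-eta, zeta, `+`))      # n x (J-1), F at zeta_j - eta
  fin <- Fin * (1 - Fin)                            # logistic density
  Fm <- cbind(0, Fin, 1)
  fm <- cbind(0, fin, 0)
  p <- pmax(Fm[cbind(seq_len(n), y + 1L)] - Fm[cbind(seq_len(n), y)], 1e-300)
  f_up <- fm[cbind(seq_len(n), y + 1L)]
  f_lo <- fm[cbind(seq_len(n), y)]
  # d nll / d zeta_j: -(1{y=j} f_j - 1{y=j+1} f_j) / p
  gz <- vapply(seq_len(nz), function(j) {
    -sum(((y == j) * fin[, j] - (y == j + 1L) * fin[, j]) / p)
  }, numeric(1))
  # d nll / d beta: sum x_i (f_up - f_lo) / p
  gb <- as.numeric(crossprod(X, (f_up - f_lo) / p))
  c(gz, gb)
}

#' Fit a proportional-odds cumulative-logit model
#'
#' Maximum-likelihood fit of `P(Y <= j | x) = plogis(zeta_j - x'beta)` by
#' Newton-Raphson with step-halving; the Hessian is the central-difference
#' Jacobian of the analytic score, and standard errors come from the inverse
#' observed information. Used per voxel by [fit_ordinal_voxelwise()].
#'
#' @param y Integer ordinal outcome, categories `0..J-1` or `1..J`.
#' @param X Covariate matrix (no intercept; the cutpoints absorb it).
#' @param tol Convergence tolerance on the score and the step (default 1e-8).
#' @param max_iter Maximum Newton iterations (default 100).
#' @param separation_norm Coefficient norm beyond which the fit is declared
#'   separated (default 1e3).
#' @return A list with `status` (`"converged"`, `"separation"`,
#'   `"no_convergence"`, `"singular_information"`, `"degenerate_outcome"`)
#'   and, when converged, `zeta`, `beta`, `se`, `logLik`, `iterations`.
#' @export
fit_prop_odds <- function(y, X, tol = 1e-8, max_iter = 100L,
                          separation_norm = 1e3) {
  y <- as.integer(y)
  if (min(y) == 0L) y <- y + 1L                 # accept 0-based categories
  J <- max(y)
  if (length(unique(y)) < 2L) {
    return(list(status = "degenerate_outcome"))
  }
  X <- as.matrix(X)
  k <- ncol(X)
  nz <- J - 1L
  # start: intercept-only cumulative logits, beta = 0
  cum <- cumsum(tabulate(y, J))[seq_len(nz)] / length(y)
  theta <- c(stats::qlogis(pmin(pmax(cum, 1e-6), 1 - 1e-6)), rep(0, k))

  nll <- prop_odds_nll(theta, y, X, J)
  status <- "no_convergence"
  for (iter in seq_len(max_iter)) {
    g <- prop_odds_grad(theta, y, X, J)
    H <- num_jacobian(function(th) prop_odds_grad(th, y, X, J), theta)
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) {
      status <- "singular_information"
      break
    }
    # step-halving: keep cutpoints ordered and the objective decreasing
    lambda <- 1
    repeat {
      cand <- theta - lambda * step
      zeta <- cand[seq_len(nz)]
      cand_nll <- if (is.unsorted(zeta, strictly = TRUE)) Inf
                  else prop_odds_nll(cand, y, X, J)
      if (cand_nll <= nll + 1e-12 || lambda < 1e-8) break
      lambda <- lambda / 2
    }
    if (!is.finite(cand_nll)) break  # step-halving failed; report no_convergence
    moved <- max(abs(theta - cand))
    theta <- cand
    nll <- cand_nll
    if (sqrt(sum(cand[-seq_len(nz)]^2)) > separation_norm) {
      status <- "separation"
      break
    }
    if (max(abs(prop_odds_grad(theta, y, X, J))) < tol || moved < tol) {
      status <- "converged"
      break
    }
  }
  if (status != "converged") return(list(status = status))
  H <- num_jacobian(function(th) prop_odds_grad(th, y, X, J), theta)
  H <- (H + t(H)) / 2
  vc <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(vc) || any(diag(vc) <= 0)) return(list(status = "singular_information"))
  list(status = "converged",
       zeta = theta[seq_len(nz)],
       beta = theta[-seq_len(nz)],
       se = sqrt(diag(vc))[-seq_len(nz)],
       logLik = -nll, iterations = iter)
}

# Central-difference Jacobian of a vector-valued function.
num_jacobian <- function(f, x, eps = 1e-6) {
  k <- length(x)
  J <- matrix(0, k, k)
  for (i in seq_len(k)) {
    h <- eps * max(1, abs(x[i]))
    up <- x; up[i] <- up[i] + h
    dn <- x; dn[i] <- dn[i] - h
    J[, i] <- (f(up) - f(dn)) / (2 * h)
  }
  J
}

#' Voxel-wise proportional-odds regression of ordinal EDSS
#'
#' The ordinal counterpart of [fit_voxelwise()]: EDSS is cut into ordered
#' categories (default: < 4, 4-5.5, >= 6) and, at every retained voxel, a
#' cumulative-logit proportional-odds model is maximized by Newton-Raphson
#' (tolerance 1e-8, at most 100 iterations). The mapped statistic is the
#' lesion log-odds coefficient with its Wald standard error and two-sided
#' normal p-value. Voxels where the fit does not converge, the information
#' matrix is singular, or the data are separated (coefficient norm exceeding
#' 1e3, as when the category is a step function of the lesion indicator) are
#' flagged `NaN` with the reason recorded in `flags`, and are excluded from
#' the test count.
#'
#' @inheritParams fit_voxelwise
#' @param spec A [model_spec()] with `outcome_mode = "ordinal"`.
#' @return A `stat_map` (see [fit_voxelwise()]); `df = Inf` marks the normal
#'   Wald reference, and `flags` tabulates per-voxel failure reasons.
#' @export
fit_ordinal_voxelwise <- function(cohort, metrics = NULL,
                                  spec = model_spec("M1", outcome_mode = "ordinal"),
                                  mask) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(spec, "model_spec"))
  if (spec$outcome_mode != "ordinal") {
    stop("`spec` must have outcome_mode = \"ordinal\"")
  }
  mask <- check_binary_mask(mask, cohort$space$shape, "analysis mask")
  frame <- build_model_frame(cohort, metrics, spec)
  use <- which(frame$usable)
  confounders <- setdiff(spec$covariates, "lesion")
  n_params <- 2L + length(confounders)
  if (length(use) < n_params + 2L) {
    stop("only ", length(use), " usable subjects for model ", spec$name)
  }
  ycat <- edss_category(frame$edss[use], spec$ordinal_cutpoints)
  if (length(unique(ycat)) < 2L) {
    stop("fewer than 2 populated outcome categories among usable subjects")
  }
  # renumber to consecutive 1..J (an empty middle category drops out)
  ycat <- as.integer(factor(ycat))
  voxel_idx <- which(mask == 1L)
  if (!length(voxel_idx)) stop("analysis mask retains no voxels")
  n <- length(use)
  Zc <- NULL
  for (v in confounders) Zc <- cbind(Zc, frame[[v]][use])
  L <- lesion_matrix(cohort, voxel_idx, use)

  nv <- length(voxel_idx)
  beta <- se <- rep(NaN, nv)
  flags <- character(nv)
  carriers <- colSums(L)
  for (j in seq_len(nv)) {
    if (carriers[j] == 0 || carriers[j] == n) {
      flags[j] <- "no_contrast"
      next
    }
    X <- cbind(lesion = L[, j], Zc)
    fit <- fit_prop_odds(ycat, X)
    if (fit$status != "converged") {
      flags[j] <- fit$status
      next
    }
    beta[j] <- fit$beta[1L]
    se[j] <- fit$se[1L]
    flags[j] <- "ok"
  }
  tval <- beta / se
  pval <- 2 * stats::pnorm(-abs(tval))
  new_stat_map(cohort$space, voxel_idx, beta, se, tval, pval,
               df = Inf, n_used = n, n_params = n_params,
               n_dropped_voxels = sum(flags != "ok"),
               n_zero_residual = 0L,
               analysis_mask = mask, model = spec$name,
               outcome_mode = "ordinal",
               registration_label = cohort$registration_label,
               flags = table(flags))
}

#' Simulate an ordinal outcome from a latent-logistic proportional-odds model
#'
#' Draws `Y* = x * beta + logistic error` and cuts the latent score at the
#' given thresholds, so the resulting categories follow a proportional-odds
#' model with lesion log-odds exactly `beta`. Used for parameter-recovery
#' checks of the ordinal fitter.
#'
#' @param x Covariate vector (e.g. 0/1 lesion indicator).
#' @param beta True log-odds coefficient.
#' @param cutpoints Ascending latent thresholds (default `c(0, 2)` for three
#'   categories).
#' @return Integer categories `0 .. length(cutpoints)`.
#' @export
simulate_ordinal_outcome <- function(x, beta, cutpoints = c(0, 2)) {
  latent <- x * beta + stats::rlogis(length(x))
  findInterval(latent, sort(cutpoints))
}
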