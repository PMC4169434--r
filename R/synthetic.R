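#' Simulation configuration
#'
#' Collects every knob of the synthetic lesion-cohort generator. Defaults
#' emulate the cohort the analysis is designed for: 98 subjects; EDSS with
#' mean 3.9 and SD 2.2 on the 0-10 half-point scale with 7/98 missing; age
#' mean 43.5 / SD 12.5 years; disease duration mean 11.4 / SD 9.2 years with
#' 3/98 missing; spatially clustered periventricular lesions inside a
#' white-matter shell; and a configurable female fraction (default 0.7).
#' The test-scale grid is 32^3 at 1 mm isotropic resolution; pass a larger
#' `shape` for realism runs.
#'
#' @param n_subjects Cohort size.
#' @param shape,voxel_dims Template grid (3 integers; mm).
#' @param outer_semiaxes,inner_semiaxes Semi-axes (voxels) of the outer
#'   ellipsoid and the inner "ventricle" ellipsoid; white matter is the shell
#'   between them. `inner_semiaxes = c(0,0,0)` gives a solid ellipsoid.
#' @param background_rate,peak_rate,decay Lesion-center intensity: the
#'   sampling weight of a WM voxel is
#'   `background_rate + peak_rate * exp(-d / decay)` where `d` is the voxel's
#'   normalized distance above the ventricle surface; `peak_rate >>
#'   background_rate` concentrates lesions periventricularly.
#' @param mean_lesions,lesion_dispersion Per-subject lesion count is negative
#'   binomial with this mean and size (smaller size = more between-subject
#'   TLV heterogeneity).
#' @param radius_values,radius_probs Discrete lesion radius distribution
#'   (voxels); lesions are spheres clipped to WM.
#' @param effect Effect specification, a list with elements `beta_lesion`,
#'   `beta_tlv`, `beta_age`, `beta_sex`, `beta_duration` (linear-predictor
#'   coefficients, default 0), `intercept` (default 3.9), `noise_sd`
#'   (default 2.2), `n_voxels` (effect-region size, default 20),
#'   `center` (voxel coordinates; default the most periventricular WM voxel)
#'   and `carrier_fraction` (default 0.5). When `beta_lesion != 0` a compact
#'   effect region of `n_voxels` WM voxels is planted verbatim in a random
#'   carrier subset and background lesions are kept out of it, so the lesion
#'   indicator at every effect voxel equals the carrier indicator.
#' @param age_mean,age_sd,duration_mean,duration_sd,female_fraction
#'   Covariate marginals.
#' @param edss_missing,duration_missing Missingness fractions.
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_subjects = 98L,
                       shape = c(32L, 32L, 32L),
                       voxel_dims = c(1, 1, 1),
                       outer_semiaxes = c(13, 13, 13),
                       inner_semiaxes = c(4, 4, 4),
                       background_rate = 0.2,
                       peak_rate = 2,
                       decay = 0.25,
                       mean_lesions = 10,
                       lesion_dispersion = 4,
                       radius_values = c(1, 2, 3),
                       radius_probs = c(0.5, 0.35, 0.15),
                       effect = list(),
                       age_mean = 43.5, age_sd = 12.5,
                       duration_mean = 11.4, duration_sd = 9.2,
                       female_fraction = 0.7,
                       edss_missing = 7 / 98,
                       duration_missing = 3 / 98,
                       seed = 1L) {
  effect_defaults <- list(beta_lesion = 0, beta_tlv = 0, beta_age = 0,
                          beta_sex = 0, beta_duration = 0,
                          intercept = 3.9, noise_sd = 2.2,
                          n_voxels = 20L, center = NULL,
                          carrier_fraction = 0.5)
  unknown <- setdiff(names(effect), names(effect_defaults))
  if (length(unknown)) stop("unknown effect fields: ", paste(unknown, collapse = ", "))
  effect <- utils::modifyList(effect_defaults, effect)
  cfg <- list(n_subjects = as.integer(n_subjects), shape = as.integer(shape),
              voxel_dims = as.numeric(voxel_dims),
              outer_semiaxes = as.numeric(outer_semiaxes),
              inner_semiaxes = as.numeric(inner_semiaxes),
              background_rate = background_rate, peak_rate = peak_rate,
              decay = decay, mean_lesions = mean_lesions,
              lesion_dispersion = lesion_dispersion,
              radius_values = radius_values, radius_probs = radius_probs,
              effect = effect,
              age_mean = age_mean, age_sd = age_sd,
              duration_mean = duration_mean, duration_sd = duration_sd,
              female_fraction = female_fraction,
              edss_missing = edss_missing, duration_missing = duration_missing,
              seed = as.integer(seed))
  if (cfg$n_subjects < 1L) stop("n_subjects must be positive")
  if (any(cfg$background_rate < 0, cfg$peak_rate < 0)) stop("rates must be >= 0")
  if (effect$noise_sd <= 0) stop("noise_sd must be > 0")
  if (any(cfg$inner_semiaxes >= cfg$outer_semiaxes) &&
      any(cfg$inner_semiaxes > 0)) {
    stop("inner ellipsoid must lie strictly inside the outer ellipsoid")
  }
  if (abs(sum(cfg$radius_probs) - 1) > 1e-8 || any(cfg$radius_probs < 0)) {
    stop("radius_probs must be a probability vector")
  }
  structure(cfg, class = "sim_config")
}

# Normalized squared ellipsoid coordinate of every voxel:
# sum(((v - center) / semiaxes)^2), with zero semi-axes giving Inf (no
# membership). Voxel coordinates are 1-based grid indices.
ellipsoid_q <- function(shape, semiaxes) {
  center <- (shape + 1) / 2
  ax <- function(i) {
    if (semiaxes[i] <= 0) return(rep(Inf, shape[i]))
    ((seq_len(shape[i]) - center[i]) / semiaxes[i])^2
  }
  q1 <- ax(1); q2 <- ax(2); q3 <- ax(3)
  outer(outer(q1, q2, `+`), q3, `+`)
}

#' Build a synthetic template space
#'
#' White matter is modelled as the shell between two concentric ellipsoids:
#' the outer one stands in for the brain's WM envelope, the inner one for the
#' ventricles (lesions in MS cluster around the ventricles, so the generator
#' concentrates lesion centers just outside the inner surface). Deterministic
#' given the configuration.
#'
#' @param config A [sim_config()].
#' @return A [template_space()] whose `wm_mask` is the ellipsoid shell.
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  q_out <- ellipsoid_q(config$shape, config$outer_semiaxes)
  q_in <- ellipsoid_q(config$shape, config$inner_semiaxes)
  wm <- (q_out <= 1) & (q_in > 1)
  if (!any(wm)) stop("infeasible geometry: empty white-matter shell")
  template_space(config$shape, config$voxel_dims, wm)
}

# Lesion-center sampling weights over WM voxels: peaked just outside the
# ventricle surface, decaying with normalized radial distance.
periventricular_weights <- function(space, config) {
  q_in <- ellipsoid_q(space$shape, config$inner_semiaxes)
  d <- pmax(sqrt(q_in) - 1, 0)
  d[!is.finite(d)] <- 1  # solid-ellipsoid case: flat field
  w <- config$background_rate + config$peak_rate * exp(-d / config$decay)
  w * (space$wm_mask == 1L)
}

# Ball of integer offsets with squared radius <= r^2 (matrix, memoized:
# stamping thousands of spheres per cohort hits this hard).
.ball_cache <- new.env(parent = emptyenv())
ball_offsets <- function(r) {
  key <- as.character(r)
  hit <- .ball_cache[[key]]
  if (!is.null(hit)) return(hit)
  s <- seq(-floor(r), floor(r))
  g <- as.matrix(expand.grid(dx = s, dy = s, dz = s))
  g <- g[g[, 1]^2 + g[, 2]^2 + g[, 3]^2 <= r^2, , drop = FALSE]
  .ball_cache[[key]] <- g
  g
}

# Stamp a sphere of radius r centered at voxel `center` into `mask`,
# clipped to the grid and to `clip` (0/1 array) when given.
stamp_sphere <- function(mask, center, r, clip = NULL) {
  off <- ball_offsets(r)
  vx <- center[1] + off[, 1]; vy <- center[2] + off[, 2]; vz <- center[3] + off[, 3]
  d <- dim(mask)
  ok <- vx >= 1 & vx <= d[1] & vy >= 1 & vy <= d[2] & vz >= 1 & vz <= d[3]
  idx <- vx[ok] + d[1] * (vy[ok] - 1L) + d[1] * d[2] * (vz[ok] - 1L)
  if (!is.null(clip)) idx <- idx[clip[idx] == 1L]
  mask[idx] <- 1L
  mask
}

# The n WM voxels nearest to `center` (Euclidean, ties broken by index):
# the deterministic compact effect region.
effect_region <- function(space, center, n_voxels) {
  wm_idx <- which(space$wm_mask == 1L)
  co <- arrayInd(wm_idx, space$shape)
  d2 <- (co[, 1] - center[1])^2 + (co[, 2] - center[2])^2 + (co[, 3] - center[3])^2
  wm_idx[order(d2, wm_idx)][seq_len(min(n_voxels, length(wm_idx)))]
}

#' Simulate a lesion cohort
#'
#' Draws, reproducibly from `config$seed`: per-subject covariates from the
#' configured marginals (durations truncated at 0); lesion masks as unions of
#' spheres clipped to white matter, with centers sampled from the
#' periventricular intensity field and per-subject lesion counts drawn
#' negative-binomially (between-subject TLV heterogeneity); and EDSS as
#'
#' `intercept + beta_lesion * carrier + beta_tlv * TLV_mm3 + beta_age * age +
#'  beta_sex * sex + beta_duration * duration + N(0, noise_sd)`,
#'
#' clipped to `[0, 10]` and rounded to the half-point grid, then subjected to
#' the configured missingness. When `beta_lesion != 0`, a compact effect
#' region is planted verbatim in a random carrier subset (see [sim_config()]),
#' so the per-voxel lesion indicator at effect voxels equals the carrier
#' status that drives EDSS.
#'
#' @param space A [template_space()] from [make_template()] (or compatible).
#' @param config A [sim_config()].
#' @return A [lesion_cohort()] with `registration_label = "simulated"`. When
#'   an effect region was planted, its voxel indices are attached as
#'   attribute `"effect_voxels"` and the carrier indicator as `"carriers"`.
#' @export
simulate_cohort <- function(space, config) {
  stopifnot(inherits(space, "template_space"), inherits(config, "sim_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  n <- config$n_subjects
  eff <- config$effect
  has_effect <- eff$beta_lesion != 0 || !is.null(eff$center)
  weights <- periventricular_weights(space, config)
  wm_idx <- which(space$wm_mask == 1L)
  w <- weights[wm_idx]
  if (all(w == 0)) {
    if (has_effect) stop("zero-rate intensity field with effect voxels requested")
    w <- rep(1, length(w))  # degenerate but effect-free: uniform over WM
  }

  region <- integer(0)
  carriers <- rep(0L, n)
  clip <- space$wm_mask
  if (has_effect) {
    center <- eff$center
    if (is.null(center)) {
      center <- arrayInd(wm_idx[which.max(w)], space$shape)[1, ]
    }
    region <- effect_region(space, center, eff$n_voxels)
    carriers <- stats::rbinom(n, 1L, eff$carrier_fraction)
    clip <- space$wm_mask
    clip[region] <- 0L  # background lesions stay out of the effect region
  }

  co_all <- arrayInd(wm_idx, space$shape)
  masks <- vector("list", n)
  for (i in seq_len(n)) {
    m <- array(0L, dim = space$shape)
    k <- stats::rnbinom(1L, size = config$lesion_dispersion, mu = config$mean_lesions)
    if (k > 0L) {
      centers <- sample.int(length(wm_idx), k, replace = TRUE, prob = w)
      radii <- sample(config$radius_values, k, replace = TRUE,
                      prob = config$radius_probs)
      for (l in seq_len(k)) {
        m <- stamp_sphere(m, co_all[centers[l], ], radii[l], clip = clip)
      }
    }
    if (has_effect && carriers[i] == 1L) m[region] <- 1L
    masks[[i]] <- m
  }

  age <- pmax(stats::rnorm(n, config$age_mean, config$age_sd), 18)
  duration <- pmax(stats::rnorm(n, config$duration_mean, config$duration_sd), 0)
  sex <- stats::rbinom(n, 1L, config$female_fraction)
  vv <- prod(config$voxel_dims)
  tlv_mm3 <- vapply(masks, sum, numeric(1)) * vv
  lp <- eff$intercept + eff$beta_lesion * carriers + eff$beta_tlv * tlv_mm3 +
    eff$beta_age * age + eff$beta_sex * sex + eff$beta_duration * duration
  edss <- round(pmin(pmax(lp + stats::rnorm(n, 0, eff$noise_sd), 0), 10) * 2) / 2

  edss[sample.int(n, round(config$edss_missing * n))] <- NA_real_
  duration[sample.int(n, round(config$duration_missing * n))] <- NA_real_

  subjects <- data.frame(subject_id = sprintf("s%03d", seq_len(n)),
                         edss = edss, age = age, sex = sex,
                         duration = duration, stringsAsFactors = FALSE)
  cohort <- lesion_cohort(space, subjects, masks, registration_label = "simulated")
  if (has_effect) {
    attr(cohort, "effect_voxels") <- region
    attr(cohort, "carriers") <- carriers
  }
  cohort
}

# Shift a 3-D 0/1 array by an integer offset, zero-filling.
shift_array <- function(mask, d) {
  out <- array(0L, dim = dim(mask))
  sh <- dim(mask)
  src <- dst <- vector("list", 3L)
  for (i in 1:3) {
    lo <- max(1L, 1L - d[i])
    hi <- min(sh[i], sh[i] - d[i])
    if (hi < lo) return(out)  # shifted fully off-grid
    src[[i]] <- lo:hi
    dst[[i]] <- src[[i]] + d[i]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- mask[src[[1]], src[[2]], src[[3]]]
  out
}

# Binary dilation/erosion with a spherical structuring element of radius r.
morph_binary <- function(mask, r, op = c("dilate", "erode")) {
  op <- match.arg(op)
  off <- ball_offsets(r)
  acc <- NULL
  for (j in seq_len(nrow(off))) {
    s <- shift_array(mask, off[j, ])
    acc <- if (is.null(acc)) s else {
      if (op == "dilate") pmax(acc, s) else pmin(acc, s)
    }
  }
  array(as.integer(acc), dim = dim(mask))
}

# Center-scale a mask about its centroid by `factor` (nearest-neighbour
# pull-back with re-binarization).
scale_mask <- function(mask, factor) {
  if (factor <= 0) stop("scale factor must be positive")
  idx <- which(mask == 1L)
  if (!length(idx)) return(mask)
  ctr <- colMeans(arrayInd(idx, dim(mask)))
  sh <- dim(mask)
  g <- arrayInd(seq_along(mask), sh)
  src <- round(sweep(sweep(g, 2, ctr), 2, rep(factor, 3), `/`) + rep(1, nrow(g)) %o% ctr)
  ok <- src[, 1] >= 1 & src[, 1] <= sh[1] & src[, 2] >= 1 & src[, 2] <= sh[2] &
    src[, 3] >= 1 & src[, 3] <= sh[3]
  out <- array(0L, dim = sh)
  out[which(ok)] <- mask[src[ok, , drop = FALSE]]
  out
}

#' Perturb a cohort's masks to emulate misregistration
#'
#' Applies a controlled distortion to every mask and relabels the cohort, so
#' registration-quality metrics can be exercised against a known failure
#' mode: `"translate"` rigidly shifts lesions (e.g. into the ventricles,
#' inflating GLSR), `"dilate"`/`"erode"` change lesion volume the way some
#' deformable registrations inflate or shrink lesions, and `"scale"` rescales
#' each mask about its centroid with re-binarization. The perturbation acts
#' directly on masks — registration itself is upstream of this package.
#'
#' @param cohort A [lesion_cohort()].
#' @param mode One of `"translate"`, `"dilate"`, `"erode"`, `"scale"`.
#' @param magnitude Integer offset vector (length 3, or a scalar applied to
#'   the first axis) for `"translate"`; structuring-element radius for
#'   `"dilate"`/`"erode"`; scale factor for `"scale"`.
#' @param seed Unused by the deterministic modes; kept for interface
#'   stability.
#' @return A new [lesion_cohort()] tagged
#'   `"<old label>+<mode><magnitude>"`. Translating any non-empty mask fully
#'   off-grid is an error.
#' @export
perturb_registration <- function(cohort,
                                 mode = c("translate", "dilate", "erode", "scale"),
                                 magnitude, seed = NULL) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  mode <- match.arg(mode)
  masks <- cohort$masks
  new_masks <- vector("list", length(masks))
  for (i in seq_along(masks)) {
    m <- masks[[i]]
    out <- switch(mode,
      translate = {
        d <- as.integer(if (length(magnitude) == 1L) c(magnitude, 0L, 0L) else magnitude)
        if (length(d) != 3L) stop("translate magnitude must be 1 or 3 integers")
        s <- shift_array(m, d)
        if (sum(m) > 0L && sum(s) == 0L) {
          stop("translation pushes mask of subject ",
               cohort$subjects$subject_id[i], " fully off-grid")
        }
        s
      },
      dilate = morph_binary(m, magnitude, "dilate"),
      erode = morph_binary(m, magnitude, "erode"),
      scale = scale_mask(m, magnitude))
    new_masks[[i]] <- out
  }
  label <- paste0(cohort$registration_label, "+", mode,
                  paste(magnitude, collapse = ","))
  lesion_cohort(cohort$space, cohort$subjects, new_masks,
                registration_label = label)
}
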