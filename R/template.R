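#' Template space
#'
#' A `template_space` describes the common voxel grid to which all subjects'
#' lesion masks have been registered: the grid shape, voxel size, a 4x4
#' voxel-to-world affine, and the binary white-matter (WM) mask of the template
#' on that grid. The WM mask is the reference used by the GLSR registration
#' quality statistic; its derivation (tissue segmentation) happens upstream.
#'
#' @param shape Integer vector of length 3, voxels per axis.
#' @param voxel_dims Numeric vector of length 3, voxel edge lengths in mm.
#' @param wm_mask 3-D array on `shape` containing only 0/1 (logical allowed).
#' @param affine Optional 4x4 voxel-to-world matrix (0-based voxel indices).
#'   Defaults to `diag(c(voxel_dims, 1))`. Its linear part must be consistent
#'   with `voxel_dims` (|det| equals the voxel volume).
#' @return An object of class `template_space` with fields `shape`,
#'   `voxel_dims`, `affine` and `wm_mask` (stored as an integer 0/1 array).
#' @examples
#' wm <- array(1L, dim = c(4, 4, 4))
#' sp <- template_space(c(4, 4, 4), c(1, 1, 1), wm)
#' voxel_volume(sp)
#' @export
template_space <- function(shape, voxel_dims, wm_mask, affine = NULL) {
  shape <- as.integer(shape)
  voxel_dims <- as.numeric(voxel_dims)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be 3 positive integers")
  }
  if (length(voxel_dims) != 3L || any(!is.finite(voxel_dims)) || any(voxel_dims <= 0)) {
    stop("`voxel_dims` must be 3 positive lengths (mm)")
  }
  if (is.null(affine)) affine <- diag(c(voxel_dims, 1))
  if (!is.matrix(affine) || any(dim(affine) != 4L)) stop("`affine` must be 4x4")
  vol <- prod(voxel_dims)
  if (abs(abs(det(affine[1:3, 1:3])) - vol) > 1e-4 * vol) {
    stop("affine determinant inconsistent with voxel_dims")
  }
  wm_mask <- check_binary_mask(wm_mask, shape, "wm_mask")
  structure(list(shape = shape, voxel_dims = voxel_dims, affine = affine,
                 wm_mask = wm_mask),
            class = "template_space")
}

#' @export
print.template_space <- function(x, ...) {
  cat("template_space: grid", paste(x$shape, collapse = " x "),
      "| voxels", paste(signif(x$voxel_dims, 4), collapse = " x "), "mm",
      "| WM voxels:", sum(x$wm_mask), "\n")
  invisible(x)
}

#' Voxel volume of a template space
#'
#' @param space A [template_space()].
#' @return Voxel volume in mm^3.
#' @export
voxel_volume <- function(space) {
  stopifnot(inherits(space, "template_space"))
  prod(space$voxel_dims)
}

# Validate a binary mask against a grid shape; returns integer 0/1 array.
check_binary_mask <- function(mask, shape, what = "mask") {
  if (is.logical(mask)) mask <- mask + 0L
  d <- dim(mask)
  if (is.null(d) || length(d) != 3L) stop("`", what, "` must be a 3-D array")
  if (any(d != shape)) {
    stop("`", what, "` shape (", paste(d, collapse = "x"),
         ") does not match grid (", paste(shape, collapse = "x"), ")")
  }
  if (is.integer(mask)) {
    if (anyNA(mask)) stop("`", what, "` contains non-finite voxels")
    rng <- range(mask)
    if (rng[1] < 0L || rng[2] > 1L) {
      stop("`", what, "` is not binary (values outside {0,1})")
    }
    return(mask)
  }
  if (any(!is.finite(mask))) stop("`", what, "` contains non-finite voxels")
  if (any(mask != 0 & mask != 1)) {
    stop("`", what, "` is not binary (values outside {0,1})")
  }
  array(as.integer(mask), dim = shape)
}

# Absolute per-element affine agreement tolerance used when reading volumes.
AFFINE_TOL <- 1e-4

#' Lesion cohort
#'
#' Bundles per-subject binary lesion masks on a common [template_space()] with
#' the subject metadata used by the disability models (EDSS score, age, sex,
#' disease duration). Exactly one mask per subject; missing covariates are
#' kept as `NA` and handled listwise by each model downstream (a subject is
#' excluded only from models that use its missing variable; its mask still
#' contributes to prevalence, GLSR and LDI).
#'
#' @param space A [template_space()].
#' @param subjects A data.frame with columns `subject_id`, `edss`, `age`,
#'   `sex` (female = 1), `duration`; see [read_cohort()] for validation rules.
#' @param masks List of binary 3-D arrays on the template grid, one per
#'   subject, in the same order as `subjects`.
#' @param registration_label Character tag for the registration that produced
#'   the masks (e.g. `"rigid"`).
#' @return An object of class `lesion_cohort`.
#' @export
lesion_cohort <- function(space, subjects, masks, registration_label = "unlabelled") {
  stopifnot(inherits(space, "template_space"))
  subjects <- validate_subjects(subjects)
  if (!is.list(masks) || length(masks) != nrow(subjects)) {
    stop("need exactly one mask per subject (got ", length(masks),
         " masks for ", nrow(subjects), " subjects)")
  }
  masks <- lapply(seq_along(masks), function(i) {
    check_binary_mask(masks[[i]], space$shape,
                      paste0("mask[", subjects$subject_id[i], "]"))
  })
  names(masks) <- subjects$subject_id
  structure(list(space = space, subjects = subjects, masks = masks,
                 registration_label = as.character(registration_label)),
            class = "lesion_cohort")
}

#' @export
print.lesion_cohort <- function(x, ...) {
  cat("lesion_cohort:", nrow(x$subjects), "subjects | registration:",
      x$registration_label, "| grid", paste(x$space$shape, collapse = " x "), "\n")
  invisible(x)
}

#' Number of subjects in a cohort
#' @param cohort A [lesion_cohort()].
#' @return Integer subject count.
#' @export
n_subjects <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  nrow(cohort$subjects)
}

validate_subjects <- function(subjects) {
  subjects <- as.data.frame(subjects)
  required <- c("subject_id", "edss", "age", "sex", "duration")
  missing_cols <- setdiff(required, names(subjects))
  if (length(missing_cols)) {
    stop("subject table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  subjects$subject_id <- as.character(subjects$subject_id)
  if (anyDuplicated(subjects$subject_id)) {
    stop("duplicate subject ids: ",
         paste(unique(subjects$subject_id[duplicated(subjects$subject_id)]),
               collapse = ", "))
  }
  for (col in c("edss", "age", "sex", "duration")) {
    subjects[[col]] <- as.numeric(subjects[[col]])
  }
  e <- subjects$edss[!is.na(subjects$edss)]
  if (any(e < 0 | e > 10)) stop("edss outside [0, 10]")
  if (any(abs(e * 2 - round(e * 2)) > 1e-8)) {
    stop("edss values must lie on the half-point grid 0, 0.5, ..., 10")
  }
  if (any(subjects$age < 0, na.rm = TRUE)) stop("negative age")
  if (any(subjects$duration < 0, na.rm = TRUE)) stop("negative duration")
  s <- subjects$sex[!is.na(subjects$sex)]
  if (!all(s %in% c(0, 1))) stop("sex must be coded 0/1 (female = 1)")
  subjects[required]
}
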