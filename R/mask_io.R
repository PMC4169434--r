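#' Read a lesion (or analysis) mask registered to a template space
#'
#' Reads a NIfTI volume, checks that it lives on the template grid (shape must
#' match exactly; affine must agree element-wise within an absolute tolerance
#' of 1e-4), and binarizes it: values strictly greater than
#' `binarize_threshold` map to 1, the rest to 0. Interpolation during
#' resampling can leave fractional values in a nominally binary mask, which is
#' why the threshold exists; masks that are already 0/1 pass through unchanged
#' at the default threshold.
#'
#' @param path Path to a NIfTI volume on the template grid.
#' @param space The [template_space()] the mask must match.
#' @param binarize_threshold Scalar in `[0, 1)`; default 0.5.
#' @return Integer 0/1 array on `space$shape`.
#' @export
read_mask <- function(path, space, binarize_threshold = 0.5) {
  stopifnot(inherits(space, "template_space"))
  nii <- read_nifti(path)
  d <- dim(nii$data)
  if (any(d != space$shape)) {
    stop("grid mismatch: volume is ", paste(d, collapse = "x"),
         ", template is ", paste(space$shape, collapse = "x"))
  }
  if (max(abs(nii$affine - space$affine)) > AFFINE_TOL) {
    stop("affine mismatch beyond tolerance ", AFFINE_TOL, ": ", path)
  }
  if (any(!is.finite(nii$data))) stop("non-finite voxels in ", path)
  array(as.integer(nii$data > binarize_threshold), dim = space$shape)
}

#' Write a map or mask to NIfTI on the template grid
#'
#' Writes a 3-D array with the template's affine. Values round-trip exactly
#' through [read_nifti()] (float64 storage by default); `NA`/`NaN` voxels are
#' preserved as `NaN`, the conventional sentinel for "not tested" in p-value
#' maps.
#'
#' @param map 3-D array on `space$shape`.
#' @param space A [template_space()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param datatype NIfTI storage type; default `"float64"` for exact
#'   round-trips, use `"uint8"` for binary masks.
#' @return `path`, invisibly.
#' @export
write_map <- function(map, space, path, datatype = "float64") {
  stopifnot(inherits(space, "template_space"))
  d <- dim(map)
  if (is.null(d) || length(d) != 3L || any(d != space$shape)) {
    stop("map shape does not match template grid")
  }
  write_nifti(map, space$affine, path, datatype = datatype)
}

#' Read a cohort table
#'
#' Reads a CSV with header columns `id, edss, age, sex, duration` (extra
#' columns are ignored; empty cells are missing). No imputation is performed:
#' missing values are preserved as `NA` and each downstream model drops
#' subjects listwise only when it actually uses the missing variable.
#'
#' Validation: subject ids must be unique; EDSS, when present, must lie in
#' `[0, 10]` on the half-point grid; age and duration must be non-negative;
#' sex is coded 0/1 (female = 1).
#'
#' @param path Path to a CSV file.
#' @return A data.frame with columns `subject_id`, `edss`, `age`, `sex`,
#'   `duration`, one row per subject.
#' @export
read_cohort <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character"))
  required <- c("id", "edss", "age", "sex", "duration")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("cohort table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  names(tab)[names(tab) == "id"] <- "subject_id"
  validate_subjects(tab)
}

#' Write a cohort table
#'
#' Inverse of [read_cohort()]: writes the subject table as CSV with the
#' `id, edss, age, sex, duration` header, missing values as empty cells.
#'
#' @param subjects Subject data.frame (as in a [lesion_cohort()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(subjects, path) {
  subjects <- validate_subjects(subjects)
  out <- subjects
  names(out)[names(out) == "subject_id"] <- "id"
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
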