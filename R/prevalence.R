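#' Lesion prevalence map (3-D lesion histogram)
#'
#' Counts, at every voxel of the template grid, the number of subjects whose
#' lesion mask is 1 there. This is the population lesion histogram: dividing
#' by `n_subjects` gives the per-voxel lesion prevalence. In MS cohorts the
#' map is typically maximal in the periventricular white matter.
#'
#' @param cohort A non-empty [lesion_cohort()].
#' @return An object of class `prevalence_map` with fields `counts` (integer
#'   3-D array), `n_subjects`, and `registration_label`.
#' @export
lesion_count_map <- function(cohort) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  n <- n_subjects(cohort)
  if (n == 0L) stop("empty cohort")
  counts <- Reduce(`+`, cohort$masks)
  structure(list(counts = array(as.integer(counts), dim = cohort$space$shape),
                 n_subjects = n,
                 registration_label = cohort$registration_label),
            class = "prevalence_map")
}

#' @export
print.prevalence_map <- function(x, ...) {
  cat("prevalence_map:", x$n_subjects, "subjects | registration:",
      x$registration_label, "| max count:", max(x$counts),
      "| lesioned voxels:", sum(x$counts > 0L), "\n")
  invisible(x)
}

#' Proportion view of a prevalence map
#'
#' @param prev A [lesion_count_map()] result.
#' @return 3-D array of per-voxel lesion prevalence `counts / n_subjects`.
#' @export
prevalence_proportion <- function(prev) {
  stopifnot(inherits(prev, "prevalence_map"))
  prev$counts / prev$n_subjects
}

#' Analysis mask: voxels with enough lesion carriers
#'
#' Voxel-wise testing is restricted to voxels where *more than* `min_subjects`
#' subjects have a lesion (strict inequality); elsewhere the lesion-presence
#' contrast is too sparse to be informative. The retained-voxel count is the
#' number of simultaneous tests performed downstream and travels with the
#' result.
#'
#' @param prev A [lesion_count_map()] result.
#' @param min_subjects Integer, `0 <= min_subjects < n_subjects`. Default 3.
#' @return Integer 0/1 array with attributes `n_retained` (retained voxel
#'   count) and `min_subjects`.
#' @export
analysis_mask <- function(prev, min_subjects = 3L) {
  stopifnot(inherits(prev, "prevalence_map"))
  min_subjects <- as.integer(min_subjects)
  if (min_subjects < 0L || min_subjects >= prev$n_subjects) {
    stop("`min_subjects` must satisfy 0 <= min_subjects < n_subjects")
  }
  mask <- array(as.integer(prev$counts > min_subjects), dim = dim(prev$counts))
  attr(mask, "n_retained") <- sum(mask)
  attr(mask, "min_subjects") <- min_subjects
  mask
}
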