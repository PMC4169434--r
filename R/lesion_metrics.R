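#' Total lesion volume
#'
#' The total lesion volume (TLV) of one subject: the number of 1-voxels in the
#' lesion mask, and the corresponding volume in mm^3 (count times voxel
#' volume). TLV is both a burden measure and a key confounder of voxel-wise
#' lesion-disability associations, since registration algorithms can change
#' it substantially.
#'
#' @param mask Binary 3-D array on the template grid.
#' @param space A [template_space()].
#' @return A list with `voxels` (integer count) and `mm3` (volume).
#' @export
tlv <- function(mask, space) {
  stopifnot(inherits(space, "template_space"))
  mask <- check_binary_mask(mask, space$shape)
  count <- sum(mask)
  list(voxels = count, mm3 = count * voxel_volume(space))
}

#' Goodness-of-lesion-spatial-registration (GLSR) for one subject
#'
#' White-matter lesions should remain in the template's white matter after
#' registration. GLSR is the proportion of a subject's lesion voxels that fall
#' *outside* the template WM mask: 0 means perfect placement, 1 total failure
#' (all lesion tissue registered out of WM). It is a joint measure of
#' registration and tissue-classification quality; it does not assess lesion
#' position relative to anatomical landmarks.
#'
#' The numerator is always counted in registered (template) space. The
#' denominator is by default the registered-mask lesion count, which is
#' self-contained even when registration inflates or shrinks lesion volume;
#' `denominator = "native"` divides by the supplied native-space lesion count
#' instead.
#'
#' @param registered_mask Binary 3-D lesion mask on the template grid.
#' @param space A [template_space()] carrying the WM mask.
#' @param denominator `"registered"` (default) or `"native"`.
#' @param native_voxels Native-space lesion voxel count, required (and > 0)
#'   when `denominator = "native"`.
#' @param subject_id,registration_label Tags copied into the record.
#' @return A one-row data.frame with columns `subject_id`,
#'   `registration_label`, `glsr`, `outside_wm`, `lesion_voxels_registered`,
#'   `lesion_voxels_native`. A zero denominator yields `glsr = NA` (flagged,
#'   not an error): an empty registered mask carries no placement information.
#' @export
glsr <- function(registered_mask, space,
                 denominator = c("registered", "native"),
                 native_voxels = NA_integer_,
                 subject_id = NA_character_,
                 registration_label = NA_character_) {
  stopifnot(inherits(space, "template_space"))
  denominator <- match.arg(denominator)
  mask <- check_binary_mask(registered_mask, space$shape)
  n_reg <- sum(mask)
  outside <- sum(mask == 1L & space$wm_mask == 0L)
  den <- if (denominator == "registered") n_reg else {
    if (is.na(native_voxels) || native_voxels <= 0) {
      stop("`native_voxels` must be a positive count when denominator = \"native\"")
    }
    as.integer(native_voxels)
  }
  value <- if (den == 0L) NA_real_ else outside / den
  data.frame(subject_id = as.character(subject_id),
             registration_label = as.character(registration_label),
             glsr = value,
             outside_wm = outside,
             lesion_voxels_registered = n_reg,
             lesion_voxels_native = as.integer(native_voxels),
             stringsAsFactors = FALSE)
}

#' GLSR for every subject of a cohort
#'
#' @param cohort A [lesion_cohort()].
#' @param denominator,native_voxels As in [glsr()]; `native_voxels` may be a
#'   named vector (by subject id) when `denominator = "native"`.
#' @return A data.frame with one [glsr()] record per subject.
#' @export
glsr_cohort <- function(cohort, denominator = c("registered", "native"),
                        native_voxels = NULL) {
  stopifnot(inherits(cohort, "lesion_cohort"))
  denominator <- match.arg(denominator)
  ids <- cohort$subjects$subject_id
  rows <- lapply(ids, function(id) {
    nv <- if (is.null(native_voxels)) NA_integer_ else native_voxels[[id]]
    glsr(cohort$masks[[id]], cohort$space, denominator = denominator,
         native_voxels = nv, subject_id = id,
         registration_label = cohort$registration_label)
  })
  do.call(rbind, rows)
}

#' Summarize GLSR over a cohort for one registration
#'
#' Computes the cohort mean, median and sample SD (denominator n-1) of GLSR,
#' the mean squared error with respect to the truth GLSR = 0 (so
#' `mse = mean(glsr^2) = mean^2 + population variance`), and — when values for
#' several registrations are supplied — the mean rank: within each subject the
#' algorithms are ranked by GLSR (rank 1 = smallest, ties get average ranks)
#' and ranks are averaged over subjects. Lower mean, MSE and mean rank all
#' indicate better registration.
#'
#' Subjects with missing GLSR (empty registered mask) are dropped from the
#' summaries; for the mean rank, only subjects with a value under *every*
#' registration are used, and the subject sets must otherwise agree.
#'
#' @param records Data.frame of per-subject GLSR values for one registration
#'   (columns `subject_id`, `registration_label`, `glsr`), e.g. from
#'   [glsr_cohort()].
#' @param all_algorithms Optional long data.frame with the same columns
#'   covering every registration under comparison (it must include this
#'   registration's rows); required for `mean_rank`.
#' @return One-row data.frame: `registration_label`, `n`, `mean`, `median`,
#'   `sd`, `mse`, `mean_rank` (`NA` if `all_algorithms` not given).
#' @export
summarize_glsr <- function(records, all_algorithms = NULL) {
  label <- unique(records$registration_label)
  if (length(label) != 1L) stop("`records` must cover exactly one registration")
  g <- records$glsr[!is.na(records$glsr)]
  if (length(g) < 2L) stop("need at least 2 subjects with defined GLSR")
  mean_rank <- NA_real_
  if (!is.null(all_algorithms)) {
    mean_rank <- glsr_mean_ranks(all_algorithms)[[label]]
  }
  data.frame(registration_label = label,
             n = length(g),
             mean = mean(g),
             median = stats::median(g),
             sd = stats::sd(g),
             mse = mean(g^2),
             mean_rank = mean_rank,
             stringsAsFactors = FALSE)
}

# Within-subject ranks of GLSR across registrations, averaged over subjects.
# Returns a named vector (one entry per registration label).
glsr_mean_ranks <- function(all_algorithms) {
  labels <- unique(all_algorithms$registration_label)
  sets <- lapply(split(all_algorithms$subject_id, all_algorithms$registration_label),
                 function(s) sort(unique(s)))
  if (!all(vapply(sets, identical, logical(1), y = sets[[1L]]))) {
    stop("subject sets differ across registrations; mean rank undefined")
  }
  df <- all_algorithms[!is.na(all_algorithms$glsr), , drop = FALSE]
  subjects <- sort(unique(df$subject_id))
  wide <- matrix(NA_real_, length(subjects), length(labels),
                 dimnames = list(subjects, labels))
  wide[cbind(match(df$subject_id, subjects),
             match(df$registration_label, labels))] <- df$glsr
  complete <- rowSums(is.na(wide)) == 0L
  if (!any(complete)) stop("no subject has GLSR under every registration")
  wide <- wide[complete, , drop = FALSE]
  ranks <- matrix(NA_real_, nrow(wide), ncol(wide), dimnames = dimnames(wide))
  for (i in seq_len(nrow(wide))) ranks[i, ] <- rank(wide[i, ])
  colMeans(ranks)
}

#' Location-discrepancy index (LDI)
#'
#' For each subject, the fraction of their lesion voxels that are "rare" in
#' the cohort: voxel v counts toward subject i's rare set when no more than
#' `rarity_k` *other* subjects have a lesion at v (the subject's own lesion is
#' excluded from the count). LDI = rare voxels / TLV lies in `[0, 1]`; large
#' values flag an atypical lesion pattern — a departure from the population
#' prevalence map — and such subjects may be outliers in lesion structure.
#'
#' @param cohort A [lesion_cohort()].
#' @param prev The [lesion_count_map()] of the *same* cohort (checked).
#' @param rarity_k Non-negative integer; a voxel is rare for a subject when at
#'   most this many other subjects share it. Default
#'   `ceiling(0.05 * (n_subjects - 1))`, i.e. roughly the rarest 5% sharing
#'   level; the value used is recorded on the result.
#' @return A data.frame with one row per subject: `subject_id`, `rare_voxels`,
#'   `tlv_voxels`, `tlv_mm3`, `ldi` (`NA` for subjects with empty masks), with
#'   attribute `rarity_k`.
#' @export
ldi <- function(cohort, prev, rarity_k = NULL) {
  stopifnot(inherits(cohort, "lesion_cohort"), inherits(prev, "prevalence_map"))
  n <- n_subjects(cohort)
  if (prev$n_subjects != n || any(dim(prev$counts) != cohort$space$shape)) {
    stop("prevalence map was not computed from this cohort")
  }
  if (is.null(rarity_k)) rarity_k <- as.integer(ceiling(0.05 * (n - 1L)))
  rarity_k <- as.integer(rarity_k)
  if (rarity_k < 0L) stop("`rarity_k` must be >= 0")
  vv <- voxel_volume(cohort$space)
  rows <- lapply(cohort$subjects$subject_id, function(id) {
    m <- cohort$masks[[id]]
    tlv_vox <- sum(m)
    # counts - 1 at the subject's own lesion voxels = number of *other* carriers
    rare <- sum(m == 1L & (prev$counts - 1L) <= rarity_k)
    data.frame(subject_id = id,
               rare_voxels = rare,
               tlv_voxels = tlv_vox,
               tlv_mm3 = tlv_vox * vv,
               ldi = if (tlv_vox > 0L) rare / tlv_vox else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "rarity_k") <- rarity_k
  out
}
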