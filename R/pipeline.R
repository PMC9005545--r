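#' Preprocess a native subject volume to a segment stack
#'
#' Runs the preprocessing chain for one subject: 9-DOF landmark similarity
#' fit ([fit_similarity_9dof()]), optional mutual-information refinement,
#' resampling onto the atlas grid (shape normalization), optional block-wise
#' intensity normalization ([normalize_intensity()]), skull stripping, and
#' extraction of the four segment crops.
#'
#' `level = "landmark"` stops the spatial stage after the landmark
#' similarity fit (the fast path for large phantom experiments, where
#' analytic landmarks make the fit essentially exact) and uses the
#' identity-deformation block intensity normalization
#' ([normalize_intensity_blocks()]); `"mi"` adds the MI refinement of the
#' similarity transform; `"full"` runs the complete chain with nonlinear
#' B-spline registration and back-projected intensity maps
#' ([normalize_intensity()]).
#'
#' @param volume native-space `mci_volume`.
#' @param landmarks subject [landmark_set()].
#' @param atlas an [atlas_bundle()].
#' @param level preprocessing depth: `"landmark"`, `"mi"`, or `"full"`.
#' @param with_intensity apply the intensity stage (default TRUE).
#' @param subject_id identifier for the resulting stack.
#' @return list with `stack` ([segment_stack()]), `shape_normalized`
#'   (`mci_volume`), `similarity` and the intensity-stage artifacts.
#' @export
preprocess_subject <- function(volume, landmarks, atlas,
                               level = c("landmark", "mi", "full"),
                               with_intensity = TRUE,
                               subject_id = "subject") {
  level <- match.arg(level)
  tr <- fit_similarity_9dof(atlas$landmarks, landmarks)
  if (level %in% c("mi", "full"))
    tr <- refine_similarity_mi(volume, atlas$template, atlas$brain_mask,
                               init = tr)
  sn <- resample(volume, tr, atlas$template, space = "shape_normalized")
  intensity <- NULL
  if (level == "full" && with_intensity) {
    intensity <- normalize_intensity(sn, atlas)
    sn <- intensity$volume
    sn$space <- "shape_normalized"
  } else if (with_intensity) {
    intensity <- normalize_intensity_blocks(sn, atlas)
    sn <- intensity$volume
  }
  list(stack = segment_stack(sn, atlas, subject_id = subject_id),
       shape_normalized = sn, similarity = tr, intensity = intensity)
}

#' Preprocess a phantom cohort to segment stacks
#'
#' Applies [preprocess_subject()] to every subject of an in-memory cohort
#' from [make_cohort()].
#'
#' @param cohort a [make_cohort()] result (in-memory form).
#' @param atlas the [atlas_bundle()] the cohort was generated from.
#' @param level preprocessing depth, see [preprocess_subject()].
#' @return list with `stacks` (list of [segment_stack()]s) and `records`
#'   (the cohort's subject table).
#' @export
preprocess_cohort <- function(cohort, atlas, level = "landmark") {
  stacks <- vector("list", length(cohort$subjects))
  for (i in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[i]]
    pp <- preprocess_subject(s$volume, s$landmarks, atlas, level = level,
                             subject_id = cohort$table$subject_id[i])
    stacks[[i]] <- pp$stack
  }
  list(stacks = stacks, records = cohort$table)
}
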