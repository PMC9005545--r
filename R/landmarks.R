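#' The six anatomical landmark names used for shape normalization
#'
#' Landmark-based alignment uses six brain locations with distinct local
#' anatomy: the two eyes, the front of the fornix body, the centre of the
#' midbrain, the centre of the fourth ventricle, and the top of the corpus
#' callosum.
#' @export
LANDMARK_NAMES <- c("eye_left", "eye_right", "fornix_body_front",
                    "midbrain_center", "fourth_ventricle_center",
                    "corpus_callosum_top")

#' Landmark sets
#'
#' A `landmark_set` is a named 6 x 3 matrix of world coordinates (mm), rows
#' fixed to [LANDMARK_NAMES].
#'
#' @param points 6 x 3 numeric matrix with rownames from [LANDMARK_NAMES]
#'   (any order), or a named list of length-3 vectors.
#' @return a `landmark_set`.
#' @export
landmark_set <- function(points) {
  if (is.list(points))
    points <- do.call(rbind, lapply(points, as.numeric))
  points <- as.matrix(points)
  nm <- rownames(points)
  if (is.null(nm)) stop("landmark points must be named")
  if (anyDuplicated(nm)) stop("duplicate landmark name(s): ",
                              paste(unique(nm[duplicated(nm)]), collapse = ", "))
  missing <- setdiff(LANDMARK_NAMES, nm)
  if (length(missing))
    stop("missing landmark(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(nm, LANDMARK_NAMES)
  if (length(extra))
    stop("unknown landmark name(s): ", paste(extra, collapse = ", "))
  points <- points[LANDMARK_NAMES, , drop = FALSE]
  if (ncol(points) != 3L || !all(is.finite(points)))
    stop("landmark coordinates must be finite x,y,z triples")
  structure(points, class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  cat("<landmark_set> 6 points (mm):\n")
  print(round(unclass(x), 3))
  invisible(x)
}

#' Read / write landmark sets as JSON
#'
#' The on-disk format is a JSON object mapping each of the six fixed landmark
#' names to an `[x, y, z]` world coordinate in mm.
#'
#' @param path file path.
#' @param landmarks a [landmark_set()].
#' @export
read_landmarks <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(obj) && !is.matrix(obj)) stop("landmark file must be a JSON object")
  landmark_set(lapply(obj, as.numeric))
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "landmark_set"))
  obj <- lapply(seq_len(nrow(landmarks)), function(i) as.numeric(landmarks[i, ]))
  names(obj) <- rownames(unclass(landmarks))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Default APOE genotype to AD-risk encoding
#'
#' Relative Alzheimer's risk values for the APOE genotypes used by the
#' classifier: e2/e3 -> 0.6, e3/e3 -> 1.0, e2/e4 and e4/e2 -> 3.2,
#' e4/e4 -> 11.6.  Other genotypes have no default and must be supplied
#' through `extra`.
#'
#' @param extra optional named numeric vector of additional genotype -> risk
#'   entries (all positive).
#' @return named numeric vector mapping genotype tokens to risk values.
#' @export
apoe_risk_map <- function(extra = NULL) {
  m <- c("e2/e3" = 0.6, "e3/e3" = 1.0, "e2/e4" = 3.2, "e4/e2" = 3.2,
         "e4/e4" = 11.6)
  if (!is.null(extra)) {
    if (is.null(names(extra)) || any(!nzchar(names(extra))))
      stop("extra risk entries must be named by genotype token")
    if (any(extra <= 0)) stop("risk values must be positive")
    m[names(extra)] <- extra
  }
  m
}

#' Encode an APOE genotype as a scalar risk value
#'
#' @param genotype genotype token such as `"e3/e3"`.
#' @param risk_map mapping from [apoe_risk_map()].
#' @return positive risk value.
#' @export
encode_apoe <- function(genotype, risk_map = apoe_risk_map()) {
  v <- risk_map[genotype]
  if (any(is.na(v)))
    stop("no risk value configured for genotype(s): ",
         paste(unique(genotype[is.na(v)]), collapse = ", "))
  unname(v)
}

#' Read / write subject tables
#'
#' A subject table is a CSV with header columns
#' `subject_id, mmse, faq, cdr_sb, adas, age, apoe, label`.  Labels are parsed
#' case-insensitively to `sMCI`/`pMCI` (empty or `NA` means unknown).  APOE
#' genotype tokens must be covered by `risk_map`.
#'
#' @param path CSV path.
#' @param risk_map genotype risk mapping used to validate tokens.
#' @return a data.frame of subject records.
#' @export
read_subject_table <- function(path, risk_map = apoe_risk_map()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  needed <- c("subject_id", "mmse", "faq", "cdr_sb", "adas", "age", "apoe",
              "label")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("subject table is missing column(s): ", paste(missing, collapse = ", "))
  df <- df[, needed]
  if (nrow(df) == 0) return(df)
  for (col in c("mmse", "faq", "cdr_sb", "adas", "age")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (any(is.na(v)))
      stop("unparsable numeric in column '", col, "' (row ",
           which(is.na(v))[1], ")")
    df[[col]] <- v
  }
  if (any(df$age <= 0)) stop("age must be positive")
  bad <- setdiff(unique(df$apoe), names(risk_map))
  if (length(bad))
    stop("unknown APOE genotype token(s): ", paste(bad, collapse = ", "),
         " (supply a risk value via apoe_risk_map(extra=))")
  lab <- tolower(trimws(as.character(df$label)))
  parsed <- ifelse(lab %in% "smci", "sMCI",
                   ifelse(lab %in% "pmci", "pMCI", NA_character_))
  unknown <- !is.na(lab) & nzchar(lab) & is.na(parsed)
  if (any(unknown))
    stop("unparsable label(s): ", paste(unique(df$label[unknown]), collapse = ", "))
  df$label <- parsed
  df
}

#' @rdname read_subject_table
#' @param table data.frame as returned by `read_subject_table()`.
#' @export
write_subject_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' Atlas bundle
#'
#' Bundles the atlas template volume, its binary brain mask (same grid), the
#' six template landmarks and the segment box definitions used for cropping.
#'
#' @param template `mci_volume` template image.
#' @param brain_mask `mci_volume` binary mask on the same grid.
#' @param landmarks [landmark_set()] in template world coordinates.
#' @param segment_specs list of [segment_spec()] entries.
#' @return an `atlas_bundle`.
#' @export
atlas_bundle <- function(template, brain_mask, landmarks, segment_specs) {
  stopifnot(is_volume(template), is_volume(brain_mask),
            inherits(landmarks, "landmark_set"))
  if (!all(dim(template$data) == dim(brain_mask$data)))
    stop("template and brain mask must share a grid")
  if (max(abs(template$affine - brain_mask$affine)) > 1e-6)
    stop("template and brain mask must share an affine")
  if (sum(brain_mask$data > 0) == 0) stop("brain mask has no foreground voxels")
  vox <- world_to_voxel(template, unclass(landmarks))
  d <- dim(template$data)
  if (any(vox < -0.5) || any(vox > rep(d - 0.5, each = 6)))
    stop("landmarks must lie inside the template bounds")
  structure(list(template = template, brain_mask = brain_mask,
                 landmarks = landmarks, segment_specs = segment_specs),
            class = "atlas_bundle")
}

#' @export
print.atlas_bundle <- function(x, ...) {
  cat("<atlas_bundle> template ", paste(dim(x$template$data), collapse = "x"),
      ", mask foreground ", sum(x$brain_mask$data > 0), " voxels, ",
      length(x$segment_specs), " segment boxes\n", sep = "")
  invisible(x)
}

#' Segment box specification
#'
#' An axis-aligned cubic crop box in atlas space.  Full-scale boxes are
#' 64 x 64 x 64 voxels; scaled-down phantom configurations may use smaller
#' cubes.
#'
#' @param name one of `hippocampus_L`, `hippocampus_R`, `ant_temporal_L`,
#'   `ant_temporal_R`.
#' @param center world coordinate (mm) of the box centre.
#' @param size cube edge length in voxels.
#' @return a `segment_spec`.
#' @export
segment_spec <- function(name, center, size = 64L) {
  name <- match.arg(name, c("hippocampus_L", "hippocampus_R",
                            "ant_temporal_L", "ant_temporal_R"))
  structure(list(name = name, center = as.numeric(center),
                 size = as.integer(size),
                 laterality = if (grepl("_L$", name)) "L" else "R"),
            class = "segment_spec")
}
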