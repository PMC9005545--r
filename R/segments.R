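#' Atlas-mask skull stripping
#'
#' Fallback skull stripping for shape-normalized images: voxels outside the
#' atlas brain mask are set to zero.  Optionally the mask is refined by
#' intensity thresholding inside a 3-voxel dilation band (voxels in the band
#' darker than `threshold` times the in-mask median are also removed) —
#' disabled by default, where the operation is a pure mask application.
#'
#' @param volume shape-normalized `mci_volume` on the atlas grid.
#' @param atlas an [atlas_bundle()].
#' @param refine logical; apply the band refinement.
#' @param threshold refinement threshold (fraction of in-mask median).
#' @return masked `mci_volume`.
#' @export
skull_strip_fallback <- function(volume, atlas, refine = FALSE,
                                 threshold = 0.25) {
  stopifnot(all(dim(volume$data) == dim(atlas$brain_mask$data)))
  m <- atlas$brain_mask$data > 0
  out <- volume$data
  if (refine) {
    dil <- dilate_mask(m, 3L)
    band <- dil & !m
    med <- stats::median(out[m])
    keep_band <- band & (out > threshold * med)
    m2 <- m | keep_band
    out[!m2] <- 0
  } else {
    out[!m] <- 0
  }
  as_volume(out, spacing = volume$spacing, affine = volume$affine,
            space = volume$space)
}

# binary dilation by r voxels (chebyshev ball) via max-filtering per axis
dilate_mask <- function(m, r) {
  a <- m * 1
  for (ax in 1:3) {
    d <- dim(a)
    shifted <- a
    for (s in seq_len(r)) {
      idx_lo <- pmax(seq_len(d[ax]) - s, 1)
      idx_hi <- pmin(seq_len(d[ax]) + s, d[ax])
      sel <- function(idx) {
        args <- list(a, 1:d[1], 1:d[2], 1:d[3])
        args[[ax + 1]] <- idx
        do.call(`[`, args)
      }
      shifted <- pmax(shifted, sel(idx_lo), sel(idx_hi))
    }
    a <- shifted
  }
  a > 0
}

#' Extract a fixed segment crop
#'
#' Crops the axis-aligned cube defined by a [segment_spec()] from a volume
#' already in atlas (shape-normalized) space.  No resampling: the crop is the
#' exact source sub-array.  A box extending beyond the volume bounds is an
#' error.
#'
#' @param volume `mci_volume` on the atlas grid.
#' @param spec a [segment_spec()].
#' @return 3D array of side `spec$size`, with attributes `segment` and
#'   `start` (1-based corner index).
#' @export
extract_segment <- function(volume, spec) {
  d <- dim(volume$data)
  cvox <- round(world_to_voxel(volume, spec$center))  # 0-based
  half <- spec$size %/% 2
  start <- as.integer(cvox) - half + 1L  # 1-based corner; centre voxel at size/2
  end <- start + spec$size - 1L
  if (any(start < 1L) || any(end > d))
    stop("segment box '", spec$name, "' exceeds volume bounds (",
         paste(start, collapse = ","), " .. ", paste(end, collapse = ","), ")")
  crop <- volume$data[start[1]:end[1], start[2]:end[2], start[3]:end[3]]
  attr(crop, "segment") <- spec$name
  attr(crop, "start") <- start
  crop
}

#' Mirror a segment crop across the left-right axis
#'
#' Reverses the crop along the first (x, left-right in RAS) axis so that
#' left-hemisphere segments can be pooled with right-hemisphere ones when
#' training a shared network.  An involution: `flip_lr(flip_lr(x))` is
#' bit-identical to `x`.
#'
#' @param crop 3D array.
#' @return flipped 3D array.
#' @export
flip_lr <- function(crop) {
  out <- crop[dim(crop)[1]:1, , , drop = FALSE]
  attr(out, "segment") <- attr(crop, "segment")
  out
}

#' Scale segment intensities to the unit interval
#'
#' Clips to `[0, max_intensity]` then divides by `max_intensity` (fixed at
#' 400, the nominal white-matter-plus-margin ceiling of the normalized
#' intensity scale).
#'
#' @param crop numeric array.
#' @param max_intensity fixed ceiling (default 400).
#' @return array with values in `[0, 1]`.
#' @export
scale_intensity <- function(crop, max_intensity = 400) {
  pmin(pmax(crop, 0), max_intensity) / max_intensity
}

#' Extract the four-segment stack of one subject
#'
#' Applies skull stripping and crops the four configured segments
#' (hippocampus L/R, anterior temporal L/R) from a shape-normalized,
#' intensity-normalized volume, scaling each crop to `[0, 1]`.
#'
#' @param volume `mci_volume` in atlas space.
#' @param atlas an [atlas_bundle()].
#' @param subject_id identifier carried in the result.
#' @param skull_strip logical; apply [skull_strip_fallback()] first.
#' @return a `segment_stack`: list of 4 crops keyed by segment name.
#' @export
segment_stack <- function(volume, atlas, subject_id = "subject",
                          skull_strip = TRUE) {
  if (skull_strip) volume <- skull_strip_fallback(volume, atlas)
  crops <- lapply(atlas$segment_specs, function(sp)
    scale_intensity(extract_segment(volume, sp)))
  names(crops) <- vapply(atlas$segment_specs, `[[`, "", "name")
  structure(list(subject_id = subject_id, crops = crops,
                 space = "shape_normalized"),
            class = "segment_stack")
}

#' @export
print.segment_stack <- function(x, ...) {
  cat("<segment_stack> ", x$subject_id, ": ",
      paste(names(x$crops), collapse = ", "), " (",
      paste(dim(x$crops[[1]]), collapse = "x"), " each)\n", sep = "")
  invisible(x)
}
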