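#' 3D volume container
#'
#' A `mci_volume` wraps a 3D scalar array together with its voxel spacing (mm),
#' a 4x4 voxel-to-world affine (RAS convention, 0-based voxel indices) and a
#' `space` tag recording which stage of the pipeline produced it.
#'
#' @param data 3D numeric array.
#' @param spacing numeric length-3, mm per voxel along each axis (positive).
#' @param affine 4x4 voxel-to-world matrix; defaults to `diag(spacing)` with
#'   origin at 0.
#' @param space one of `"native"`, `"shape_normalized"`, `"warped_to_atlas"`.
#' @return An object of class `mci_volume`.
#' @export
as_volume <- function(data, spacing = c(1, 1, 1), affine = NULL,
                      space = c("native", "shape_normalized", "warped_to_atlas")) {
  space <- match.arg(space)
  data <- unclass(data)
  if (length(dim(data)) != 3L)
    stop("volume data must have exactly 3 axes, got ", length(dim(data)))
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 strictly positive finite values")
  if (is.null(affine)) {
    affine <- diag(4)
    affine[1:3, 1:3] <- diag(spacing)
  }
  affine <- unname(as.matrix(affine))
  if (!all(dim(affine) == c(4, 4)) || abs(det(affine)) < 1e-12)
    stop("affine must be an invertible 4x4 matrix")
  structure(list(data = data, spacing = spacing, affine = affine,
                 space = space),
            class = "mci_volume")
}

#' @export
print.mci_volume <- function(x, ...) {
  cat("<mci_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = "/"),
      " mm, space: ", x$space, "\n", sep = "")
  cat("  intensity range: ", paste(signif(range(x$data), 5), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.mci_volume <- function(x) dim(x$data)

is_volume <- function(x) inherits(x, "mci_volume")

#' Convert between voxel and world coordinates
#'
#' Voxel indices are 0-based, following the NIfTI convention, so the world
#' position of array element `[i, j, k]` is `affine %*% c(i-1, j-1, k-1, 1)`.
#'
#' @param vol an `mci_volume`.
#' @param pts n x 3 matrix of coordinates (rows are points).
#' @return n x 3 matrix of transformed coordinates.
#' @export
voxel_to_world <- function(vol, pts) {
  pts <- rbind_pts(pts)
  t(vol$affine %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(vol, pts) {
  pts <- rbind_pts(pts)
  t(solve(vol$affine) %*% rbind(t(pts), 1))[, 1:3, drop = FALSE]
}

rbind_pts <- function(pts) {
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 3)
  as.matrix(pts)
}

# World coordinates of every voxel of a volume, as an n x 3 matrix in array
# order (first axis fastest).
grid_world_coords <- function(vol) {
  d <- dim(vol$data)
  ijk <- cbind(
    rep.int(seq_len(d[1]) - 1, d[2] * d[3]),
    rep.int(rep(seq_len(d[2]) - 1, each = d[1]), d[3]),
    rep(seq_len(d[3]) - 1, each = d[1] * d[2]))
  voxel_to_world(vol, ijk)
}

#' Read / write volumes as NIfTI-1
#'
#' `read_volume()` reads a `.nii`/`.nii.gz` file into an [as_volume()]
#' container; `write_volume()` writes one back.  Data round-trips bit exactly
#' (stored as float64) and the affine to single precision (well within 1e-5).
#'
#' @param path file path.
#' @param space space tag to attach on read (not stored in the NIfTI header).
#' @param volume an `mci_volume`.
#' @return `read_volume()` returns an `mci_volume`; `write_volume()` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path, space = "native") {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  nd <- length(dim(img))
  if (nd != 3L) {
    d <- dim(img)
    # trailing singleton dims are tolerated; anything else is malformed here
    if (nd > 3L && all(d[-(1:3)] == 1L)) {
      img <- array(as.array(img), d[1:3])
    } else {
      stop("format error in '", path, "': field dim describes a ", nd,
           "-dimensional image, expected 3 axes")
    }
  }
  aff <- unname(structure(RNifti::xform(img), code = NULL))
  attr(aff, "imagedim") <- NULL
  attr(aff, "code") <- NULL
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr)[1:3])
  sp <- abs(RNifti::pixdim(img))[1:3]
  sp[sp == 0] <- 1
  as_volume(arr, spacing = sp, affine = matrix(aff, 4, 4), space = space)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  stopifnot(is_volume(volume))
  if (!dir.exists(dirname(path))) stop("parent directory does not exist: ",
                                       dirname(path))
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- volume$spacing
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

# Trilinear interpolation of a plain 3D array at (possibly fractional) 0-based
# voxel coordinates.  Points outside the array evaluate to `outside`.
interp_trilinear <- function(arr, vox0, outside = 0) {
  d <- dim(arr)
  x <- vox0[, 1]; y <- vox0[, 2]; z <- vox0[, 3]
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  # valid if the full 8-neighbourhood (after clamping the ==d-1 edge) exists
  ok <- x >= 0 & y >= 0 & z >= 0 & x <= d[1] - 1 & y <= d[2] - 1 & z <= d[3] - 1
  out <- rep(outside, length(x))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; z0 <- z0[ok]
  fx <- fx[ok]; fy <- fy[ok]; fz <- fz[ok]
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  ix <- function(a, b, c) a + d[1] * (b + d[2] * c) + 1
  v000 <- arr[ix(x0, y0, z0)]; v100 <- arr[ix(x1, y0, z0)]
  v010 <- arr[ix(x0, y1, z0)]; v110 <- arr[ix(x1, y1, z0)]
  v001 <- arr[ix(x0, y0, z1)]; v101 <- arr[ix(x1, y0, z1)]
  v011 <- arr[ix(x0, y1, z1)]; v111 <- arr[ix(x1, y1, z1)]
  out[ok] <-
    ((v000 * (1 - fx) + v100 * fx) * (1 - fy) +
     (v010 * (1 - fx) + v110 * fx) * fy) * (1 - fz) +
    ((v001 * (1 - fx) + v101 * fx) * (1 - fy) +
     (v011 * (1 - fx) + v111 * fx) * fy) * fz
  out
}

# Sample a volume at world points (n x 3), trilinear, 0 outside the field.
sample_volume_world <- function(vol, world_pts, outside = 0) {
  interp_trilinear(vol$data, world_to_voxel(vol, world_pts), outside = outside)
}
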