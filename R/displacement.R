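#' Dense displacement field
#'
#' A displacement field defined on a reference grid: a 4D array
#' `(nx, ny, nz, 3)` holding, at each reference voxel, a world-space (mm)
#' displacement `u(X)`.  As a transform it maps `T(X) = X + u(X)` with
#' trilinear interpolation of `u` between voxel centres (zero outside the
#' grid).
#'
#' @param u 4D numeric array `(nx, ny, nz, 3)` of mm displacements.
#' @param reference `mci_volume` (or atlas bundle) whose grid the field lives
#'   on.
#' @return a `displacement_field`.
#' @export
displacement_field <- function(u, reference) {
  if (inherits(reference, "atlas_bundle")) reference <- reference$template
  stopifnot(length(dim(u)) == 4L, dim(u)[4] == 3L,
            all(dim(u)[1:3] == dim(reference$data)))
  structure(list(u = u, spacing = reference$spacing,
                 affine = reference$affine, dim = dim(u)[1:3]),
            class = "displacement_field")
}

#' @export
print.displacement_field <- function(x, ...) {
  mag <- sqrt(x$u[, , , 1]^2 + x$u[, , , 2]^2 + x$u[, , , 3]^2)
  cat("<displacement_field> ", paste(x$dim, collapse = "x"),
      " grid, |u| max ", signif(max(mag), 4), " mm, mean ",
      signif(mean(mag), 4), " mm\n", sep = "")
  invisible(x)
}

field_ref_volume <- function(field) {
  as_volume(array(0, field$dim), spacing = field$spacing, affine = field$affine)
}

# u interpolated at world points; coordinates are clamped to the grid so the
# field extends continuously (nearest-edge) beyond its domain, which keeps the
# fixed-point inversion a contraction near the boundary.
field_u_at <- function(field, pts) {
  ref <- field_ref_volume(field)
  vox <- world_to_voxel(ref, pts)
  for (a in 1:3) vox[, a] <- pmin(pmax(vox[, a], 0), field$dim[a] - 1)
  cbind(interp_trilinear(field$u[, , , 1], vox),
        interp_trilinear(field$u[, , , 2], vox),
        interp_trilinear(field$u[, , , 3], vox))
}

displace_points <- function(field, pts) {
  pts + field_u_at(field, pts)
}

#' Invert a displacement transform on a grid
#'
#' Computes a dense inverse displacement `v` such that
#' `(X + v(X)) + u(X + v(X)) = X` by damped fixed-point iteration
#' `v <- -u(X + v)` (at most `max_iter` sweeps, stopping when the largest
#' update falls below `tol` voxels).  Errors if the forward field is locally
#' non-invertible (finite-difference Jacobian determinant <= 0).
#'
#' @param transform a [displacement_field()] or [bspline_transform()].
#' @param grid reference `mci_volume` (or atlas bundle) for the inverse field;
#'   defaults to the transform's own grid.
#' @param max_iter,tol iteration cap and convergence tolerance (voxels).
#' @return a `displacement_field` holding the inverse displacement, with
#'   attribute `composition_error` (mm residual of forward-after-inverse).
#' @export
invert_transform_on_grid <- function(transform, grid = NULL, max_iter = 50L,
                                     tol = 1e-3) {
  if (inherits(transform, "bspline_transform"))
    transform <- bspline_to_field(transform)
  stopifnot(inherits(transform, "displacement_field"))
  if (is.null(grid)) grid <- field_ref_volume(transform)
  if (inherits(grid, "atlas_bundle")) grid <- grid$template
  jmin <- min_jacobian_det(transform)
  if (jmin <= 0)
    stop("displacement field is non-invertible (Jacobian determinant ",
         signif(jmin, 4), " <= 0)")
  X <- grid_world_coords(grid)
  v <- -field_u_at(transform, X)
  sp_min <- min(grid$spacing)
  for (it in seq_len(max_iter)) {
    vnew <- -field_u_at(transform, X + v)
    delta <- max(abs(vnew - v)) / sp_min
    v <- vnew
    if (delta < tol) break
  }
  resid <- X + v + field_u_at(transform, X + v) - X
  out <- displacement_field(array(v, c(dim(grid$data), 3)), grid)
  attr(out, "composition_error") <- sqrt(rowSums(resid^2))
  out
}

# Minimum finite-difference Jacobian determinant of X + u(X), interior voxels.
min_jacobian_det <- function(field) {
  u <- field$u
  sp <- field$spacing
  d <- field$dim
  if (any(d < 3)) return(1)
  J11 <- diffc(u[, , , 1], 1) / sp[1] + 1
  J12 <- diffc(u[, , , 1], 2) / sp[2]
  J13 <- diffc(u[, , , 1], 3) / sp[3]
  J21 <- diffc(u[, , , 2], 1) / sp[1]
  J22 <- diffc(u[, , , 2], 2) / sp[2] + 1
  J23 <- diffc(u[, , , 2], 3) / sp[3]
  J31 <- diffc(u[, , , 3], 1) / sp[1]
  J32 <- diffc(u[, , , 3], 2) / sp[2]
  J33 <- diffc(u[, , , 3], 3) / sp[3] + 1
  det <- J11 * (J22 * J33 - J23 * J32) - J12 * (J21 * J33 - J23 * J31) +
    J13 * (J21 * J32 - J22 * J31)
  min(det)
}

# Central difference along one axis (one-sided at the edges), same-size array.
diffc <- function(a, axis) {
  d <- dim(a)
  n <- d[axis]
  idx_hi <- pmin(seq_len(n) + 1, n)
  idx_lo <- pmax(seq_len(n) - 1, 1)
  sel <- function(idx) {
    args <- list(a, 1:d[1], 1:d[2], 1:d[3])
    args[[axis + 1]] <- idx
    do.call(`[`, args)
  }
  denom <- idx_hi - idx_lo
  shape <- c(1, 1, 1); shape[axis] <- n
  (sel(idx_hi) - sel(idx_lo)) / array(rep(denom, each = prod(d[seq_len(axis - 1)])),
                                      dim = d)
}
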