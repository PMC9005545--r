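#' 9-degree-of-freedom similarity transform
#'
#' A similarity transform with three rotation angles (degrees, intrinsic
#' x-y-z order), three positive per-axis scale factors and three translations
#' (mm), applied about a fixed centre `c`:
#' \deqn{y = c + S R (x - c) + t}
#' where `S = diag(scale)` and `R = Rx Ry Rz`.  This is the linear transform
#' used for shape normalization: it adjusts location, orientation and size but
#' introduces no shear.
#'
#' @param rotation numeric length-3, degrees about x, y, z.
#' @param scale numeric length-3, positive.
#' @param translation numeric length-3, mm.
#' @param center numeric length-3, mm; rotation/scaling centre.
#' @return a `similarity9` object.
#' @export
similarity9 <- function(rotation = c(0, 0, 0), scale = c(1, 1, 1),
                        translation = c(0, 0, 0), center = c(0, 0, 0)) {
  scale <- as.numeric(scale)
  if (any(scale <= 0)) stop("scales must be strictly positive")
  structure(list(rotation = as.numeric(rotation), scale = scale,
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "similarity9")
}

#' @export
print.similarity9 <- function(x, ...) {
  cat("<similarity9> rot (deg):", paste(signif(x$rotation, 5), collapse = ", "),
      "| scale:", paste(signif(x$scale, 5), collapse = ", "),
      "| trans (mm):", paste(signif(x$translation, 5), collapse = ", "), "\n")
  invisible(x)
}

rot_matrix_xyz <- function(deg) {
  r <- deg * pi / 180
  cx <- cos(r[1]); sx <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cz <- cos(r[3]); sz <- sin(r[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rx %*% Ry %*% Rz
}

# Euler angles (degrees, intrinsic x-y-z) from a rotation matrix R = Rx Ry Rz.
euler_from_rot <- function(R) {
  sy <- -R[3, 1]
  ry <- asin(max(-1, min(1, sy)))
  if (abs(cos(ry)) > 1e-8) {
    rx <- atan2(R[3, 2], R[3, 3])
    rz <- atan2(R[2, 1], R[1, 1])
  } else {  # gimbal: fold z into x
    rx <- atan2(-R[2, 3], R[2, 2])
    rz <- 0
  }
  c(rx, ry, rz) * 180 / pi
}

#' Convert a similarity transform to a 4x4 matrix
#' @param tr a [similarity9()].
#' @return 4x4 homogeneous matrix in world (mm) coordinates.
#' @export
similarity_matrix <- function(tr) {
  A <- diag(tr$scale) %*% rot_matrix_xyz(tr$rotation)
  M <- diag(4)
  M[1:3, 1:3] <- A
  M[1:3, 4] <- tr$center + tr$translation - A %*% tr$center
  M
}

#' Apply a spatial transform to points
#'
#' Generic over the transform representations used in the pipeline:
#' `similarity9`, 4x4 matrices, displacement fields ([displacement_field()]),
#' `"identity"`, and lists of transforms (applied left to right).
#'
#' @param tr a transform.
#' @param pts n x 3 matrix of world points (mm).
#' @return n x 3 matrix of mapped points.
#' @export
transform_points <- function(tr, pts) {
  pts <- rbind_pts(pts)
  if (identical(tr, "identity")) return(pts)
  if (inherits(tr, "similarity9")) tr <- similarity_matrix(tr)
  if (is.matrix(tr) && all(dim(tr) == c(4, 4)))
    return(t(tr %*% rbind(t(pts), 1))[, 1:3, drop = FALSE])
  if (inherits(tr, "displacement_field"))
    return(displace_points(tr, pts))
  if (is.list(tr)) {
    for (t1 in tr) pts <- transform_points(t1, pts)
    return(pts)
  }
  stop("unsupported transform type")
}

#' Landmark-based 9-DOF similarity fit
#'
#' Estimates the similarity transform (3 rotations, 3 anisotropic scales,
#' 3 translations) minimizing the total squared error
#' \deqn{\sum_i \| Q_i - (S R P_i + T) \|^2}
#' between transformed atlas landmarks \eqn{P_i} and subject landmarks
#' \eqn{Q_i}.  A closed-form isotropic Procrustes solution initializes a
#' damped Gauss-Newton refinement over the 9 parameters (no closed form exists
#' once the scales are anisotropic).  Rotation and scaling act about the atlas
#' landmark centroid, which improves conditioning; the reported translation is
#' the effective offset at that centre.
#'
#' @param atlas_landmarks,subject_landmarks [landmark_set()]s (or plain
#'   n x 3 matrices with matched rows).
#' @param max_iter Gauss-Newton iteration cap.
#' @param tol parameter-step convergence tolerance.
#' @return a `similarity9` with attributes `objective` (sum of squared
#'   residuals), `residuals` (per-landmark residual norms, mm) and
#'   `initial_objective`.
#' @export
fit_similarity_9dof <- function(atlas_landmarks, subject_landmarks,
                                max_iter = 200L, tol = 1e-14) {
  P <- unclass(rbind_pts(atlas_landmarks))
  Q <- unclass(rbind_pts(subject_landmarks))
  if (nrow(P) != nrow(Q)) stop("landmark sets must have matched points")
  n <- nrow(P)
  if (n < 4) stop("need at least 4 landmark pairs")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2, ctr)
  if (svd(Pc)$d[3] < 1e-8 * svd(Pc)$d[1])
    stop("atlas landmarks are coplanar or degenerate: the 9-DOF fit is ill-posed")

  # --- isotropic Procrustes (Umeyama) initialization ---
  qbar <- colMeans(Q)
  Qc <- sweep(Q, 2, qbar)
  S <- crossprod(Qc, Pc) / n
  sv <- svd(S)
  D <- diag(c(1, 1, sign(det(sv$u %*% t(sv$v)))))
  R0 <- sv$u %*% D %*% t(sv$v)
  varP <- sum(Pc^2) / n
  s0 <- sum(diag(diag(sv$d) %*% D)) / varP
  theta <- c(euler_from_rot(R0), rep(max(s0, 1e-3), 3), qbar - ctr)

  resid_fun <- function(th) {
    A <- diag(th[4:6]) %*% rot_matrix_xyz(th[1:3])
    pred <- t(A %*% t(Pc)) + matrix(ctr + th[7:9], n, 3, byrow = TRUE)
    as.vector(Q - pred)
  }
  obj <- function(th) sum(resid_fun(th)^2)
  f0 <- obj(theta)
  lambda <- 1e-6
  f <- f0
  step <- rep(Inf, 9)
  for (it in seq_len(max_iter)) {
    r <- resid_fun(theta)
    # numerical Jacobian (central differences)
    J <- matrix(0, length(r), 9)
    for (j in 1:9) {
      h <- max(1e-7, 1e-7 * abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      J[, j] <- (resid_fun(tp) - resid_fun(tm)) / (2 * h)
    }
    g <- crossprod(J, r)
    H <- crossprod(J)
    repeat {
      step <- tryCatch(solve(H + lambda * diag(9), g),
                       error = function(e) NULL)
      if (is.null(step)) { lambda <- lambda * 10; next }
      cand <- theta - as.vector(step)
      cand[4:6] <- pmax(cand[4:6], 1e-6)
      fc <- obj(cand)
      if (fc <= f) {
        theta <- cand; f <- fc; lambda <- max(lambda / 3, 1e-12)
        break
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (max(abs(step)) < tol || lambda > 1e12) break
  }
  stopifnot(f <= f0 + 1e-12)
  res <- matrix(resid_fun(theta), n, 3)
  out <- similarity9(rotation = theta[1:3], scale = theta[4:6],
                     translation = theta[7:9], center = ctr)
  attr(out, "objective") <- f
  attr(out, "initial_objective") <- f0
  attr(out, "residuals") <- sqrt(rowSums(res^2))
  out
}

#' Serialize / read a similarity transform as JSON
#' @param tr a [similarity9()].
#' @param path file path.
#' @export
write_similarity <- function(tr, path) {
  jsonlite::write_json(unclass(tr), path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_similarity
#' @export
read_similarity <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  similarity9(o$rotation, o$scale, o$translation, o$center)
}

#' Invert a similarity transform
#' @param tr a [similarity9()].
#' @return the inverse as a 4x4 matrix.
#' @export
invert_similarity <- function(tr) solve(similarity_matrix(tr))

#' Resample a volume through a spatial transform
#'
#' Evaluates `volume` at `transform(X)` for every voxel centre `X` of the
#' reference grid (the ITK resampling convention: the transform maps reference
#' space into input space).  Out-of-field voxels are set to 0.
#'
#' @param volume input `mci_volume`.
#' @param transform anything accepted by [transform_points()].
#' @param reference `mci_volume` (or atlas bundle) defining the output grid.
#' @param interpolation `"linear"` (default) or `"nearest"`.
#' @param space space tag for the output.
#' @return `mci_volume` on the reference grid.
#' @export
resample <- function(volume, transform, reference,
                     interpolation = c("linear", "nearest"),
                     space = volume$space) {
  interpolation <- match.arg(interpolation)
  if (inherits(reference, "atlas_bundle")) reference <- reference$template
  pts <- grid_world_coords(reference)
  mapped <- transform_points(transform, pts)
  vox <- world_to_voxel(volume, mapped)
  if (interpolation == "nearest") vox <- round(vox)
  vals <- interp_trilinear(volume$data, vox)
  as_volume(array(vals, dim(reference$data)), spacing = reference$spacing,
            affine = reference$affine, space = space)
}
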