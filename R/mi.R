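#' Masked mutual information between two images
#'
#' Histogram-based mutual information (nats) between two equally sized arrays,
#' computed from a joint histogram with `bins` x `bins` equal-width bins over
#' the masked intensity ranges.
#'
#' @param a,b numeric arrays/vectors of equal length.
#' @param mask logical/numeric selector; only voxels with `mask > 0` count.
#' @param bins number of histogram bins per image (default 32).
#' @return mutual information in nats.
#' @export
mutual_information <- function(a, b, mask = NULL, bins = 32L) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (!is.null(mask)) {
    keep <- as.numeric(mask) > 0
    if (!any(keep)) stop("mask is empty")
    a <- a[keep]; b <- b[keep]
  }
  ra <- range(a); rb <- range(b)
  if (diff(ra) == 0 || diff(rb) == 0) return(0)
  ia <- pmin(pmax(floor((a - ra[1]) / diff(ra) * bins) + 1, 1), bins)
  ib <- pmin(pmax(floor((b - rb[1]) / diff(rb) * bins) + 1, 1), bins)
  joint <- tabulate(ia + bins * (ib - 1), nbins = bins * bins)
  p <- joint / sum(joint)
  pj <- matrix(p, bins, bins)
  pa <- rowSums(pj); pb <- colSums(pj)
  nz <- pj > 0
  sum(pj[nz] * log(pj[nz] / (pa[row(pj)[nz]] * pb[col(pj)[nz]])))
}

#' Refine a similarity transform by mutual-information registration
#'
#' Refines an initial landmark-derived 9-DOF similarity transform by
#' maximizing the mutual information between the resampled moving image and
#' the fixed (atlas) image, evaluated only inside the brain mask.  Histogram
#' MI with 32 bins, Nelder-Mead optimization over the 9 parameters, and a
#' multiresolution pyramid (coarse to fine).  The routine is deterministic
#' and never returns a transform with lower full-resolution masked MI than
#' the initialization.
#'
#' @param moving native-space `mci_volume`.
#' @param fixed atlas template `mci_volume` (or atlas bundle, whose mask is
#'   then used when `mask` is missing).
#' @param mask binary `mci_volume` on the fixed grid.
#' @param init initial [similarity9()] (landmark fit output).
#' @param bins histogram bins.
#' @param levels pyramid levels (downsampling factors `2^(levels-1) .. 1`).
#' @param maxit per-level Nelder-Mead iteration caps (recycled).
#' @return refined `similarity9` with attribute `mi` = c(init, final).
#' @export
refine_similarity_mi <- function(moving, fixed, mask = NULL, init = similarity9(),
                                 bins = 32L, levels = 3L,
                                 maxit = c(200L, 120L, 60L)) {
  if (inherits(fixed, "atlas_bundle")) {
    if (is.null(mask)) mask <- fixed$brain_mask
    fixed <- fixed$template
  }
  if (is.null(mask) || sum(mask$data > 0) == 0) stop("mask is empty")
  maxit <- rep_len(maxit, levels)
  ctr <- init$center
  theta <- c(init$rotation, init$scale, init$translation)
  obj_level <- function(fx, mk) {
    Xw <- grid_world_coords(fx)
    keep <- as.vector(mk$data) > 0.5
    Xw <- Xw[keep, , drop = FALSE]
    fv <- as.vector(fx$data)[keep]
    function(th) {
      tr <- similarity9(th[1:3], pmax(th[4:6], 1e-3), th[7:9], ctr)
      mv <- sample_volume_world(moving, transform_points(tr, Xw))
      -mutual_information(mv, fv, bins = bins)
    }
  }
  for (lev in seq(levels, 1)) {
    f <- 2^(lev - 1)
    fx <- downsample_volume(fixed, f)
    mk <- downsample_volume(mask, f, smooth = FALSE)
    fn <- obj_level(fx, mk)
    o <- stats::optim(theta, fn, method = "Nelder-Mead",
                      control = list(maxit = maxit[levels - lev + 1],
                                     parscale = c(1, 1, 1, .02, .02, .02, 1, 1, 1),
                                     reltol = 1e-7))
    theta <- o$par
  }
  refined <- similarity9(theta[1:3], pmax(theta[4:6], 1e-3), theta[7:9], ctr)
  # full-resolution guard: keep the better of init and refined
  Xw <- grid_world_coords(fixed)
  keep <- as.vector(mask$data) > 0.5
  Xw <- Xw[keep, , drop = FALSE]
  fv <- as.vector(fixed$data)[keep]
  mi_of <- function(tr)
    mutual_information(sample_volume_world(moving, transform_points(tr, Xw)),
                       fv, bins = bins)
  mi_init <- mi_of(init)
  mi_ref <- mi_of(refined)
  if (mi_ref < mi_init) {
    refined <- init
    mi_ref <- mi_init
  }
  attr(refined, "mi") <- c(init = mi_init, final = mi_ref)
  refined
}
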