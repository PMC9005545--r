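test_that("MI refinement of an already aligned pair stays near identity", {
  atlas <- test_atlas()
  ctr <- attr(atlas, "phantom_params")$center_mm
  ref <- refine_similarity_mi(atlas$template, atlas$template,
                              atlas$brain_mask,
                              init = similarity9(center = ctr),
                              levels = 2L, maxit = c(60L, 30L))
  sp <- atlas$template$spacing[1]
  expect_lt(max(abs(ref$rotation)), 0.1)
  expect_lt(max(abs(ref$translation)) / sp, 0.1)
  expect_lt(max(abs(ref$scale - 1)), 0.01)
})

test_that("MI refinement recovers a known 2-voxel translation", {
  atlas <- test_atlas()
  pp <- attr(atlas, "phantom_params")
  sp <- pp$spacing
  shift <- similarity9(translation = c(2 * sp, 0, 0), center = pp$center_mm)
  moving <- resample(atlas$template, shift, atlas$template)
  ref <- refine_similarity_mi(moving, atlas$template, atlas$brain_mask,
                              init = similarity9(center = pp$center_mm))
  # aligning moving onto the template needs the inverse shift
  expect_lt(max(abs(ref$translation - c(-2 * sp, 0, 0))) / sp, 0.5)
  mi <- attr(ref, "mi")
  expect_gte(mi["final"], mi["init"])
})

test_that("MI never decreases across a phantom cohort and the full spatial
           chain beats naive resampling", {
  bm <- test_benchmark()
  atlas <- test_atlas()
  msk <- atlas$brain_mask$data > 0
  improved <- logical(20)
  mi_ok <- logical(20)
  for (i in 1:20) {
    s <- bm$cohort$subjects[[i]]
    fit <- fit_similarity_9dof(atlas$landmarks, s$landmarks)
    ref <- refine_similarity_mi(s$volume, atlas$template, atlas$brain_mask,
                                init = fit, levels = 2L,
                                maxit = c(30L, 12L))
    mi <- attr(ref, "mi")
    mi_ok[i] <- mi["final"] >= mi["init"] - 1e-9
    sn <- resample(s$volume, ref, atlas$template)
    improved[i] <- masked_rmse(sn, atlas$template, msk) <
      masked_rmse(s$volume, atlas$template, msk)
  }
  expect_true(all(mi_ok))
  expect_gte(mean(improved), 0.95)
})

test_that("registering identical images yields a near-zero deformation", {
  atlas <- test_atlas()
  bs <- register_bspline(atlas$template, atlas$template, atlas$brain_mask,
                         spacing_vox = 12, levels = 2L, iters = 10L)
  u <- bspline_to_field(bs)$u
  expect_lt(max(abs(u)) / atlas$template$spacing[1], 0.5)
})

test_that("a known smooth deformation is recovered and warping improves the
           masked alignment and MI", {
  atlas <- test_atlas()
  set.seed(5)
  u <- array(0, c(64, 64, 64, 3))
  for (c in 1:3)
    u[, , , c] <- mciprog:::random_smooth_field(c(64, 64, 64), 12, 2.0)
  def <- displacement_field(u, atlas$template)
  moving <- resample(atlas$template, def, atlas$template)
  bs <- register_bspline(moving, atlas$template, atlas$brain_mask,
                         spacing_vox = 12, levels = 3L, iters = 30L)
  # recovered field vs the true inverse, in voxels, inside the mask
  inv_true <- invert_transform_on_grid(def)
  urec <- bspline_to_field(bs)$u
  err <- sqrt(rowSums((matrix(urec, ncol = 3) -
                       matrix(inv_true$u, ncol = 3))^2))
  msk <- as.vector(atlas$brain_mask$data > 0)
  sp <- atlas$template$spacing[1]
  expect_lt(mean(err[msk]) / sp, 1)

  w <- warp(moving, bs)
  expect_lt(masked_rmse(w, atlas$template, atlas$brain_mask),
            masked_rmse(moving, atlas$template, atlas$brain_mask))
  expect_gte(mutual_information(w$data, atlas$template$data,
                                atlas$brain_mask$data),
             mutual_information(moving$data, atlas$template$data,
                                atlas$brain_mask$data))
})

test_that("warping with the identity and with a pure translation behave
           as the composition rule dictates", {
  atlas <- test_atlas()
  bs0 <- bspline_transform(NULL, atlas$template, spacing_vox = 16)
  w0 <- warp(atlas$template, bs0)
  expect_equal(w0$data, atlas$template$data, tolerance = 1e-12)

  # constant displacement: u = +2 voxels along x everywhere
  sp <- atlas$template$spacing[1]
  u <- array(0, c(64, 64, 64, 3)); u[, , , 1] <- 2 * sp
  def <- displacement_field(u, atlas$template)
  arr <- array(0, c(64, 64, 64)); arr[33, 33, 33] <- 1
  v <- as_volume(arr, spacing = atlas$template$spacing,
                 affine = atlas$template$affine)
  wt <- warp(v, def)
  expect_equal(wt$data[31, 33, 33], 1, tolerance = 1e-12)
})

test_that("displacement-field inversion satisfies its composition bound", {
  atlas <- test_atlas()
  # zero field -> zero inverse
  z <- displacement_field(array(0, c(64, 64, 64, 3)), atlas$template)
  zi <- invert_transform_on_grid(z)
  expect_equal(max(abs(zi$u)), 0)

  # constant translation -> negated translation
  sp <- atlas$template$spacing[1]
  u <- array(0, c(64, 64, 64, 3)); u[, , , 2] <- 1.5 * sp
  ci <- invert_transform_on_grid(displacement_field(u, atlas$template))
  expect_lt(max(abs(ci$u[, , , 2] + 1.5 * sp)), 1e-3 * sp)

  # smooth random field of ~2 voxel amplitude: 99th-percentile composition
  # error below 0.1 voxel
  set.seed(9)
  u <- array(0, c(64, 64, 64, 3))
  for (c in 1:3)
    u[, , , c] <- mciprog:::random_smooth_field(c(64, 64, 64), 12, 2.0)
  inv <- invert_transform_on_grid(displacement_field(u, atlas$template))
  ce <- attr(inv, "composition_error")
  expect_lt(unname(stats::quantile(ce, 0.99)) / sp, 0.1)

  # a non-invertible field (folding) is rejected
  bad <- array(0, c(64, 64, 64, 3))
  bad[, , , 1] <- -matrix(rep(seq(0, 63) * sp * 1.5, 64 * 64), 64)
  expect_error(invert_transform_on_grid(
    displacement_field(bad, atlas$template)), "non-invertible")
})
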