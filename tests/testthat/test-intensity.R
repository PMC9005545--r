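cube_vol <- function(n, value = 1) {
  as_volume(array(value, c(n, n, n)), spacing = c(1, 1, 1))
}

test_that("block grid tiles the mask bounding box as specified", {
  g <- build_block_grid(cube_vol(64))
  expect_equal(nrow(g$blocks), 512)
  expect_true(all(g$count == 8^3))
  expect_true(all(g$valid))
  expect_equal(unname(g$s), c(8, 8, 8))

  # 65^3: remainder voxels join the last block along each axis
  g2 <- build_block_grid(cube_vol(65))
  last <- g2$bounds[[1]][8, ]
  expect_equal(unname(last["end"] - last["start"] + 1), 9)
  expect_equal(sum(g2$count), 65^3)

  expect_error(build_block_grid(cube_vol(16, 0)), "empty")
})

test_that("spherical mask: corner blocks invalid, gravity centres in-mask", {
  n <- 64
  g1 <- seq_len(n) - (n + 1) / 2
  sphere <- outer(outer(g1^2, g1^2, `+`), g1^2, `+`) <= (n / 2 - 2)^2
  mask <- as_volume(sphere * 1, spacing = c(1, 1, 1))
  g <- build_block_grid(mask)
  corners <- g$blocks$bx %in% c(1, 8) & g$blocks$by %in% c(1, 8) &
    g$blocks$bz %in% c(1, 8)
  expect_true(all(!g$valid[corners]))
  # gravity centres of valid blocks lie inside their own block extents
  for (k in which(g$valid)) {
    b <- g$blocks[k, ]
    expect_gte(g$gravity[k, 1], g$bounds[[1]][b$bx, "start"] - 1)
    expect_lte(g$gravity[k, 1], g$bounds[[1]][b$bx, "end"] - 1)
  }
})

test_that("block ranges are robust percentiles, invariant to voxel order", {
  mask <- cube_vol(16)
  g <- build_block_grid(mask)
  set.seed(2)
  vals <- array(runif(16^3, 0, 100), c(16, 16, 16))
  v <- as_volume(vals, spacing = c(1, 1, 1))
  r <- block_range(v, g, 1, mask)
  blockv <- mciprog:::block_voxel_values(v, g, 1, mask)
  expect_equal(r, unname(stats::quantile(blockv, c(0.01, 0.99))),
               tolerance = 1e-12)

  # permutation invariance within the block
  vals2 <- vals
  vals2[1:2, 1:2, 1:2] <- vals[2:1, 2:1, 2:1]
  expect_equal(block_range(as_volume(vals2, spacing = c(1, 1, 1)), g, 1, mask),
               r, tolerance = 1e-9)

  # constant block is demoted
  const <- cube_vol(16, 5)
  expect_true(all(is.na(block_range(const, g, 1, mask))))
})

test_that("block transforms solve the range-matching algebra exactly", {
  atlas <- test_atlas()
  tmpl <- atlas$template
  mask <- atlas$brain_mask
  grid <- build_block_grid(mask)

  m_id <- fit_block_transforms(tmpl, tmpl, mask, grid)
  expect_lt(max(abs(m_id$a[m_id$valid] - 1)), 1e-12)
  expect_lt(max(abs(m_id$b[m_id$valid])), 1e-9)

  # warped = 2*atlas + 10  =>  a = 0.5, b = -5
  w <- as_volume(2 * tmpl$data + 10, spacing = tmpl$spacing,
                 affine = tmpl$affine)
  m <- fit_block_transforms(w, tmpl, mask, grid)
  expect_lt(max(abs(m$a[m$valid] - 0.5)), 1e-9)
  expect_lt(max(abs(m$b[m$valid] + 5)), 1e-6)

  # doubling the warped intensities halves every slope
  w2 <- as_volume(2 * w$data, spacing = tmpl$spacing, affine = tmpl$affine)
  m2 <- fit_block_transforms(w2, tmpl, mask, grid)
  expect_equal(m2$a[m2$valid], m$a[m$valid] / 2, tolerance = 1e-9)
})

test_that("kernel parameter maps: partition of unity, bounds, locality", {
  atlas <- test_atlas()
  grid <- build_block_grid(atlas$brain_mask)
  model <- fit_block_transforms(atlas$template, atlas$template,
                                atlas$brain_mask, grid)
  # constant parameters expand to constant maps (partition of unity)
  maps <- build_parameter_maps(model, atlas$template)
  expect_lt(max(abs(maps$a - 1)), 1e-9)
  expect_lt(max(abs(maps$b)), 1e-6)

  # convexity: maps bounded by min/max block parameters
  set.seed(4)
  model$a[model$valid] <- runif(sum(model$valid), 0.5, 2)
  model$b[model$valid] <- runif(sum(model$valid), -10, 10)
  maps2 <- build_parameter_maps(model, atlas$template)
  eps <- 1e-9
  expect_gte(min(maps2$a), min(model$a[model$valid]) - eps)
  expect_lte(max(maps2$a), max(model$a[model$valid]) + eps)
  expect_gte(min(maps2$b), min(model$b[model$valid]) - eps)
  expect_lte(max(maps2$b), max(model$b[model$valid]) + eps)

  # locality: with a single valid block, the map at its gravity centre
  # equals that block's parameter
  model3 <- model
  keep <- which(model3$valid)[100]
  model3$valid[] <- FALSE; model3$valid[keep] <- TRUE
  maps3 <- build_parameter_maps(model3, atlas$template)
  gc <- round(grid$gravity[keep, ]) + 1
  expect_equal(maps3$a[gc[1], gc[2], gc[3]], model3$a[keep],
               tolerance = 1e-6)

  # strided evaluation approximates the exact maps closely inside the mask
  maps_s <- build_parameter_maps(model, atlas$template, stride = 4L)
  msk <- atlas$brain_mask$data > 0
  expect_lt(max(abs(maps_s$a[msk] - maps2$a[msk])),
            0.02 * diff(range(maps2$a[msk])) + 1e-9)
})

test_that("back-projection composes maps with the inverse deformation", {
  atlas <- test_atlas()
  grid <- build_block_grid(atlas$brain_mask)
  model <- fit_block_transforms(atlas$template, atlas$template,
                                atlas$brain_mask, grid)
  set.seed(8)
  model$a[model$valid] <- runif(sum(model$valid), 0.8, 1.2)
  maps <- build_parameter_maps(model, atlas$template)

  # identity deformation leaves the maps unchanged
  bs0 <- bspline_transform(NULL, atlas$template, spacing_vox = 16)
  m0 <- backproject_maps(maps, bs0)
  expect_equal(m0$a, maps$a, tolerance = 1e-9)

  # a constant translation shifts the maps oppositely
  sp <- atlas$template$spacing[1]
  u <- array(0, c(64, 64, 64, 3)); u[, , , 1] <- 2 * sp
  inv <- invert_transform_on_grid(displacement_field(u, atlas$template))
  mt <- backproject_maps(maps, inv)
  expect_equal(mt$a[10:50, 20, 20], maps$a[8:48, 20, 20], tolerance = 1e-6)
})

test_that("voxelwise application follows out = a*I + b", {
  atlas <- test_atlas()
  v <- atlas$template
  d <- dim(v$data)
  mk <- function(a, b) structure(list(a = array(a, d), b = array(b, d),
                                      space = "shape_normalized",
                                      spacing = v$spacing, affine = v$affine),
                                 class = "parameter_maps")
  expect_equal(apply_intensity_normalization(v, mk(1, 0))$data, v$data)
  cst <- as_volume(array(10, d), spacing = v$spacing, affine = v$affine)
  out <- apply_intensity_normalization(cst, mk(2, -5))
  expect_true(all(out$data == 15))
})

test_that("a global affine intensity perturbation is corrected to <1% and a
           smooth bias field is at least halved", {
  atlas <- test_atlas()
  tmpl <- atlas$template
  msk <- atlas$brain_mask$data > 0
  rng <- diff(range(tmpl$data[msk]))

  # alpha * I + beta with identity deformation
  w <- as_volume(1.3 * tmpl$data + 20, spacing = tmpl$spacing,
                 affine = tmpl$affine, space = "shape_normalized")
  out <- normalize_intensity_blocks(w, atlas, stride = 1L)
  expect_lt(masked_rmse(out$volume, tmpl, msk) / rng, 0.01)

  # smooth +-20% multiplicative bias (96 mm correlation length, the typical
  # scale of B1 inhomogeneity; the kernel-smoothed block correction tracks
  # variation above about two block widths)
  set.seed(12)
  f <- mciprog:::random_smooth_field(c(64, 64, 64), 24, 0.1)
  bias <- 1 + 0.2 * f / max(abs(f[msk]))  # in-mask peak exactly +-20%
  wb <- as_volume(bias * tmpl$data, spacing = tmpl$spacing,
                  affine = tmpl$affine, space = "shape_normalized")
  outb <- normalize_intensity_blocks(wb, atlas, stride = 1L)
  expect_lt(masked_rmse(outb$volume, tmpl, msk),
            0.5 * masked_rmse(wb, tmpl, msk))

  # idempotence: renormalizing changes the image by < 2% masked RMSE
  out2 <- normalize_intensity_blocks(outb$volume, atlas, stride = 1L)
  expect_lt(masked_rmse(out2$volume, outb$volume, msk) / rng, 0.02)
})
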