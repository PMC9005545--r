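test_that("skull stripping zeroes exactly the out-of-mask voxels", {
  atlas <- test_atlas()
  out <- skull_strip_fallback(atlas$template, atlas)
  m <- atlas$brain_mask$data > 0
  expect_equal(out$data[m], atlas$template$data[m])
  expect_true(all(out$data[!m] == 0))
  expect_equal(sum(out$data == 0 & atlas$template$data != 0), sum(!m) -
                 sum(atlas$template$data[!m] == 0))
})

test_that("phantom subjects keep >=99% of their brain after stripping", {
  bm <- test_benchmark()
  atlas <- test_atlas()
  s <- bm$cohort$subjects[[1]]
  fit <- fit_similarity_9dof(atlas$landmarks, s$landmarks)
  sn <- resample(s$volume, fit, atlas$template)
  stripped <- skull_strip_fallback(sn, atlas)
  m <- atlas$brain_mask$data > 0
  # brain voxels (atlas mask is the truth brain in atlas space) retained
  expect_gte(mean(stripped$data[m] == sn$data[m]), 0.99)
})

test_that("segment crops are exact sub-arrays of the requested box", {
  atlas <- test_atlas()
  sp <- atlas$segment_specs[[1]]
  crop <- extract_segment(atlas$template, sp)
  expect_equal(dim(crop), rep(sp$size, 3))
  st <- attr(crop, "start")
  expect_identical(unclass(crop)[1:3, 1, 1],
                   atlas$template$data[st[1]:(st[1] + 2), st[2], st[3]])

  # two overlapping boxes agree on their intersection
  sp2 <- segment_spec("hippocampus_L", sp$center + c(6, 0, 0), sp$size)
  crop2 <- extract_segment(atlas$template, sp2)
  shift <- attr(crop2, "start") - st
  n <- sp$size
  expect_equal(unclass(crop)[(1 + shift[1]):n, , ],
               unclass(crop2)[1:(n - shift[1]), , ])

  # out-of-bounds box errors rather than padding
  far <- segment_spec("hippocampus_L", c(0, 0, 0), sp$size)
  expect_error(extract_segment(atlas$template, far), "exceeds")
})

test_that("left-right flip is an involution with the right index map", {
  set.seed(3)
  crop <- array(rnorm(64^3 * 0 + 32768), c(32, 32, 32))
  expect_identical(unclass(flip_lr(flip_lr(crop))), crop)
  spike <- array(0, c(64, 64, 64)); spike[6, 2, 3] <- 1
  flipped <- flip_lr(spike)
  expect_equal(flipped[59, 2, 3], 1)  # index 5 (0-based) -> 58 (0-based)
  expect_equal(mean(flipped), mean(spike))
})

test_that("intensity scaling clips at the fixed ceiling of 400", {
  expect_equal(scale_intensity(200), 0.5)
  expect_equal(scale_intensity(500), 1.0)
  expect_equal(scale_intensity(0), 0.0)
  expect_equal(scale_intensity(-10), 0.0)
})

test_that("segment stacks are deterministic and complete", {
  atlas <- test_atlas()
  s1 <- segment_stack(atlas$template, atlas, "t")
  s2 <- segment_stack(atlas$template, atlas, "t")
  expect_identical(s1$crops, s2$crops)
  expect_setequal(names(s1$crops), c("hippocampus_L", "hippocampus_R",
                                     "ant_temporal_L", "ant_temporal_R"))
  expect_true(all(vapply(s1$crops, max, 1) <= 1))
  expect_true(all(vapply(s1$crops, min, 1) >= 0))
})

test_that("hippocampal blob centroids fall inside the hippocampus crops", {
  bm <- test_benchmark()
  atlas <- test_atlas()
  pp <- attr(atlas, "phantom_params")
  box <- atlas$segment_specs[[1]]
  half_mm <- box$size / 2 * pp$spacing
  inside <- vapply(1:40, function(i) {
    s <- bm$cohort$subjects[[i]]
    # map the true native-space blob centre back through the fitted
    # similarity transform into atlas space
    fit <- fit_similarity_9dof(atlas$landmarks, s$landmarks)
    ctr_atlas <- transform_points(solve(similarity_matrix(fit)),
                                  s$truth$hippo_centers_native[1, ])
    all(abs(ctr_atlas - box$center) < half_mm)
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})
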