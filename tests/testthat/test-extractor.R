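test_that("forward contract: logits, features, reconstruction shapes", {
  cf <- unit_config()
  m <- build_extractor(cf)
  x <- array(runif(16^3 * 2), c(16, 16, 16, 2, 1))
  fw <- mciprog:::extractor_forward(m$params, x, cf, m$arch, train = FALSE)
  expect_equal(dim(fw$logits), c(2, 2))
  expect_equal(nrow(fw$features), cf$feature_dim)
  expect_equal(dim(fw$recon), dim(x))
})

test_that("ablation switches change the wiring and parameter counts", {
  npar <- function(cf) {
    sum(vapply(build_extractor(cf)$params, length, 1L))
  }
  base <- unit_config()
  no_sa <- unit_config(use_self_attention = FALSE)
  no_ae <- unit_config(use_autoencoder = FALSE)
  expect_gt(npar(base), npar(no_sa))
  expect_gt(npar(base), npar(no_ae))
  m <- build_extractor(no_ae)
  x <- array(runif(16^3), c(16, 16, 16, 1, 1))
  fw <- mciprog:::extractor_forward(m$params, x, no_ae, m$arch)
  expect_null(fw$recon)
})

test_that("training reduces the loss and is reproducible under a seed", {
  bm <- test_benchmark()
  crops <- pool_segment_group(bm$stacks[c(1:20, 101:120)], "hippocampus")
  labels <- bm$records$label[c(1:20, 101:120)][crops$subject_idx]
  cfg <- tiny_extractor_config(epochs = 5, seed = 7)
  m <- train_extractor(crops$crops, labels, cfg)
  lg <- m$log$epoch_loss
  expect_lt(lg[length(lg)], lg[1])

  cfg2 <- tiny_extractor_config(epochs = 2, seed = 9)
  mixed <- c(1:8, 21:28)  # both classes among the pooled crops
  small <- crops$crops[mixed]
  lab_s <- labels[mixed]
  m1 <- train_extractor(small, lab_s, cfg2)
  m2 <- train_extractor(small, lab_s, cfg2)
  expect_equal(m1$log$epoch_loss, m2$log$epoch_loss, tolerance = 1e-12)

  expect_error(train_extractor(small, rep("sMCI", 16), cfg2), "single class")
  expect_error(train_extractor(list(), character(0), cfg2), "empty|dim")
})

test_that("disabling the auto-encoder trains with alpha forced to zero", {
  bm <- test_benchmark()
  crops <- pool_segment_group(bm$stacks[c(1:6, 101:106)], "hippocampus")
  labels <- bm$records$label[c(1:6, 101:106)][crops$subject_idx]
  cfg <- tiny_extractor_config(epochs = 1, seed = 3, use_autoencoder = FALSE)
  m <- train_extractor(crops$crops, labels, cfg)
  expect_equal(m$config$alpha, 0)
  expect_true(all(m$log$epoch_ae == 0))
})

test_that("feature extraction is deterministic and mirror-consistent", {
  atlas <- test_atlas()
  cfg <- tiny_extractor_config(seed = 5)
  m <- build_extractor(cfg)
  stack <- segment_stack(atlas$template, atlas)
  f1 <- extract_features(m, stack$crops$hippocampus_R)
  f2 <- extract_features(m, stack$crops$hippocampus_R)
  expect_identical(f1, f2)
  expect_length(f1, cfg$feature_dim)

  # the atlas is left-right symmetric: flipped-left and right crops give
  # nearly identical features
  fl <- extract_features(m, flip_lr(stack$crops$hippocampus_L))
  cosine <- sum(fl * f1) / sqrt(sum(fl^2) * sum(f1^2))
  expect_gt(cosine, 0.99)
})

test_that("a tiny extractor can overfit a handful of subjects", {
  bm <- test_benchmark()
  idx <- c(1:4, 101:104)
  crops <- pool_segment_group(bm$stacks[idx], "hippocampus")
  labels <- bm$records$label[idx][crops$subject_idx]
  cfg <- tiny_extractor_config(epochs = 200, seed = 1, dropout = 0,
                               use_autoencoder = FALSE, lr = 2e-3)
  no_aug <- augmentation_spec(rotation_deg = 0, scale_range = c(1, 1),
                              translation_vox = 0, gray_slope = c(1, 1),
                              gray_shift = 0, out_size = cfg$input_size)
  m <- train_extractor(crops$crops, labels, cfg, aug = no_aug,
                       stop_class_below = 0.05)
  expect_lt(min(m$log$epoch_class), 0.05)
  expect_lte(length(m$log$epoch_class), 200)
})

test_that("smoothgrad saliency matches its definition", {
  cf <- unit_config()
  m <- build_extractor(cf)
  set.seed(4)
  crop <- array(runif(16^3), c(16, 16, 16))
  sal <- smoothgrad(m, crop, n_samples = 1, noise_sigma = 0, seed = 1)
  expect_equal(dim(sal), dim(crop))
  expect_true(all(sal >= 0))

  # sigma = 0, n = 1 equals |d logit_pMCI / d input|: spot-check three
  # voxels by finite differences of the pMCI logit
  logit_p <- function(cr) {
    x <- array(cr, c(dim(cr), 1, 1))
    fw <- mciprog:::extractor_forward(m$params, x, cf, m$arch, train = FALSE)
    fw$logits[2, 1]
  }
  set.seed(8)
  for (v in sample(length(crop), 3)) {
    h <- 1e-5
    c2 <- crop; c2[v] <- c2[v] + h
    c3 <- crop; c3[v] <- c3[v] - h
    expect_equal(sal[v], abs((logit_p(c2) - logit_p(c3)) / (2 * h)),
                 tolerance = 1e-3)
  }

  # a model with an all-zero first layer has identically zero saliency
  m0 <- m
  m0$params[["stem.conv.W"]][] <- 0
  sal0 <- smoothgrad(m0, crop, n_samples = 2, noise_sigma = 0.05, seed = 2)
  expect_true(all(sal0 == 0))

  expect_error(smoothgrad(m, crop, n_samples = 0), "n_samples")
})

test_that("end-to-end model: logits, non-image sensitivity, image-only wiring", {
  bm <- test_benchmark()
  cfg <- tiny_extractor_config(seed = 2)
  m <- build_e2e(cfg, use_nonimage = TRUE)
  stacks <- bm$stacks[c(1, 101)]
  recs <- bm$records[c(1, 101), ]
  fw <- e2e_forward(m, stacks, recs)
  expect_equal(dim(fw$logits), c(2, 2))

  # gradient flows through the fusion: different non-image records change
  # the logits for the same images
  recs2 <- recs
  recs2$mmse <- recs2$mmse - 6
  recs2$adas <- recs2$adas + 10
  fw2 <- e2e_forward(m, stacks, recs2)
  expect_gt(max(abs(fw2$logits - fw$logits)), 0)

  # image-only variant builds and runs without records
  mi <- build_e2e(cfg, use_nonimage = FALSE)
  fwi <- e2e_forward(mi, stacks)
  expect_equal(dim(fwi$logits), c(2, 2))
  expect_error(e2e_forward(m, stacks, NULL), "records")
})
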