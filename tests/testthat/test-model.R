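fit_small_hybrid <- function() {
  if (!is.null(.fixtures$small_hybrid)) return(.fixtures$small_hybrid)
  bm <- test_benchmark()
  idx <- c(1:12, 101:112)
  cfg <- tiny_extractor_config(epochs = 2, seed = 3)
  m <- progression_model(bm$stacks[idx], bm$records[idx, ], "hybrid",
                         config = cfg, seed = 3)
  .fixtures$small_hybrid <- list(model = m, idx = idx)
  .fixtures$small_hybrid
}

test_that("the hybrid progression model exposes the classic S3 surface", {
  bm <- test_benchmark()
  sh <- fit_small_hybrid()
  m <- sh$model
  expect_s3_class(m, "progression_model")
  expect_output(print(m), "hybrid")
  expect_output(summary(m), "explained variance")

  w <- coef(m)
  expect_length(w, 10)
  expect_equal(names(w), FUSED_FEATURE_ORDER)

  te <- c(21:30, 121:130)
  nd <- list(stacks = bm$stacks[te], records = bm$records[te, ])
  pr <- predict(m, nd, type = "prob")
  expect_length(pr, 20)
  expect_true(all(pr >= 0 & pr <= 1))
  cl <- predict(m, nd, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), c("sMCI", "pMCI"))
  fz <- predict(m, nd, type = "fused")
  expect_equal(dim(fz), c(20, 10))
  expect_true(all(fz >= 0 & fz <= 1))

  pdf(NULL)
  on.exit(dev.off())
  roc <- plot(m)
  expect_s3_class(roc, "metric_report")
})

test_that("prediction never touches the fitted normalization tables", {
  bm <- test_benchmark()
  sh <- fit_small_hybrid()
  m <- sh$model
  before <- serialize(list(m$qtabs, m$pcas), NULL)
  te <- c(31:40, 131:140)
  invisible(predict(m, list(stacks = bm$stacks[te],
                            records = bm$records[te, ])))
  after <- serialize(list(m$qtabs, m$pcas), NULL)
  expect_identical(before, after)
})

test_that("non-image variant works without stacks and ensembles average", {
  bm <- test_benchmark()
  idx <- c(1:20, 101:120)
  m0a <- progression_model(NULL, bm$records[idx, ], "nonimage", seed = 1)
  m0b <- progression_model(NULL, bm$records[idx, ], "nonimage", seed = 2)
  te <- c(41:50, 141:150)
  nd <- list(records = bm$records[te, ])
  pa <- predict(m0a, nd)
  pb <- predict(m0b, nd)
  en <- predict_ensemble(list(m0a, m0b), nd)
  expect_equal(en$score, (pa + pb) / 2, tolerance = 1e-12)

  met <- cross_cohort_evaluate(list(m0a, m0b), nd, bm$records$label[te])
  expect_true(is.finite(met$auc))
})

test_that("a cohort shift in the bias field degrades the AUC only mildly", {
  bm <- test_benchmark()
  atlas <- test_atlas()
  idx <- c(1:30, 101:130)
  cfg <- tiny_extractor_config(epochs = 3, seed = 5)
  m <- progression_model(bm$stacks[idx], bm$records[idx, ], "hybrid",
                         config = cfg,
                         cnn_train_idx = c(1:15, 31:45), seed = 5)
  te <- c(51:70, 151:170)
  in_met <- compute_metrics(
    predict(m, list(stacks = bm$stacks[te], records = bm$records[te, ])),
    bm$records$label[te])

  # external phantom cohort with doubled intensity bias amplitude
  ec <- default_effect_config()
  ec$bias_slope_amp <- ec$bias_slope_amp * 2
  ec$bias_offset_amp <- ec$bias_offset_amp * 2
  ext <- make_cohort(atlas, 15, 15, effect_config = ec, seed = 77)
  pre <- preprocess_cohort(ext, atlas, level = "landmark")
  ext_met <- compute_metrics(
    predict(m, list(stacks = pre$stacks, records = pre$records)),
    pre$records$label)
  expect_true(is.finite(ext_met$auc))
  expect_lt(in_met$auc - ext_met$auc, 0.15)
})
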