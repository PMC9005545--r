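test_that("APOE risk encoding follows the configured genotype map", {
  expect_equal(encode_apoe("e3/e3"), 1.0)
  expect_equal(encode_apoe("e4/e4"), 11.6)
  expect_equal(encode_apoe("e2/e4"), 3.2)
  expect_equal(encode_apoe("e4/e2"), 3.2)   # order-symmetric
  expect_equal(encode_apoe("e2/e3"), 0.6)
  expect_error(encode_apoe("e3/e4"), "e3/e4")
  expect_equal(encode_apoe("e3/e4", apoe_risk_map(c("e3/e4" = 3.2))), 3.2)
  expect_error(apoe_risk_map(c("x/x" = -1)), "positive")
})

test_that("segment PCA recovers a 1-D structure and is reproducible", {
  set.seed(1)
  t_true <- rnorm(40)
  dirn <- c(2, -1, 0.5)
  x <- outer(t_true, dirn) + matrix(rnorm(120, sd = 1e-9), 40)
  p <- fit_segment_pca(x)
  proj <- project_segment_pca(p, x)
  # projections recover position along the line (up to sign, which the
  # largest-loading convention fixes to positive on the dominant axis)
  expect_gt(abs(cor(proj[, 1], t_true)), 1 - 1e-9)
  expect_gt(p$rotation[which.max(abs(p$rotation[, 1])), 1], 0)
  expect_gt(p$explained_variance[1], 1 - 1e-12)

  # training mean projects to zero
  expect_lt(abs(mean(proj[, 1])), 1e-9)
  expect_lt(max(abs(project_segment_pca(p, colMeans(x)))), 1e-9)

  # permutation invariance of the fit
  o <- sample(40)
  p2 <- fit_segment_pca(x[o, ])
  expect_equal(p2$rotation, p$rotation, tolerance = 1e-9)

  expect_error(fit_segment_pca(matrix(1, 5, 3)), "zero-variance")
  expect_error(fit_segment_pca(x[1, , drop = FALSE]), "2 training samples")
})

test_that("quantile normalization maps to interpolated training quantiles", {
  tabs <- quantile_normalize_fit(matrix(c(1, 2, 3, 4, 5), ncol = 1))
  expect_equal(as.numeric(quantile_normalize_apply(3, tabs)), 0.5)
  expect_equal(as.numeric(quantile_normalize_apply(1, tabs)), 0)
  expect_equal(as.numeric(quantile_normalize_apply(99, tabs)), 1)   # clipped
  expect_equal(as.numeric(quantile_normalize_apply(1.5, tabs)), 0.125)

  # monotone per feature
  set.seed(2)
  x <- matrix(rnorm(200), ncol = 2)
  tb <- quantile_normalize_fit(x)
  xs <- sort(rnorm(50))
  ys <- quantile_normalize_apply(cbind(xs, xs), tb)
  expect_true(all(diff(ys[, 1]) >= 0))
  expect_true(all(diff(ys[, 2]) >= 0))

  # the normalized training sample is uniform on its ranks
  z <- quantile_normalize_apply(x, tb)
  ks <- suppressWarnings(stats::ks.test(z[, 1], "punif")$statistic)
  expect_lt(unname(ks), 2 / sqrt(nrow(x)))

  expect_error(quantile_normalize_fit(matrix(1, 10, 1)), "constant")
})

test_that("the fused vector follows the fixed 10-feature contract", {
  proj <- list(hippocampus_L = 0.3, hippocampus_R = -0.2,
               ant_temporal_L = 0.1, ant_temporal_R = 0.05)
  rec <- data.frame(mmse = 27, faq = 3, cdr_sb = 1.5, adas = 11, age = 72,
                    apoe = "e3/e3")
  fv <- assemble_fused(proj, rec)
  expect_length(fv, 10)
  expect_equal(names(fv), FUSED_FEATURE_ORDER)
  expect_equal(unname(fv["apoe_risk"]), 1.0)
  fv2 <- assemble_fused(proj, rec)
  expect_identical(fv, fv2)

  expect_error(assemble_fused(proj[-2], rec), "hippocampus_R")
  expect_error(assemble_fused(proj, within(rec, rm(adas))), "adas")
})

test_that("the SVM separates, switches kernels, and is deterministic", {
  set.seed(3)
  n <- 40
  x <- rbind(matrix(rnorm(n, 0), ncol = 2), matrix(rnorm(n, 3), ncol = 2))
  y <- rep(c("sMCI", "pMCI"), each = n / 2)
  m <- fit_svm(x, y, "linear", seed = 1)
  pr <- predict_svm_prob(m, x)
  expect_equal(mean((pr >= 0.5) == (y == "pMCI")), 1.0)

  # XOR: linear fails, RBF succeeds
  xx <- cbind(rep(c(0, 0, 1, 1), 20) + rnorm(80, sd = 0.05),
              rep(c(0, 1, 0, 1), 20) + rnorm(80, sd = 0.05))
  yy <- ifelse(xor(round(xx[, 1]) == 1, round(xx[, 2]) == 1), "pMCI", "sMCI")
  acc <- function(model) mean((predict_svm_prob(model, xx) >= 0.5) ==
                                (yy == "pMCI"))
  expect_lt(acc(fit_svm(xx, yy, "linear", seed = 1)), 0.7)
  expect_gt(acc(fit_svm(xx, yy, "rbf", seed = 1)), 0.9)

  m2 <- fit_svm(x, y, "linear", seed = 1)
  expect_equal(predict_svm_prob(m2, x), pr, tolerance = 1e-12)
  expect_error(fit_svm(x, rep("sMCI", 2 * n / 2), "linear"), "single class")
})

test_that("ensemble prediction averages probabilities with a >= 0.5 rule", {
  set.seed(4)
  x <- rbind(matrix(rnorm(30, 0), ncol = 3), matrix(rnorm(30, 2), ncol = 3))
  y <- rep(c("sMCI", "pMCI"), each = 10)
  m1 <- fit_svm(x, y, seed = 1)
  m2 <- fit_svm(x, y, seed = 2)
  xn <- matrix(rnorm(6), ncol = 3)
  pr <- predict_ensemble(list(m1, m2), xn)
  expect_equal(pr$score,
               (predict_svm_prob(m1, xn) + predict_svm_prob(m2, xn)) / 2)
  # permutation of members leaves the score unchanged
  pr2 <- predict_ensemble(list(m2, m1), xn)
  expect_equal(pr2$score, pr$score)
  # boundary scores go to pMCI
  expect_equal(levels(pr$class), c("sMCI", "pMCI"))
  expect_error(predict_ensemble(list(), xn), "at least one")
})
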