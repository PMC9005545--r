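test_that("fold plans stratify exactly and partition the test folds", {
  lab <- rep(c("sMCI", "pMCI"), each = 50)
  plan <- make_fold_plan(lab, 10, seed = 1)
  counts <- table(plan$subset, lab)
  expect_true(all(counts == 5))

  # 43/57: per-subset class counts within 1 of proportionality
  lab2 <- c(rep("sMCI", 43), rep("pMCI", 57))
  plan2 <- make_fold_plan(lab2, 10, seed = 2)
  c2 <- table(plan2$subset, lab2)
  expect_true(all(abs(c2[, "sMCI"] - 4.3) <= 1))
  expect_true(all(abs(c2[, "pMCI"] - 5.7) <= 1))

  # every sample tested exactly once, also when n is not divisible by 10
  for (n in c(100, 47)) {
    lab3 <- rep(c("sMCI", "pMCI"), length.out = n)
    p3 <- make_fold_plan(lab3, 10, seed = 3)
    tested <- unlist(lapply(p3$repeats, `[[`, "test"))
    expect_equal(sort(tested), seq_len(n))
    for (r in p3$repeats) {
      expect_length(intersect(r$test, r$val), 0)
      expect_length(intersect(r$test, r$train), 0)
      expect_equal(sort(c(r$test, r$val, r$train)), seq_len(n))
    }
  }
  expect_error(make_fold_plan(rep(c("sMCI", "pMCI"), c(5, 95)), 10, 1),
               "at least")
})

test_that("metrics at a threshold and the rank AUC behave as defined", {
  # perfect separation
  m <- compute_metrics(c(0.9, 0.8, 0.1, 0.2),
                       c("pMCI", "pMCI", "sMCI", "sMCI"))
  expect_equal(m$accuracy, 1)
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)

  # 4-sample case against the brute-force pairwise oracle
  sc <- c(0.7, 0.4, 0.6, 0.3)
  lb <- c("pMCI", "pMCI", "sMCI", "sMCI")
  expect_equal(compute_metrics(sc, lb)$auc, 0.75)
  expect_equal(compute_metrics(sc, lb)$auc, auc_bruteforce(sc, lb))

  # ties get half credit; threshold 0.5 assigns boundary scores to pMCI
  mt <- compute_metrics(c(0.5, 0.5), c("pMCI", "sMCI"))
  expect_equal(mt$auc, 0.5)
  expect_equal(mt$sensitivity, 1)
  expect_equal(mt$specificity, 0)

  expect_error(compute_metrics(c(0.1, 0.9), c("pMCI", "pMCI")), "undefined")
})

test_that("rank AUC equals trapezoidal ROC integration to 1e-12", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    lb <- sample(c("sMCI", "pMCI"), n, replace = TRUE,
                 prob = c(0.5, 0.5))
    if (length(unique(lb)) < 2) next
    sc <- round(runif(n), 2)  # rounding forces ties
    m <- compute_metrics(sc, lb)
    expect_equal(m$auc, mciprog:::roc_trapezoid_auc(m$roc),
                 tolerance = 1e-12)
    expect_equal(m$auc, auc_bruteforce(sc, lb), tolerance = 1e-12)
    if (requireNamespace("pROC", quietly = TRUE)) {
      ext <- suppressMessages(pROC::auc(pROC::roc(
        response = lb, predictor = sc, levels = c("sMCI", "pMCI"),
        direction = "<", quiet = TRUE)))
      expect_equal(m$auc, as.numeric(ext), tolerance = 1e-12)
    }
    # invariance under strictly monotone transforms
    m2 <- compute_metrics(qlogis(pmin(pmax(sc, 1e-3), 1 - 1e-3)), lb,
                          threshold = -10)
    expect_equal(m2$auc, m$auc, tolerance = 1e-12)
    # ROC monotone from (0,0) to (1,1)
    expect_true(all(diff(m$roc$fpr) >= 0))
    expect_true(all(diff(m$roc$tpr) >= 0))
    expect_equal(unlist(m$roc[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(m$roc[nrow(m$roc), ]), c(fpr = 1, tpr = 1))
  }
})

test_that("repeated CV: oracle, constant and null pipelines score as expected", {
  set.seed(6)
  n <- 60
  lab <- rep(c("sMCI", "pMCI"), each = n / 2)
  plan <- make_fold_plan(lab, 10, seed = 4)

  oracle <- function(train, val) {
    f <- function(idx) ifelse(lab[idx] == "pMCI", 0.9, 0.1)
    f
  }
  r1 <- run_repeated_cv(lab, oracle, plan)
  expect_true(all(vapply(r1$per_repeat, `[[`, 1, "accuracy") == 1))
  expect_equal(unname(r1$mean["accuracy"]), 1)

  constant <- function(train, val) function(idx) rep(0.5, length(idx))
  r2 <- run_repeated_cv(lab, constant, plan)
  expect_equal(r2$pooled$auc, 0.5)

  # label-permuted features: mean accuracy within 3 sigma of chance
  set.seed(7)
  x <- matrix(rnorm(n * 4), n)
  accs <- vapply(1:3, function(s) {
    set.seed(100 + s)
    yperm <- sample(lab)
    pl <- make_fold_plan(yperm, 10, seed = s)
    factory <- function(train, val) {
      m <- fit_svm(x[train, ], yperm[train], seed = s)
      function(idx) predict_svm_prob(m, x[idx, , drop = FALSE])
    }
    run_repeated_cv(yperm, factory, pl)$pooled$accuracy
  }, 1)
  se <- sqrt(0.25 / n)
  expect_lt(abs(mean(accs) - 0.5), 3 * se)
})

test_that("cross-cohort ensemble evaluation matches its definition", {
  set.seed(8)
  x <- rbind(matrix(rnorm(40, 0), ncol = 2), matrix(rnorm(40, 2), ncol = 2))
  y <- rep(c("sMCI", "pMCI"), each = 20)
  m1 <- fit_svm(x, y, seed = 1)
  xe <- rbind(matrix(rnorm(20, 0), ncol = 2), matrix(rnorm(20, 2), ncol = 2))
  ye <- rep(c("sMCI", "pMCI"), each = 10)
  # ensemble of one equals predict-then-metrics
  r1 <- cross_cohort_evaluate(list(m1), xe, ye)
  direct <- compute_metrics(predict_svm_prob(m1, xe), ye)
  expect_equal(r1$auc, direct$auc)
  expect_equal(r1$accuracy, direct$accuracy)
  expect_true(is.finite(r1$auc))
})
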