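#' Stratified fold plan for repeated cross-validation-and-test
#'
#' Randomly splits the dataset, stratified by class label, into `n_folds`
#' subsets (per-subset class counts within one of exact proportionality).
#' Repeat number r uses subset r-1 (mod n_folds) for test and subset
#' r (mod n_folds) for validation, with the remaining `n_folds - 2` subsets
#' for training, so that across the `n_folds` repeats every sample appears in
#' a test subset exactly once.
#'
#' @param labels sMCI/pMCI label vector.
#' @param n_folds number of subsets (default 10).
#' @param seed RNG seed for the stratified shuffle.
#' @return a `fold_plan` with `subset` (per-sample subset index 1..n_folds)
#'   and `repeats` (list of train/val/test index vectors).
#' @export
make_fold_plan <- function(labels, n_folds = 10L, seed = 1L) {
  lab <- as_label_index(labels)
  n <- length(lab)
  counts <- table(lab)
  if (any(counts < n_folds))
    stop("every class needs at least n_folds = ", n_folds, " members")
  subset <- integer(n)
  withr_seed(seed, {
    for (cl in unique(lab)) {
      idx <- which(lab == cl)
      idx <- idx[sample.int(length(idx))]
      subset[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  repeats <- lapply(seq_len(n_folds), function(r) {
    test_s <- (r - 1L) %% n_folds + 1L
    val_s <- r %% n_folds + 1L
    list(test = which(subset == test_s), val = which(subset == val_s),
         train = which(!subset %in% c(test_s, val_s)))
  })
  structure(list(subset = subset, n_folds = as.integer(n_folds),
                 labels = lab, seed = as.integer(seed), repeats = repeats),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan> ", length(x$subset), " samples, ", x$n_folds,
      " stratified subsets (seed ", x$seed, ")\n", sep = "")
  print(table(subset = x$subset, class = x$labels))
  invisible(x)
}

#' Classification metrics at a fixed threshold
#'
#' Accuracy, sensitivity (pMCI recall), specificity and AUC for scores in
#' `[0, 1]` where larger means more pMCI-like.  AUC is the Mann-Whitney rank
#' statistic (ties counted 1/2), which equals the trapezoidal area under the
#' ROC curve; the ROC points are returned for plotting.
#'
#' @param scores numeric scores.
#' @param labels sMCI/pMCI labels.
#' @param threshold decision threshold (default 0.5; scores at the threshold
#'   classify as pMCI).
#' @return a `metric_report` list: `accuracy`, `sensitivity`, `specificity`,
#'   `auc`, `roc` (data.frame fpr/tpr), `n_pos`, `n_neg`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  lab <- as_label_index(labels)
  pos <- lab == 2L
  if (!any(pos) || all(pos))
    stop("AUC undefined: both classes must be present")
  pred_pos <- scores >= threshold
  acc <- mean(pred_pos == pos)
  sens <- mean(pred_pos[pos])
  spec <- mean(!pred_pos[!pos])
  r <- rank(scores)  # midranks: ties get 1/2 credit
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  # ROC points over unique thresholds (descending)
  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[pos] >= t), 1)
  fpr <- vapply(ths, function(t) mean(scores[!pos] >= t), 1)
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  structure(list(accuracy = acc, sensitivity = sens, specificity = spec,
                 auc = auc, roc = roc, n_pos = n1, n_neg = n0,
                 threshold = threshold),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf(
    "<metric_report> acc %.3f | AUC %.3f | sens %.3f | spec %.3f  (n+ %d, n- %d)\n",
    x$accuracy, x$auc, x$sensitivity, x$specificity, x$n_pos, x$n_neg))
  invisible(x)
}

# trapezoidal area under an ROC data.frame (fpr, tpr)
roc_trapezoid_auc <- function(roc) {
  o <- order(roc$fpr, roc$tpr)
  fpr <- roc$fpr[o]; tpr <- roc$tpr[o]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Run the repeated stratified cross-validation-and-test protocol
#'
#' For each repeat of the fold plan, calls
#' `pipeline_factory(train_idx, val_idx)`, which must fit a model using only
#' the training subset (the validation subset may be used for model
#' selection) and return a function mapping sample indices to pMCI scores.
#' Test labels are never passed to the factory.  Collects test predictions
#' (each sample is tested exactly once across repeats), per-repeat metrics
#' and their mean.
#'
#' @param labels sMCI/pMCI labels of all samples.
#' @param pipeline_factory `function(train_idx, val_idx) -> function(idx)`.
#' @param fold_plan a [make_fold_plan()] result.
#' @param threshold decision threshold.
#' @return list with `per_repeat` (metric reports), `mean` (named vector of
#'   mean accuracy/auc/sensitivity/specificity), `pooled` (metric report on
#'   the pooled test predictions), `scores` (per-sample pooled test scores),
#'   and `val_accuracy` (per-repeat validation accuracy, if the factory
#'   reports one via attribute `val_accuracy`).
#' @export
run_repeated_cv <- function(labels, pipeline_factory, fold_plan,
                            threshold = 0.5) {
  lab <- as_label_index(labels)
  n <- length(lab)
  scores <- rep(NA_real_, n)
  per_repeat <- vector("list", fold_plan$n_folds)
  val_acc <- rep(NA_real_, fold_plan$n_folds)
  for (r in seq_len(fold_plan$n_folds)) {
    sp <- fold_plan$repeats[[r]]
    predictor <- pipeline_factory(sp$train, sp$val)
    s <- predictor(sp$test)
    if (any(!is.na(scores[sp$test])))
      stop("internal error: sample tested twice")
    scores[sp$test] <- s
    per_repeat[[r]] <- compute_metrics(s, lab[sp$test], threshold)
    va <- attr(predictor, "val_accuracy")
    if (!is.null(va)) val_acc[r] <- va
  }
  if (any(is.na(scores))) stop("internal error: some samples never tested")
  mean_metrics <- colMeans(do.call(rbind, lapply(per_repeat, function(m)
    c(accuracy = m$accuracy, auc = m$auc, sensitivity = m$sensitivity,
      specificity = m$specificity))))
  list(per_repeat = per_repeat, mean = mean_metrics,
       pooled = compute_metrics(scores, lab, threshold), scores = scores,
       val_accuracy = val_acc)
}

#' Evaluate fold models on an external cohort
#'
#' Cross-cohort evaluation: the fold models from the repeated
#' cross-validation are ensembled by averaging their output probabilities
#' ([predict_ensemble()]), each subject of the (never seen) external cohort
#' is classified at the 0.5 threshold, and the full metric report is
#' returned.
#'
#' @param models list of fold models (see [predict_ensemble()]).
#' @param newdata external-cohort input accepted by the models.
#' @param labels external-cohort labels.
#' @param threshold decision threshold.
#' @return a `metric_report` with attribute `scores`.
#' @export
cross_cohort_evaluate <- function(models, newdata, labels, threshold = 0.5) {
  pr <- predict_ensemble(models, newdata, threshold)
  out <- compute_metrics(pr$score, labels, threshold)
  attr(out, "scores") <- pr$score
  out
}
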