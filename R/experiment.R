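#' Scaled-down phantom benchmark of the model variants
#'
#' Runs the desk-scale comparison experiment on a preprocessed phantom
#' cohort: for each seed, a stratified 10-subset fold plan supplies the
#' validation fold, a class-stratified subsample of size `n_train` drawn
#' from the remaining subsets fits the hybrid, non-image-only and end-to-end
#' variants (the end-to-end variant on a subset of the same `n_train`
#' subjects), and every subject not used for training or validation is the
#' held-out test set.  The validation fold serves for the end-to-end model's
#' epoch selection and for validation-accuracy reporting, so the signed
#' validation-minus-test accuracy gap of the hybrid and end-to-end variants
#' can be compared (the generalizability contrast).
#'
#' @param stacks,records preprocessed cohort ([preprocess_cohort()]).
#' @param seeds integer vector of experiment seeds.
#' @param n_train subjects used to fit the hybrid/non-image variants.
#' @param n_cnn subjects (within `n_train`) used for CNN extractor training;
#'   a smaller set trained for more epochs learns the segment features at
#'   desk scale, while PCA/quantile/SVM still use all `n_train` rows.
#' @param n_train_e2e subjects used to fit the end-to-end variant (its
#'   training cost per subject is about four crop passes).
#' @param config [extractor_config()] for the CNN stages.
#' @param cnn_epochs,e2e_epochs training epochs of the CNN stages.
#' @param variants subset of `c("hybrid", "nonimage", "e2e")` to run.
#' @return data.frame with one row per seed: test AUC and accuracy per
#'   variant, validation accuracies, and signed accuracy gaps.
#' @export
run_phantom_experiment <- function(stacks, records, seeds = 1:10,
                                   n_train = 64L, n_cnn = 32L,
                                   n_train_e2e = 32L,
                                   config = tiny_extractor_config(),
                                   cnn_epochs = 4L, e2e_epochs = 4L,
                                   variants = c("hybrid", "nonimage",
                                                "e2e")) {
  labels <- records$label
  out <- list()
  for (s in seeds) {
    plan <- make_fold_plan(labels, 10L, seed = s)
    sp <- plan$repeats[[1]]
    sub <- stratified_subsample(sp$train, labels, n_train, seed = s * 31L)
    sub_e <- sub[stratified_subsample(seq_along(sub), labels[sub],
                                      n_train_e2e, seed = s * 57L)]
    test_pool <- setdiff(seq_along(labels), c(sub, sp$val))
    test_idx <- stratified_subsample(test_pool, labels, 80L, seed = s * 71L)
    valdata <- list(stacks = stacks[sp$val],
                    records = records[sp$val, , drop = FALSE])
    testdata <- list(stacks = stacks[test_idx],
                     records = records[test_idx, , drop = FALSE])
    row <- list(seed = s)
    if ("hybrid" %in% variants) {
      cfg <- config; cfg$seed <- s; cfg$epochs <- cnn_epochs
      cnn_idx <- stratified_subsample(seq_along(sub), labels[sub], n_cnn,
                                      seed = s * 13L)
      m5 <- progression_model(stacks[sub], records[sub, , drop = FALSE],
                              "hybrid", config = cfg,
                              cnn_train_idx = cnn_idx, val = valdata,
                              seed = s)
      p5 <- predict(m5, testdata)
      met5 <- compute_metrics(p5, labels[test_idx])
      row$auc_hybrid <- met5$auc
      row$acc_hybrid <- met5$accuracy
      row$val_acc_hybrid <- m5$val_accuracy
      row$gap_hybrid <- m5$val_accuracy - met5$accuracy
    }
    if ("nonimage" %in% variants) {
      m0 <- progression_model(NULL, records[sub, , drop = FALSE], "nonimage",
                              val = valdata, seed = s)
      p0 <- predict(m0, testdata)
      met0 <- compute_metrics(p0, labels[test_idx])
      row$auc_nonimage <- met0$auc
      row$acc_nonimage <- met0$accuracy
      row$val_acc_nonimage <- m0$val_accuracy
    }
    if ("e2e" %in% variants) {
      cfe <- config; cfe$seed <- s; cfe$epochs <- e2e_epochs
      # the fusion dilutes the classification gradient; the comparator gets
      # a doubled rate so it trains to a non-trivial classifier at this scale
      cfe$lr <- config$lr * 2
      me <- progression_model(stacks[sub_e], records[sub_e, , drop = FALSE],
                              "e2e", config = cfe, val = valdata, seed = s)
      pe <- predict(me, testdata)
      mete <- compute_metrics(pe, labels[test_idx])
      row$auc_e2e <- mete$auc
      row$acc_e2e <- mete$accuracy
      row$val_acc_e2e <- me$val_accuracy
      row$gap_e2e <- me$val_accuracy - mete$accuracy
    }
    out[[length(out) + 1L]] <- as.data.frame(row)
  }
  do.call(rbind, out)
}

stratified_subsample <- function(idx, labels, n, seed) {
  if (length(idx) <= n) return(idx)
  lab <- as_label_index(labels)[idx]
  withr_seed(seed, {
    per_class <- split(idx, lab)
    take <- round(n * vapply(per_class, length, 1L) / length(idx))
    sort(unlist(mapply(function(ix, k) ix[sample.int(length(ix), min(k, length(ix)))],
                       per_class, take, SIMPLIFY = FALSE), use.names = FALSE))
  })
}
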