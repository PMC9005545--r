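#' Fit an MCI-to-AD progression model
#'
#' The package's central fitting function.  Variants:
#' \describe{
#'   \item{`hybrid`}{the full pipeline: two CNN feature extractors (trained
#'     on the pooled hippocampus and anterior-temporal crops, left crops
#'     mirrored), per-segment PCA to `n_components` dimension(s),
#'     fused with the four cognitive scores, age and APOE risk, quantile
#'     normalization fitted on training data, and a linear (or RBF) SVM with
#'     probability output.}
#'   \item{`nonimage`}{SVM on the six non-image features only.}
#'   \item{`image_only`}{SVM on the four per-segment image projections only.}
#'   \item{`e2e`}{the end-to-end comparator ([train_e2e()]): CNN backbones
#'     with bilinear non-image fusion, classified by the network head.}
#' }
#'
#' @param stacks list of [segment_stack()]s (training subjects).
#' @param records matching subject data.frame (needs `mmse, faq, cdr_sb,
#'   adas, age, apoe, label`).
#' @param variant model variant, see above.
#' @param config an [extractor_config()] for the CNN stages.
#' @param svm_kernel `"linear"` (default) or `"rbf"`.
#' @param cost SVM regularization constant.
#' @param n_components PCA components per segment (1 gives the 10-feature
#'   contract).
#' @param risk_map APOE risk encoding.
#' @param cnn_train_idx optional subject indices used for CNN training (a
#'   subsample keeps desk-scale runs fast; PCA/SVM still use all rows).
#' @param val optional list(stacks, records) used as validation set (epoch
#'   selection for `e2e`; validation accuracy reporting otherwise).
#' @param seed seed for SVM probability calibration.
#' @return a fitted `progression_model`.
#' @export
progression_model <- function(stacks, records,
                              variant = c("hybrid", "nonimage", "image_only",
                                          "e2e"),
                              config = tiny_extractor_config(),
                              svm_kernel = c("linear", "rbf"), cost = 1,
                              n_components = 1L,
                              risk_map = apoe_risk_map(),
                              cnn_train_idx = NULL, val = NULL, seed = 1L) {
  variant <- match.arg(variant)
  svm_kernel <- match.arg(svm_kernel)
  labels <- records$label
  if (any(is.na(labels))) stop("all training records need an sMCI/pMCI label")
  obj <- structure(list(variant = variant, config = config,
                        risk_map = risk_map, n_components = n_components,
                        svm_kernel = svm_kernel, cost = cost, seed = seed),
                   class = "progression_model")
  if (variant == "e2e") {
    vl <- if (!is.null(val))
      list(stacks = val$stacks, records = val$records,
           labels = val$records$label) else NULL
    obj$e2e <- train_e2e(stacks, records, labels, config,
                         use_nonimage = TRUE, val = vl)
    obj$n_train <- length(stacks)
    if (!is.null(vl))
      obj$val_accuracy <- max(obj$e2e$log$val_accuracy)
    return(obj)
  }
  if (variant %in% c("hybrid", "image_only")) {
    idx <- if (is.null(cnn_train_idx)) seq_along(stacks) else cnn_train_idx
    cfh <- config
    cfa <- config; cfa$seed <- config$seed + 101L
    ph <- pool_segment_group(stacks[idx], "hippocampus")
    pa <- pool_segment_group(stacks[idx], "ant_temporal")
    lab2 <- labels[idx][ph$subject_idx]
    obj$extractors <- list(
      hippocampus = train_extractor(ph$crops, lab2, cfh),
      ant_temporal = train_extractor(pa$crops, lab2, cfa))
    feats <- model_segment_features(obj, stacks)
    obj$pcas <- lapply(feats, fit_segment_pca, n_components = n_components)
  }
  fused <- model_fused_matrix(obj, stacks, records)
  obj$feature_names <- colnames(fused)
  obj$qtabs <- quantile_normalize_fit(fused)
  xq <- quantile_normalize_apply(fused, obj$qtabs)
  obj$svm <- fit_svm(xq, labels, kernel = svm_kernel, cost = cost,
                     seed = seed)
  obj$n_train <- length(stacks)
  obj$train_scores <- predict_svm_prob(obj$svm, xq)
  obj$train_labels <- labels
  if (!is.null(val)) {
    pv <- predict(obj, val, type = "prob")
    obj$val_accuracy <- mean((pv >= 0.5) ==
                               (as_label_index(val$records$label) == 2L))
  }
  obj
}

# per-segment feature matrices (list of 4: n x feature_dim)
model_segment_features <- function(object, stacks) {
  ex <- object$extractors
  grab <- function(seg, net, flip) {
    crops <- lapply(stacks, function(s)
      if (flip) flip_lr(s$crops[[seg]]) else s$crops[[seg]])
    t(extract_features(ex[[net]], crops))
  }
  list(hippocampus_L = grab("hippocampus_L", "hippocampus", TRUE),
       hippocampus_R = grab("hippocampus_R", "hippocampus", FALSE),
       ant_temporal_L = grab("ant_temporal_L", "ant_temporal", TRUE),
       ant_temporal_R = grab("ant_temporal_R", "ant_temporal", FALSE))
}

# raw (pre-normalization) fused matrix for any subject set
model_fused_matrix <- function(object, stacks, records) {
  segs <- c("hippocampus_L", "hippocampus_R", "ant_temporal_L",
            "ant_temporal_R")
  n <- nrow(records)
  if (object$variant %in% c("hybrid", "image_only")) {
    feats <- model_segment_features(object, stacks)
    proj <- lapply(segs, function(s) {
      if (is.null(object$pcas))
        stop("internal error: PCA projections not fitted")
      project_segment_pca(object$pcas[[s]], feats[[s]])
    })
    names(proj) <- segs
  }
  rows <- lapply(seq_len(n), function(i) {
    rec <- records[i, , drop = FALSE]
    if (object$variant == "nonimage") {
      c(mmse = rec$mmse, faq = rec$faq, cdr_sb = rec$cdr_sb, adas = rec$adas,
        age = rec$age,
        apoe_risk = encode_apoe(rec$apoe, object$risk_map))
    } else {
      ip <- lapply(proj, function(m) m[i, ])
      fv <- assemble_fused(ip, rec, object$risk_map)
      if (object$variant == "image_only")
        fv[seq_len(4 * object$n_components)]
      else fv
    }
  })
  do.call(rbind, rows)
}

#' @export
print.progression_model <- function(x, ...) {
  cat("<progression_model> variant '", x$variant, "', trained on ",
      x$n_train, " subjects\n", sep = "")
  if (!is.null(x$svm))
    cat("  fused features: ", length(x$feature_names), " [",
        paste(x$feature_names, collapse = ", "), "]; ", x$svm_kernel,
        " SVM (C = ", x$cost, ")\n", sep = "")
  if (x$variant == "e2e")
    cat("  end-to-end CNN with bilinear non-image fusion; selected epoch ",
        x$e2e$log$selected_epoch, "\n", sep = "")
  if (!is.null(x$val_accuracy))
    cat("  validation accuracy: ", round(x$val_accuracy, 3), "\n", sep = "")
  invisible(x)
}

#' @export
summary.progression_model <- function(object, ...) {
  print(object)
  if (!is.null(object$pcas)) {
    ev <- vapply(object$pcas, function(p) p$explained_variance[1], 1)
    cat("  per-segment PC1 explained variance:\n")
    print(round(ev, 3))
  }
  if (!is.null(object$train_scores)) {
    m <- compute_metrics(object$train_scores, object$train_labels)
    cat("  training (resubstitution) metrics: ")
    print(m)
  }
  if (!is.null(object$extractors)) {
    for (nm in names(object$extractors)) {
      cat("  extractor '", nm, "': ", sep = "")
      lg <- object$extractors[[nm]]$log
      cat("loss ", signif(lg$epoch_loss[1], 4), " -> ",
          signif(lg$epoch_loss[length(lg$epoch_loss)], 4), " over ",
          length(lg$epoch_loss), " epochs\n", sep = "")
    }
  }
  invisible(object)
}

#' Predict progression for new subjects
#'
#' @param object a fitted `progression_model`.
#' @param newdata list with `stacks` (list of [segment_stack()]s, not needed
#'   for the `nonimage` variant) and `records` (subject data.frame).
#' @param type `"prob"` (pMCI probability), `"class"` (0.5-threshold label),
#'   or `"fused"` (the quantile-normalized fused feature matrix).
#' @param ... unused.
#' @return per-subject probabilities, factor labels, or a feature matrix.
#' @export
predict.progression_model <- function(object, newdata, type = c("prob",
                                                                "class",
                                                                "fused"),
                                      ...) {
  type <- match.arg(type)
  if (object$variant == "e2e") {
    pr <- e2e_predict(object$e2e, newdata$stacks, newdata$records)
    if (type == "fused") stop("variant 'e2e' has no fused feature matrix")
  } else {
    fused <- model_fused_matrix(object, newdata$stacks, newdata$records)
    xq <- quantile_normalize_apply(fused, object$qtabs)
    if (type == "fused") return(xq)
    pr <- predict_svm_prob(object$svm, xq)
  }
  if (type == "prob") pr
  else factor(ifelse(pr >= 0.5, "pMCI", "sMCI"), levels = c("sMCI", "pMCI"))
}

#' @export
#' @rdname predict.progression_model
#' @param ... unused.
coef.progression_model <- function(object, ...) {
  if (is.null(object$svm) || object$svm$kernel != "linear")
    return(NULL)
  svm_linear_weights(object$svm)
}

#' Plot the ROC curve of a progression model
#'
#' Draws the ROC curve for the given scores/labels (defaulting to the
#' training resubstitution scores) with the AUC in the legend.
#'
#' @param x a fitted `progression_model`.
#' @param scores,labels evaluation scores and labels; default training.
#' @param ... passed to [graphics::plot()].
#' @export
plot.progression_model <- function(x, scores = x$train_scores,
                                   labels = x$train_labels, ...) {
  if (is.null(scores)) stop("no scores to plot")
  m <- compute_metrics(scores, labels)
  graphics::plot(m$roc$fpr, m$roc$tpr, type = "l", lwd = 2,
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = sprintf("ROC (AUC = %.3f)", m$auc), ...)
  graphics::abline(0, 1, lty = 3, col = "grey50")
  invisible(m)
}
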