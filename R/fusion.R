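#' First-principal-component projection for a segment's features
#'
#' Reduces the per-segment image feature matrix to `n_components` dimensions
#' (default 1) by principal component analysis fitted on training data only.
#' The sign of each component is fixed so that its largest-magnitude loading
#' is positive, making projections reproducible across runs.
#'
#' @param x training feature matrix (n x p, rows are subjects).
#' @param n_components number of components (1-3).
#' @return a `segment_pca` with the centre, rotation and explained variance.
#' @export
fit_segment_pca <- function(x, n_components = 1L) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training samples")
  if (!all(is.finite(x))) stop("features must be finite")
  if (all(apply(x, 2, stats::var) < 1e-24)) stop("zero-variance input")
  pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  ev <- pr$sdev^2
  structure(list(center = pr$center, rotation = rot,
                 explained_variance = ev[seq_len(k)] / sum(ev)),
            class = "segment_pca")
}

#' @rdname fit_segment_pca
#' @param pca a fitted `segment_pca`.
#' @param newdata feature matrix (n x p) or single feature vector.
#' @return n x k matrix of projections (training mean projects to 0).
#' @export
project_segment_pca <- function(pca, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(as.matrix(newdata), 2, pca$center) %*% pca$rotation
}

#' Per-feature empirical quantile normalization
#'
#' `quantile_normalize_fit()` stores each feature's sorted training values;
#' `quantile_normalize_apply()` maps a value to its interpolated empirical
#' quantile in `[0, 1]` (linear between order statistics, clipped outside the
#' training range).  The map is monotone non-decreasing per feature, and the
#' same training tables are reused unchanged for validation and test data.
#'
#' @param x training matrix (n x p).
#' @return a `quantile_tables` object.
#' @export
quantile_normalize_fit <- function(x) {
  x <- as.matrix(x)
  tabs <- lapply(seq_len(ncol(x)), function(j) {
    v <- sort(x[, j])
    if (v[length(v)] - v[1] < 1e-12)
      stop("constant training feature (column ", j, ")")
    v
  })
  structure(list(tables = tabs, p = ncol(x)), class = "quantile_tables")
}

#' @rdname quantile_normalize_fit
#' @param tables a `quantile_tables` from `quantile_normalize_fit()`.
#' @param newdata matrix (n x p) or vector of length p.
#' @return matrix of normalized values in `[0, 1]`.
#' @export
quantile_normalize_apply <- function(newdata, tables) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != tables$p) stop("feature count mismatch")
  out <- newdata
  for (j in seq_len(tables$p)) {
    v <- tables$tables[[j]]
    n <- length(v)
    probs <- (seq_len(n) - 1) / (n - 1)
    # interpolate the empirical quantile function; average probs at ties
    out[, j] <- stats::approx(v, probs, xout = newdata[, j], rule = 2,
                              ties = mean)$y
  }
  out
}

#' Fused feature-vector order
#'
#' The fixed feature contract of the fusion classifier: four per-segment
#' image projections, four cognitive scores, age, and the APOE risk value —
#' 10 dimensions in the default (1 component per segment) configuration.
#' @export
FUSED_FEATURE_ORDER <- c("hippocampus_L", "hippocampus_R", "ant_temporal_L",
                         "ant_temporal_R", "mmse", "faq", "cdr_sb", "adas",
                         "age", "apoe_risk")

#' Assemble the fused feature vector of one subject
#'
#' Combines the four segment projections with the non-image information in
#' the fixed order `[hippo_L, hippo_R, antTemp_L, antTemp_R, MMSE, FAQ,
#' CDR-SB, ADAS, age, APOE risk]`.
#'
#' @param image_proj named numeric vector (or list) with the four segment
#'   projections (scalar per segment in the default configuration).
#' @param record one-row subject data.frame with `mmse, faq, cdr_sb, adas,
#'   age, apoe`.
#' @param risk_map APOE risk mapping.
#' @return named numeric vector of length 10 (or `4k + 6` for k components).
#' @export
assemble_fused <- function(image_proj, record, risk_map = apoe_risk_map()) {
  segs <- c("hippocampus_L", "hippocampus_R", "ant_temporal_L",
            "ant_temporal_R")
  miss <- setdiff(segs, names(image_proj))
  if (length(miss)) stop("missing segment projection(s): ",
                         paste(miss, collapse = ", "))
  for (f in c("mmse", "faq", "cdr_sb", "adas", "age", "apoe")) {
    v <- record[[f]]
    if (is.null(v) || length(v) != 1 || (f != "apoe" && !is.finite(v)))
      stop("missing or non-finite field: ", f)
  }
  img <- unlist(lapply(segs, function(s) as.numeric(image_proj[[s]])))
  k <- length(img) / 4
  nm <- if (k == 1) segs else
    as.vector(t(outer(segs, seq_len(k), paste, sep = ".pc")))
  stats::setNames(
    c(img, record$mmse, record$faq, record$cdr_sb, record$adas, record$age,
      encode_apoe(record$apoe, risk_map)),
    c(nm, "mmse", "faq", "cdr_sb", "adas", "age", "apoe_risk"))
}

#' Fit the fusion support-vector classifier
#'
#' Linear-kernel (default) support-vector machine with probability
#' calibration, fitted on quantile-normalized fused features.  An RBF kernel
#' is available as a configuration switch for comparison.  Deterministic
#' given `seed` (the probability calibration involves an internal
#' cross-validation).
#'
#' @param x fused training matrix (n x p), already quantile-normalized.
#' @param labels sMCI/pMCI labels.
#' @param kernel `"linear"` or `"rbf"`.
#' @param cost SVM regularization constant C.
#' @param seed RNG seed for the probability-calibration shuffle.
#' @return a `fusion_svm` object.
#' @export
fit_svm <- function(x, labels, kernel = c("linear", "rbf"), cost = 1,
                    seed = 1L) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- factor(as_label_index(labels), levels = c(1, 2),
              labels = c("sMCI", "pMCI"))
  if (nlevels(droplevels(y)) < 2) stop("training data contains a single class")
  fit <- withr_seed(seed, {
    e1071::svm(x, y, kernel = if (kernel == "linear") "linear" else "radial",
               cost = cost, probability = TRUE, scale = FALSE)
  })
  structure(list(fit = fit, kernel = kernel, cost = cost,
                 feature_names = colnames(x), p = ncol(x)),
            class = "fusion_svm")
}

#' @rdname fit_svm
#' @param object a `fusion_svm`.
#' @param newdata matrix or vector of fused (normalized) features.
#' @return numeric vector of pMCI probabilities in `[0, 1]`.
#' @export
predict_svm_prob <- function(object, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p) stop("feature-contract mismatch: expected ",
                                      object$p, " features")
  pr <- stats::predict(object$fit, newdata, probability = TRUE)
  unname(attr(pr, "probabilities")[, "pMCI"])
}

# primal weights of a linear fusion SVM
svm_linear_weights <- function(object) {
  if (object$kernel != "linear") return(NULL)
  w <- crossprod(object$fit$coefs, object$fit$SV)
  stats::setNames(as.numeric(w), object$feature_names)
}

#' Ensemble prediction at a fixed threshold
#'
#' Averages the pMCI probabilities of several fused-feature models (e.g. the
#' 10 fold models of the repeated cross-validation) and thresholds the mean
#' at 0.5; a score exactly at the threshold is assigned to pMCI.
#'
#' @param models list of objects with a `predict_prob(model, newdata)`
#'   contract — either `fusion_svm`s (given normalized features) or fitted
#'   [progression_model()]s (given new subject data).
#' @param newdata input accepted by every member model.
#' @param threshold decision threshold (default 0.5).
#' @return list with `score` (mean probability per subject) and `class`
#'   (factor sMCI/pMCI).
#' @export
predict_ensemble <- function(models, newdata, threshold = 0.5) {
  if (length(models) == 0) stop("need at least one model")
  probs <- lapply(models, function(m) {
    if (inherits(m, "fusion_svm")) predict_svm_prob(m, newdata)
    else if (inherits(m, "progression_model"))
      predict(m, newdata, type = "prob")
    else stop("unsupported model type in ensemble")
  })
  n <- unique(vapply(probs, length, 1L))
  if (length(n) != 1) stop("ensemble members disagree on the subject count")
  score <- rowMeans(do.call(cbind, probs))
  list(score = score,
       class = factor(ifelse(score >= threshold, "pMCI", "sMCI"),
                      levels = c("sMCI", "pMCI")))
}
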