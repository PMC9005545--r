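#' End-to-end fusion model
#'
#' The end-to-end comparator: two feature-extraction backbones (hippocampus
#' and anterior temporal) run in parallel; each subject's left crop is
#' mirrored and its features averaged with the right crop's.  The two
#' per-group feature vectors are concatenated; the non-image information
#' (four cognitive scores, age, APOE risk) is embedded by a small MLP and
#' extended to the dimension of the concatenated image features, and the two
#' are combined by low-rank bilinear (Hadamard) fusion before the
#' classification layer.  Trained under the same mixed
#' classification/reconstruction loss as the hybrid extractors.  With
#' `use_nonimage = FALSE` the fusion branch is disabled (image-only
#' end-to-end model).
#'
#' @param config an [extractor_config()] shared by both backbones.
#' @param use_nonimage enable the bilinear non-image fusion branch.
#' @param embed_dim hidden width of the non-image embedding MLP.
#' @return an `e2e_model`.
#' @export
build_e2e <- function(config, use_nonimage = TRUE, embed_dim = 16L) {
  hip <- build_extractor(config)
  cfa <- config; cfa$seed <- config$seed + 101L
  ant <- build_extractor(cfa)
  fd2 <- 2L * config$feature_dim
  p <- list()
  withr_seed(config$seed + 55L, {
    if (use_nonimage) {
      e1 <- linear_init(6L, embed_dim)
      p[["emb1.W"]] <- e1$W; p[["emb1.b"]] <- e1$b
      e2 <- linear_init(embed_dim, fd2)
      # gated-fusion initialization: the extended non-image vector starts at
      # ~1, so the Hadamard fusion begins as an identity pass-through of the
      # image features and learns its modulation from there
      p[["emb2.W"]] <- e2$W; p[["emb2.b"]] <- e2$b + 1
    }
    hd <- linear_init(fd2, 2L)
    p[["fuse.W"]] <- hd$W; p[["fuse.b"]] <- hd$b
  })
  structure(list(hip = hip, ant = ant, fuse = p, config = config,
                 use_nonimage = use_nonimage, embed_dim = embed_dim,
                 log = NULL),
            class = "e2e_model")
}

#' @export
print.e2e_model <- function(x, ...) {
  cat("<e2e_model> two backbones (feature dim ", x$config$feature_dim,
      "), non-image fusion: ", x$use_nonimage, "\n", sep = "")
  invisible(x)
}

# subjects -> per-backbone input batches: for each subject the flipped left
# and the right crop of the group, stacked (2N samples, pairs adjacent)
e2e_group_batch <- function(stacks, group, input_size, aug = NULL) {
  N <- length(stacks)
  x <- array(0, c(rep(input_size, 3), 2L * N, 1L))
  ln <- paste0(group, "_L"); rn <- paste0(group, "_R")
  take <- if (is.null(aug)) function(cr) center_crop(cr, input_size)
          else function(cr) augment(cr, aug)
  for (i in seq_len(N)) {
    x[, , , 2 * i - 1, 1] <- take(flip_lr(stacks[[i]]$crops[[ln]]))
    x[, , , 2 * i, 1] <- take(stacks[[i]]$crops[[rn]])
  }
  x
}

# non-image matrix (6 x N): mmse, faq, cdr_sb, adas, age, apoe risk.
# Scores are brought to comparable scale by fixed nominal ranges.
e2e_nonimage_matrix <- function(records, risk_map = apoe_risk_map()) {
  t(cbind(records$mmse / 30, records$faq / 30, records$cdr_sb / 18,
          records$adas / 70, records$age / 100,
          log(encode_apoe(records$apoe, risk_map)) / log(12)))
}

#' Forward pass of the end-to-end model
#'
#' @param model an `e2e_model`.
#' @param stacks list of [segment_stack()]s.
#' @param records subject data.frame rows matching `stacks` (ignored when the
#'   fusion branch is disabled).
#' @param train training mode (batch statistics, dropout).
#' @param aug optional [augmentation_spec()] applied to the crops (training).
#' @return list with `logits` (2 x N), per-branch reconstructions and caches.
#' @export
e2e_forward <- function(model, stacks, records = NULL, train = FALSE,
                        aug = NULL, need_recon = TRUE) {
  cf <- model$config
  N <- length(stacks)
  xh <- e2e_group_batch(stacks, "hippocampus", cf$input_size, aug)
  xa <- e2e_group_batch(stacks, "ant_temporal", cf$input_size, aug)
  fwh <- extractor_forward(model$hip$params, xh, cf, model$hip$arch, train,
                           need_recon = need_recon)
  fwa <- extractor_forward(model$ant$params, xa, cf, model$ant$arch, train,
                           need_recon = need_recon)
  # average the two hemisphere feature vectors per subject
  pair_mean <- function(f) (f[, seq(1, 2 * N, 2), drop = FALSE] +
                            f[, seq(2, 2 * N, 2), drop = FALSE]) / 2
  z <- rbind(pair_mean(fwh$features), pair_mean(fwa$features))  # 2fd x N
  p <- model$fuse
  cache <- list(N = N, xh = xh, xa = xa, fwh = fwh, fwa = fwa, z = z)
  if (model$use_nonimage) {
    if (is.null(records)) stop("non-image fusion requires subject records")
    xni <- e2e_nonimage_matrix(records)
    if (any(!is.finite(xni))) stop("missing non-image fields")
    e1 <- linear_fwd(xni, list(W = p[["emb1.W"]], b = p[["emb1.b"]]))
    r1 <- list(y = pmax(e1$y, 0), mask = e1$y > 0)
    e2 <- linear_fwd(r1$y, list(W = p[["emb2.W"]], b = p[["emb2.b"]]))
    fused <- z * e2$y
    cache <- c(cache, list(xni = xni, e1 = e1, r1 = r1, e2 = e2,
                           ext = e2$y))
  } else {
    fused <- z
  }
  hd <- linear_fwd(fused, list(W = p[["fuse.W"]], b = p[["fuse.b"]]))
  cache$fused <- fused
  list(logits = hd$y, recon_h = fwh$recon, recon_a = fwa$recon,
       cache = c(cache, list(head = hd$cache)),
       params_h = fwh$params, params_a = fwa$params)
}

# backward + one Adam step; returns updated model and loss breakdown
e2e_train_batch <- function(model, stacks, records, labels, states,
                            aug = NULL) {
  cf <- model$config
  fw <- e2e_forward(model, stacks, records, train = TRUE, aug = aug)
  model$hip$params <- fw$params_h
  model$ant$params <- fw$params_a
  N <- length(stacks)
  ce <- softmax_ce(fw$logits, as_label_index(labels))
  alpha <- if (cf$use_autoencoder) cf$alpha else 0
  lh <- if (cf$use_autoencoder) smooth_l1(fw$recon_h, fw$cache$xh) else NULL
  la <- if (cf$use_autoencoder) smooth_l1(fw$recon_a, fw$cache$xa) else NULL
  l_ae <- if (cf$use_autoencoder) (lh$loss + la$loss) / 2 else 0
  total <- (1 - alpha) * ce$loss + alpha * l_ae
  dlogits <- (1 - alpha) * ce$dlogits
  p <- model$fuse
  g <- list()
  hb <- linear_bwd(dlogits, list(W = p[["fuse.W"]], b = p[["fuse.b"]]),
                   fw$cache$head)
  g[["fuse.W"]] <- hb$dW; g[["fuse.b"]] <- hb$db
  dfused <- hb$dx
  if (model$use_nonimage) {
    dz <- dfused * fw$cache$ext
    dext <- dfused * fw$cache$z
    e2b <- linear_bwd(dext, list(W = p[["emb2.W"]], b = p[["emb2.b"]]),
                      fw$cache$e2$cache)
    g[["emb2.W"]] <- e2b$dW; g[["emb2.b"]] <- e2b$db
    dr1 <- e2b$dx * fw$cache$r1$mask
    e1b <- linear_bwd(dr1, list(W = p[["emb1.W"]], b = p[["emb1.b"]]),
                      fw$cache$e1$cache)
    g[["emb1.W"]] <- e1b$dW; g[["emb1.b"]] <- e1b$db
  } else {
    dz <- dfused
  }
  fd <- cf$feature_dim
  # un-average: each hemisphere sample gets half the subject's gradient
  expand_pairs <- function(dzg) {
    out <- matrix(0, fd, 2 * N)
    out[, seq(1, 2 * N, 2)] <- dzg / 2
    out[, seq(2, 2 * N, 2)] <- dzg / 2
    out
  }
  dfh <- expand_pairs(dz[seq_len(fd), , drop = FALSE])
  dfa <- expand_pairs(dz[fd + seq_len(fd), , drop = FALSE])
  zl <- matrix(0, 2, 2 * N)
  drh <- if (cf$use_autoencoder) alpha / 2 * lh$grad else NULL
  dra <- if (cf$use_autoencoder) alpha / 2 * la$grad else NULL
  bwh <- extractor_backward(model$hip$params, cf, model$hip$arch,
                            fw$cache$fwh$cache, zl, drh, dfeatures = dfh)
  bwa <- extractor_backward(model$ant$params, cf, model$ant$arch,
                            fw$cache$fwa$cache, zl, dra, dfeatures = dfa)
  up <- adam_step(model$hip$params, bwh$grads, states$hip, lr = cf$lr)
  model$hip$params <- up$params; states$hip <- up$state
  up <- adam_step(model$ant$params, bwa$grads, states$ant, lr = cf$lr)
  model$ant$params <- up$params; states$ant <- up$state
  up <- adam_step(model$fuse, g, states$fuse, lr = cf$lr)
  model$fuse <- up$params; states$fuse <- up$state
  list(model = model, states = states,
       loss = list(total = total, l_class = ce$loss, l_ae = l_ae))
}

#' Train the end-to-end model
#'
#' Mini-batch Adam training under the mixed loss; after each epoch the
#' validation accuracy is evaluated and the best-validation epoch's
#' parameters are kept (the validation subset is the model-selection set of
#' the protocol).
#'
#' @param stacks,records,labels training subjects.
#' @param config an [extractor_config()].
#' @param use_nonimage enable the bilinear fusion branch.
#' @param val optional list(stacks, records, labels) used for epoch selection.
#' @return trained `e2e_model` with a training `log` (per-epoch loss and
#'   validation accuracy, and the selected epoch).
#' @export
train_e2e <- function(stacks, records, labels, config,
                      use_nonimage = TRUE, val = NULL) {
  labels <- as_label_index(labels)
  if (length(unique(labels)) < 2) stop("training data contains a single class")
  model <- build_e2e(config, use_nonimage = use_nonimage)
  cf <- model$config
  states <- list(hip = adam_init(model$hip$params),
                 ant = adam_init(model$ant$params),
                 fuse = adam_init(model$fuse))
  N <- length(stacks)
  bs <- max(2L, cf$batch_size %/% 2L)  # each subject = 4 crop passes
  epoch_loss <- val_acc <- numeric(cf$epochs)
  best <- list(acc = -Inf, model = model, epoch = 0L)
  withr_seed(cf$seed + 7L, {
    for (ep in seq_len(cf$epochs)) {
      ord <- sample.int(N)
      tot <- 0; nb <- 0
      aug <- augmentation_spec(out_size = cf$input_size)
      for (b0 in seq(1, N, by = bs)) {
        idx <- ord[b0:min(b0 + bs - 1, N)]
        st <- e2e_train_batch(model, stacks[idx], records[idx, , drop = FALSE],
                              labels[idx], states, aug = aug)
        model <- st$model; states <- st$states
        tot <- tot + st$loss$total; nb <- nb + 1
      }
      epoch_loss[ep] <- tot / nb
      model <- e2e_recalibrate(model, stacks)
      if (!is.null(val)) {
        pr <- e2e_predict(model, val$stacks, val$records)
        val_acc[ep] <- mean((pr >= 0.5) == (as_label_index(val$labels) == 2L))
        if (val_acc[ep] > best$acc)
          best <- list(acc = val_acc[ep], model = model, epoch = ep)
      }
    }
  })
  if (!is.null(val) && best$epoch > 0) model <- best$model
  model$log <- list(epoch_loss = epoch_loss, val_accuracy = val_acc,
                    selected_epoch = if (is.null(val)) cf$epochs else
                      best$epoch)
  model
}

# re-estimate both backbones' batch-norm running statistics on the
# (centre-cropped) training subjects; see bn_recalibrate
e2e_recalibrate <- function(model, stacks, batch_size = 16L) {
  cf <- model$config
  for (group in c("hippocampus", "ant_temporal")) {
    x <- e2e_group_batch(stacks, group, cf$input_size)
    n2 <- dim(x)[4]
    slot <- if (group == "hippocampus") "hip" else "ant"
    p <- model[[slot]]$params
    i <- 0L
    for (b0 in seq(1, n2, by = batch_size)) {
      idx <- b0:min(b0 + batch_size - 1, n2)
      i <- i + 1L
      fw <- extractor_forward(p, x[, , , idx, , drop = FALSE], cf,
                              model[[slot]]$arch, train = TRUE,
                              need_recon = FALSE, bn_momentum = 1 / i)
      p <- fw$params
    }
    model[[slot]]$params <- p
  }
  model
}

#' Predict pMCI probabilities with the end-to-end model
#'
#' @param model trained `e2e_model`.
#' @param stacks,records subjects to score.
#' @param batch_size subjects per forward batch (bounds memory).
#' @return numeric vector of pMCI probabilities.
#' @export
e2e_predict <- function(model, stacks, records = NULL, batch_size = 8L) {
  n <- length(stacks)
  out <- numeric(n)
  for (b0 in seq(1, n, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, n)
    fw <- e2e_forward(model, stacks[idx],
                      if (!is.null(records)) records[idx, , drop = FALSE],
                      train = FALSE, need_recon = FALSE)
    e <- exp(sweep(fw$logits, 2, apply(fw$logits, 2, max)))
    p <- sweep(e, 2, colSums(e), `/`)
    out[idx] <- p[2, ]
  }
  out
}
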