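#' Feature-extractor configuration
#'
#' Configuration of the per-segment 3D convolutional feature extractor: a
#' densely connected (DenseNet-style) backbone whose 2D operations are
#' replaced by 3D ones, a self-attention block between the last dense block
#' and the classification layer, and a five-layer auto-encoder decoder
#' reconstructing the input crop, trained under the mixed loss
#' `(1 - alpha) * L_class + alpha * L_AE`.
#'
#' `full_extractor_config()` is the full-scale architecture: dense block
#' layout (6, 12, 24, 16), growth rate 32, first convolution 3x3x3 with
#' stride 2 (smaller than stock DenseNet because the inputs are small brain
#' segments), a 1x1x1 transition to 128 channels before global average
#' pooling so the per-segment feature vector has 128 dimensions, and
#' 48x48x48 input crops.  `tiny_extractor_config()` is a two-block reduced
#' architecture for CPU-scale phantom experiments (32^3 segments, 24^3
#' crops).
#'
#' @param blocks integer vector of dense-block layer counts.
#' @param growth growth rate (channels added per dense layer).
#' @param stem_channels channels of the first convolution.
#' @param bottleneck_mult bottleneck width multiplier (1x1x1 convolution to
#'   `bottleneck_mult * growth` channels before each 3x3x3 convolution).
#' @param feature_dim length of the GAP feature vector.
#' @param use_self_attention,use_autoencoder ablation switches.
#' @param alpha mixed-loss weight of the auto-encoder term (default 0.8).
#' @param input_size cubic crop edge fed to the network.
#' @param decoder_base channels of the first decoder layer.
#' @param lr,epochs,batch_size Adam learning rate, epoch count, batch size.
#' @param dropout dropout rate on the pooled feature vector during training.
#' @param seed RNG seed for initialization and data order.
#' @return a list of class `extractor_config`.
#' @export
extractor_config <- function(blocks = c(6, 12, 24, 16), growth = 32,
                             stem_channels = 64, bottleneck_mult = 4,
                             feature_dim = 128, use_self_attention = TRUE,
                             use_autoencoder = TRUE, alpha = 0.8,
                             input_size = 48, decoder_base = 64,
                             lr = 1e-4, epochs = 10, batch_size = 8,
                             dropout = 0.1, seed = 1L) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (feature_dim < 1) stop("feature_dim must be >= 1")
  n_down <- 1L + (length(blocks) - 1L)
  if (input_size %% 2^n_down != 0)
    stop("input_size must be divisible by 2^", n_down)
  if (input_size / 2^n_down < 2)
    stop("input crop too small for ", length(blocks), " dense blocks")
  structure(list(blocks = as.integer(blocks), growth = growth,
                 stem_channels = stem_channels,
                 bottleneck_mult = bottleneck_mult, feature_dim = feature_dim,
                 use_self_attention = use_self_attention,
                 use_autoencoder = use_autoencoder, alpha = alpha,
                 input_size = as.integer(input_size),
                 decoder_base = decoder_base, lr = lr, epochs = epochs,
                 batch_size = batch_size, dropout = dropout,
                 seed = as.integer(seed)),
            class = "extractor_config")
}

#' @rdname extractor_config
#' @param ... overrides passed to [extractor_config()].
#' @export
full_extractor_config <- function(...) {
  extractor_config(...)
}

#' @rdname extractor_config
#' @export
tiny_extractor_config <- function(...) {
  args <- list(blocks = c(2, 2), growth = 6, stem_channels = 12,
               bottleneck_mult = 2, feature_dim = 16, input_size = 24,
               decoder_base = 8, lr = 1e-3, epochs = 2, batch_size = 16,
               dropout = 0.05)
  args[names(list(...))] <- list(...)
  do.call(extractor_config, args)
}

# architecture bookkeeping: channel counts and map sizes per stage
extractor_arch <- function(cf) {
  ch <- cf$stem_channels
  size <- cf$input_size %/% 2L
  stages <- list()
  for (i in seq_along(cf$blocks)) {
    cin_layers <- ch + cf$growth * (seq_len(cf$blocks[i]) - 1L)
    stages[[i]] <- list(cin = cin_layers, size = size)
    ch <- ch + cf$growth * cf$blocks[i]
    if (i < length(cf$blocks)) {
      stages[[i]]$trans_out <- ch %/% 2L
      ch <- ch %/% 2L
      size <- size %/% 2L
    }
  }
  map_size <- size
  n_up <- as.integer(round(log2(cf$input_size / map_size)))
  # five layers: plain convolutions at map resolution, then alternating
  # transposed convolutions and (1x1-convolved) nearest up-samplings, then a
  # 1x1 output convolution with sigmoid; widths halve layer by layer
  types <- c(rep("conv", max(0L, 4L - n_up)),
             rep(c("deconv", "up"), length.out = n_up), "out")
  dec <- list()
  chd <- cf$feature_dim
  for (m in seq_along(types)) {
    cout <- if (types[m] == "out") 1L else
      min(max(chd %/% 2L, 4L), cf$decoder_base)
    dec[[m]] <- list(type = types[m], cin = chd, cout = cout)
    chd <- cout
  }
  list(stages = stages, final_in = ch, map_size = map_size, decoder = dec)
}

#' Build a feature-extractor model
#'
#' Initializes all network parameters (He initialization, seeded by
#' `config$seed`).  A forward pass maps a batch of input crops to class
#' logits over (sMCI, pMCI), the GAP feature vector of length
#' `config$feature_dim`, and (when the auto-encoder branch is enabled) a
#' reconstruction of the input crop.
#'
#' @param config an [extractor_config()].
#' @return a `cnn_extractor` model object.
#' @export
build_extractor <- function(config) {
  cf <- config
  arch <- extractor_arch(cf)
  p <- list()
  withr_seed(cf$seed, {
    cv <- conv3d_init(3, 1, cf$stem_channels)
    p[["stem.conv.W"]] <- cv$W; p[["stem.conv.b"]] <- cv$b
    p <- c(p, bn_entries("stem.bn", cf$stem_channels))
    for (i in seq_along(cf$blocks)) {
      st <- arch$stages[[i]]
      for (j in seq_len(cf$blocks[i])) {
        pre <- sprintf("b%d.l%d", i, j)
        cin <- st$cin[j]
        bw <- cf$bottleneck_mult * cf$growth
        p <- c(p, bn_entries(paste0(pre, ".bn1"), cin))
        cv <- conv3d_init(1, cin, bw)
        p[[paste0(pre, ".conv1.W")]] <- cv$W
        p[[paste0(pre, ".conv1.b")]] <- cv$b
        p <- c(p, bn_entries(paste0(pre, ".bn2"), bw))
        cv <- conv3d_init(3, bw, cf$growth)
        p[[paste0(pre, ".conv3.W")]] <- cv$W
        p[[paste0(pre, ".conv3.b")]] <- cv$b
      }
      if (i < length(cf$blocks)) {
        cin <- st$cin[cf$blocks[i]] + cf$growth
        p <- c(p, bn_entries(sprintf("t%d.bn", i), cin))
        cv <- conv3d_init(1, cin, st$trans_out)
        p[[sprintf("t%d.conv.W", i)]] <- cv$W
        p[[sprintf("t%d.conv.b", i)]] <- cv$b
      }
    }
    p <- c(p, bn_entries("final.bn", arch$final_in))
    cv <- conv3d_init(1, arch$final_in, cf$feature_dim)
    p[["final.conv.W"]] <- cv$W; p[["final.conv.b"]] <- cv$b
    if (cf$use_self_attention) {
      sa <- sa_init(cf$feature_dim)
      p[["sa.Wf"]] <- sa$Wf; p[["sa.Wg"]] <- sa$Wg; p[["sa.Wh"]] <- sa$Wh
      p[["sa.gamma"]] <- sa$gamma
    }
    fc <- linear_init(cf$feature_dim, 2)
    p[["head.W"]] <- fc$W; p[["head.b"]] <- fc$b
    if (cf$use_autoencoder) {
      for (m in seq_along(arch$decoder)) {
        dl <- arch$decoder[[m]]
        cv <- conv3d_init(if (dl$type %in% c("out", "up")) 1 else 3,
                          dl$cin, dl$cout)
        p[[sprintf("dec.l%d.W", m)]] <- cv$W
        p[[sprintf("dec.l%d.b", m)]] <- cv$b
      }
    }
  })
  structure(list(params = p, config = cf, arch = arch, log = NULL),
            class = "cnn_extractor")
}

bn_entries <- function(pre, c) {
  stats::setNames(list(rep(1, c), rep(0, c), rep(0, c), rep(1, c)),
                  paste0(pre, c(".gamma", ".beta", ".rmean", ".rvar")))
}

#' @export
print.cnn_extractor <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1L))
  cat("<cnn_extractor> blocks (", paste(x$config$blocks, collapse = ", "),
      "), growth ", x$config$growth, ", feature dim ", x$config$feature_dim,
      ", SA ", x$config$use_self_attention, ", AE ", x$config$use_autoencoder,
      "; ", format(np, big.mark = ","), " parameters\n", sep = "")
  if (!is.null(x$log))
    cat("  trained ", length(x$log$epoch_loss), " epochs; loss ",
        signif(x$log$epoch_loss[1], 4), " -> ",
        signif(x$log$epoch_loss[length(x$log$epoch_loss)], 4), "\n", sep = "")
  invisible(x)
}

pc <- function(p, pre, k) list(W = p[[paste0(pre, ".W")]],
                               b = p[[paste0(pre, ".b")]], k = k)
pbn <- function(p, pre) list(gamma = p[[paste0(pre, ".gamma")]],
                             beta = p[[paste0(pre, ".beta")]],
                             rmean = p[[paste0(pre, ".rmean")]],
                             rvar = p[[paste0(pre, ".rvar")]])

# forward pass; returns logits, features, reconstruction, caches and params
# (with refreshed batch-norm running statistics when train = TRUE);
# need_recon = FALSE skips the decoder branch (cheaper evaluation passes)
extractor_forward <- function(p, x, cf, arch, train = FALSE,
                              need_recon = TRUE, bn_momentum = 0.1) {
  cache <- list()
  bn_do <- function(name, h) {
    r <- bn_fwd(h, pbn(p, name), train = train, momentum = bn_momentum)
    if (train) {
      p[[paste0(name, ".rmean")]] <<- r$par$rmean
      p[[paste0(name, ".rvar")]] <<- r$par$rvar
    }
    r
  }
  st <- conv3d_fwd(x, pc(p, "stem.conv", 3), stride = 2L, pad = 1L)
  bn0 <- bn_do("stem.bn", st$y)
  rl0 <- relu_fwd(bn0$y)
  h <- rl0$y
  cache$stem <- list(conv = st$cache, bn = bn0$cache, relu = rl0$cache)
  cache$blocks <- list()
  for (i in seq_along(cf$blocks)) {
    lc <- list()
    for (j in seq_len(cf$blocks[i])) {
      pre <- sprintf("b%d.l%d", i, j)
      a1 <- bn_do(paste0(pre, ".bn1"), h)
      r1 <- relu_fwd(a1$y)
      c1 <- conv3d_fwd(r1$y, pc(p, paste0(pre, ".conv1"), 1))
      a2 <- bn_do(paste0(pre, ".bn2"), c1$y)
      r2 <- relu_fwd(a2$y)
      c3 <- conv3d_fwd(r2$y, pc(p, paste0(pre, ".conv3"), 3), pad = 1L)
      lc[[j]] <- list(bn1 = a1$cache, relu1 = r1$cache, conv1 = c1$cache,
                      bn2 = a2$cache, relu2 = r2$cache, conv3 = c3$cache,
                      cin = dim(h)[5])
      h <- cat_ch(h, c3$y)
    }
    tc <- NULL
    if (i < length(cf$blocks)) {
      tb <- bn_do(sprintf("t%d.bn", i), h)
      tr <- relu_fwd(tb$y)
      tv <- conv3d_fwd(tr$y, pc(p, sprintf("t%d.conv", i), 1))
      pl <- avgpool2_fwd(tv$y)
      tc <- list(bn = tb$cache, relu = tr$cache, conv = tv$cache,
                 pool = pl$cache)
      h <- pl$y
    }
    cache$blocks[[i]] <- list(layers = lc, trans = tc)
  }
  fb <- bn_do("final.bn", h)
  fr <- relu_fwd(fb$y)
  fc_ <- conv3d_fwd(fr$y, pc(p, "final.conv", 1))
  fmap <- fc_$y
  cache$final <- list(bn = fb$cache, relu = fr$cache, conv = fc_$cache)
  if (cf$use_self_attention) {
    sa <- sa_fwd(fmap, list(Wf = p[["sa.Wf"]], Wg = p[["sa.Wg"]],
                            Wh = p[["sa.Wh"]], gamma = p[["sa.gamma"]]))
    fmap <- sa$y
    cache$sa <- sa$cache
  }
  gp <- gap_fwd(fmap)
  feats <- gp$y
  dp <- dropout_fwd(feats, cf$dropout, train)
  hd <- linear_fwd(dp$y, list(W = p[["head.W"]], b = p[["head.b"]]))
  cache$gap <- gp$cache
  cache$dropout <- dp$cache
  cache$head <- hd$cache
  recon <- NULL
  if (cf$use_autoencoder && need_recon) {
    cache$dec <- list()
    hdec <- fmap
    for (m in seq_along(arch$decoder)) {
      dl <- arch$decoder[[m]]
      cstep <- list(type = dl$type)
      if (dl$type == "deconv") {
        zu <- zero_up2_fwd(hdec); cstep$up <- zu$cache; hdec <- zu$y
      } else if (dl$type == "up") {
        uu <- upsample2_fwd(hdec); cstep$up <- uu$cache; hdec <- uu$y
      }
      kk <- if (dl$type %in% c("out", "up")) 1 else 3
      cv <- conv3d_fwd(hdec, pc(p, sprintf("dec.l%d", m), kk),
                       pad = if (kk == 3) 1L else 0L)
      cstep$conv <- cv$cache
      hdec <- cv$y
      if (dl$type == "out") {
        sg <- sigmoid_fwd(hdec); cstep$sig <- sg$cache; hdec <- sg$y
      } else {
        rl <- relu_fwd(hdec); cstep$relu <- rl$cache; hdec <- rl$y
      }
      cache$dec[[m]] <- cstep
    }
    recon <- hdec
  }
  list(logits = hd$y, features = feats, recon = recon, cache = cache,
       params = p)
}

# backward pass; dlogits (2 x N), drecon (same shape as recon or NULL),
# dfeatures: optional extra gradient on the (pre-dropout) GAP features,
# used by the end-to-end fusion model
extractor_backward <- function(p, cf, arch, cache, dlogits, drecon = NULL,
                               dfeatures = NULL) {
  g <- list()
  # head
  hb <- linear_bwd(dlogits, list(W = p[["head.W"]], b = p[["head.b"]]),
                   cache$head)
  g[["head.W"]] <- hb$dW; g[["head.b"]] <- hb$db
  dfeat <- dropout_bwd(hb$dx, cache$dropout)
  if (!is.null(dfeatures)) dfeat <- dfeat + dfeatures
  dmap <- gap_bwd(dfeat, cache$gap)
  # decoder path adds gradient at the pre-GAP map
  if (cf$use_autoencoder && !is.null(drecon)) {
    dh <- drecon
    for (m in rev(seq_along(arch$decoder))) {
      cs <- cache$dec[[m]]
      dh <- if (cs$type == "out") sigmoid_bwd(dh, cs$sig)
            else relu_bwd(dh, cs$relu)
      cb <- conv3d_bwd(dh, pc(p, sprintf("dec.l%d", m),
                              if (cs$type %in% c("out", "up")) 1 else 3),
                       cs$conv)
      g[[sprintf("dec.l%d.W", m)]] <- cb$dW
      g[[sprintf("dec.l%d.b", m)]] <- cb$db
      dh <- cb$dx
      if (cs$type == "deconv") dh <- zero_up2_bwd(dh, cs$up)
      if (cs$type == "up") dh <- upsample2_bwd(dh, cs$up)
    }
    dmap <- dmap + dh
  }
  if (cf$use_self_attention) {
    sb <- sa_bwd(dmap, list(Wf = p[["sa.Wf"]], Wg = p[["sa.Wg"]],
                            Wh = p[["sa.Wh"]], gamma = p[["sa.gamma"]]),
                 cache$sa)
    g[["sa.Wf"]] <- sb$dWf; g[["sa.Wg"]] <- sb$dWg; g[["sa.Wh"]] <- sb$dWh
    g[["sa.gamma"]] <- sb$dgamma
    dmap <- sb$dx
  }
  cb <- conv3d_bwd(dmap, pc(p, "final.conv", 1), cache$final$conv)
  g[["final.conv.W"]] <- cb$dW; g[["final.conv.b"]] <- cb$db
  dh <- relu_bwd(cb$dx, cache$final$relu)
  bb <- bn_bwd(dh, pbn(p, "final.bn"), cache$final$bn)
  g[["final.bn.gamma"]] <- bb$dgamma; g[["final.bn.beta"]] <- bb$dbeta
  dh <- bb$dx
  for (i in rev(seq_along(cf$blocks))) {
    bc <- cache$blocks[[i]]
    if (!is.null(bc$trans)) {
      dh <- avgpool2_bwd(dh, bc$trans$pool)
      cb <- conv3d_bwd(dh, pc(p, sprintf("t%d.conv", i), 1), bc$trans$conv)
      g[[sprintf("t%d.conv.W", i)]] <- cb$dW
      g[[sprintf("t%d.conv.b", i)]] <- cb$db
      dh <- relu_bwd(cb$dx, bc$trans$relu)
      bb <- bn_bwd(dh, pbn(p, sprintf("t%d.bn", i)), bc$trans$bn)
      g[[sprintf("t%d.bn.gamma", i)]] <- bb$dgamma
      g[[sprintf("t%d.bn.beta", i)]] <- bb$dbeta
      dh <- bb$dx
    }
    for (j in rev(seq_len(cf$blocks[i]))) {
      lc <- bc$layers[[j]]
      pre <- sprintf("b%d.l%d", i, j)
      cin <- lc$cin
      nch <- dim(dh)[5]
      dg_new <- dh[, , , , (cin + 1):nch, drop = FALSE]
      dh <- dh[, , , , seq_len(cin), drop = FALSE]
      cb <- conv3d_bwd(dg_new, pc(p, paste0(pre, ".conv3"), 3), lc$conv3)
      g[[paste0(pre, ".conv3.W")]] <- cb$dW
      g[[paste0(pre, ".conv3.b")]] <- cb$db
      dr <- relu_bwd(cb$dx, lc$relu2)
      bb <- bn_bwd(dr, pbn(p, paste0(pre, ".bn2")), lc$bn2)
      g[[paste0(pre, ".bn2.gamma")]] <- bb$dgamma
      g[[paste0(pre, ".bn2.beta")]] <- bb$dbeta
      cb <- conv3d_bwd(bb$dx, pc(p, paste0(pre, ".conv1"), 1), lc$conv1)
      g[[paste0(pre, ".conv1.W")]] <- cb$dW
      g[[paste0(pre, ".conv1.b")]] <- cb$db
      dr <- relu_bwd(cb$dx, lc$relu1)
      bb <- bn_bwd(dr, pbn(p, paste0(pre, ".bn1")), lc$bn1)
      g[[paste0(pre, ".bn1.gamma")]] <- bb$dgamma
      g[[paste0(pre, ".bn1.beta")]] <- bb$dbeta
      dh <- dh + bb$dx
    }
  }
  dh <- relu_bwd(dh, cache$stem$relu)
  bb <- bn_bwd(dh, pbn(p, "stem.bn"), cache$stem$bn)
  g[["stem.bn.gamma"]] <- bb$dgamma; g[["stem.bn.beta"]] <- bb$dbeta
  cb <- conv3d_bwd(bb$dx, pc(p, "stem.conv", 3), cache$stem$conv)
  g[["stem.conv.W"]] <- cb$dW; g[["stem.conv.b"]] <- cb$db
  list(grads = g, dx = cb$dx)
}

cat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1:4], da[5] + db[5]))
  out[, , , , seq_len(da[5])] <- a
  out[, , , , da[5] + seq_len(db[5])] <- b
  out
}

#' Mixed classification / reconstruction loss
#'
#' The training objective of the feature extractor:
#' `total = (1 - alpha) * l_class + alpha * l_ae`, where `l_class` is the
#' mean cross-entropy of the class logits and `l_ae` the mean smooth-L1
#' (transition point 1) reconstruction error of the auto-encoder branch.
#'
#' @param logits 2 x N matrix of class logits (sMCI, pMCI).
#' @param labels integer vector (1 = sMCI, 2 = pMCI) or factor/character.
#' @param reconstruction decoder output (any numeric array), or `NULL`.
#' @param target reconstruction target, same shape.
#' @param alpha weight in `[0, 1]`.
#' @return list with `l_class`, `l_ae`, `total`, and gradients `dlogits`,
#'   `drecon`.
#' @export
mixed_loss <- function(logits, labels, reconstruction = NULL, target = NULL,
                       alpha = 0.8) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  labels <- as_label_index(labels)
  ce <- softmax_ce(logits, labels)
  if (!is.null(reconstruction)) {
    sl <- smooth_l1(reconstruction, target)
    l_ae <- sl$loss
    drecon <- alpha * sl$grad
  } else {
    l_ae <- 0
    drecon <- NULL
  }
  list(l_class = ce$loss, l_ae = l_ae,
       total = (1 - alpha) * ce$loss + alpha * l_ae,
       dlogits = (1 - alpha) * ce$dlogits, drecon = drecon)
}

as_label_index <- function(labels) {
  if (is.numeric(labels)) return(as.integer(labels))
  lab <- tolower(as.character(labels))
  out <- ifelse(lab == "pmci", 2L, ifelse(lab == "smci", 1L, NA_integer_))
  if (any(is.na(out))) stop("labels must be sMCI/pMCI")
  out
}

#' Augmentation specification
#'
#' Ranges of the random training augmentation: a similarity transform with
#' rotations in ±2 degrees, scale factors 0.95-1.05 and translations of ±4
#' voxels about/along each axis, followed by a linear gray transform with
#' slope 0.95-1.05 and shift ±0.05 on the `[0, 1]` intensity scale; the
#' transformed image is centrally cropped (to 48^3 at full scale) to avoid
#' border effects.
#'
#' @param rotation_deg,scale_range,translation_vox geometric ranges.
#' @param gray_slope,gray_shift intensity transform ranges.
#' @param out_size output crop edge.
#' @return list of class `augmentation_spec`.
#' @export
augmentation_spec <- function(rotation_deg = 2.0, scale_range = c(0.95, 1.05),
                              translation_vox = 4.0,
                              gray_slope = c(0.95, 1.05), gray_shift = 0.05,
                              out_size = 48L) {
  structure(list(rotation_deg = rotation_deg, scale_range = scale_range,
                 translation_vox = translation_vox, gray_slope = gray_slope,
                 gray_shift = gray_shift, out_size = as.integer(out_size)),
            class = "augmentation_spec")
}

#' Randomly augment a segment crop
#'
#' Samples a similarity transform and gray transform uniformly within the
#' spec ranges (from the current RNG stream), applies them, takes the central
#' `out_size`^3 crop, and clips gray values back to `[0, 1]`.  With all
#' ranges collapsed to the identity the result is exactly the centre crop of
#' the input.
#'
#' @param crop 3D array in `[0, 1]` (e.g. 64^3 segment).
#' @param spec an [augmentation_spec()].
#' @return augmented array of side `spec$out_size`, with attribute
#'   `aug_params` recording the sampled parameters.
#' @export
augment <- function(crop, spec = augmentation_spec()) {
  d <- dim(crop)
  os <- spec$out_size
  if (any(os > d)) stop("output crop larger than input")
  rot <- stats::runif(3, -spec$rotation_deg, spec$rotation_deg)
  scl <- stats::runif(3, spec$scale_range[1], spec$scale_range[2])
  trn <- stats::runif(3, -spec$translation_vox, spec$translation_vox)
  slope <- stats::runif(1, spec$gray_slope[1], spec$gray_slope[2])
  shift <- stats::runif(1, -spec$gray_shift, spec$gray_shift)
  ident <- all(rot == 0) && all(scl == 1) && all(trn == 0)
  ctr_in <- (d - 1) / 2
  off <- (d - os) %/% 2
  if (ident) {
    out <- crop[off[1] + seq_len(os), off[2] + seq_len(os),
                off[3] + seq_len(os)]
  } else {
    A <- diag(scl) %*% rot_matrix_xyz(rot)
    # output voxel (0-based, within the centred crop window) -> input voxel
    g <- seq_len(os) - 1
    pts <- cbind(rep(g + off[1], os * os),
                 rep(rep(g + off[2], each = os), os),
                 rep(g + off[3], each = os * os))
    rel <- sweep(pts, 2, ctr_in)
    mapped <- t(A %*% t(rel)) + matrix(ctr_in + trn, nrow(rel), 3,
                                       byrow = TRUE)
    out <- array(interp_trilinear(crop, mapped), c(os, os, os))
  }
  out <- pmin(pmax(slope * out + shift, 0), 1)
  attr(out, "aug_params") <- list(rotation = rot, scale = scl,
                                  translation = trn, gray_slope = slope,
                                  gray_shift = shift)
  out
}

center_crop <- function(crop, os) {
  d <- dim(crop)
  if (all(d == os)) return(crop)
  off <- (d - os) %/% 2
  crop[off[1] + seq_len(os), off[2] + seq_len(os), off[3] + seq_len(os)]
}

#' Train a segment feature extractor
#'
#' Trains one extractor network on the pooled crops of a segment group
#' (left crops mirrored with [flip_lr()] before pooling with right crops),
#' with per-epoch random augmentation, Adam, and the mixed loss.  The
#' reconstruction target is the augmented input crop.  Deterministic given
#' `config$seed`.
#'
#' @param crops list (or array `(s, s, s, N)`) of segment crops in `[0, 1]`.
#' @param labels per-crop labels (sMCI/pMCI).
#' @param config an [extractor_config()].
#' @param aug an [augmentation_spec()]; defaults to the standard ranges with
#'   `out_size = config$input_size`.
#' @param model optionally, an already built [build_extractor()] model to
#'   continue training.
#' @param stop_class_below optional early-stop threshold: training ends once
#'   the epoch-mean classification loss falls below this value.
#' @return trained `cnn_extractor` with a `log` of per-epoch mean losses.
#' @export
train_extractor <- function(crops, labels, config = tiny_extractor_config(),
                            aug = NULL, model = NULL,
                            stop_class_below = NULL) {
  if (is.list(crops)) {
    N <- length(crops)
    if (N == 0) stop("empty dataset")
    crops <- array(unlist(crops), c(dim(crops[[1]]), N))
  }
  N <- dim(crops)[4]
  if (N == 0) stop("empty dataset")
  labels <- as_label_index(labels)
  if (length(unique(labels)) < 2) stop("training data contains a single class")
  if (is.null(aug)) aug <- augmentation_spec(out_size = config$input_size)
  if (!config$use_autoencoder) config$alpha <- 0
  if (is.null(model)) model <- build_extractor(config)
  cf <- model$config
  arch <- model$arch
  p <- model$params
  state <- adam_init(p)
  epoch_loss <- epoch_class <- epoch_ae <- numeric(cf$epochs)
  withr_seed(cf$seed + 1L, {
    for (ep in seq_len(cf$epochs)) {
      ord <- sample.int(N)
      tot <- cls <- ae <- 0
      nb <- 0
      for (b0 in seq(1, N, by = cf$batch_size)) {
        idx <- ord[b0:min(b0 + cf$batch_size - 1, N)]
        B <- length(idx)
        x <- array(0, c(rep(cf$input_size, 3), B, 1))
        for (ii in seq_len(B))
          x[, , , ii, 1] <- augment(crops[, , , idx[ii]], aug)
        fw <- extractor_forward(p, x, cf, arch, train = TRUE)
        p <- fw$params
        target <- if (cf$use_autoencoder) x else NULL
        ml <- mixed_loss(fw$logits, labels[idx], fw$recon, target, cf$alpha)
        bw <- extractor_backward(p, cf, arch, fw$cache, ml$dlogits, ml$drecon)
        up <- adam_step(p, bw$grads, state, lr = cf$lr)
        p <- up$params; state <- up$state
        tot <- tot + ml$total; cls <- cls + ml$l_class; ae <- ae + ml$l_ae
        nb <- nb + 1
      }
      epoch_loss[ep] <- tot / nb
      epoch_class[ep] <- cls / nb
      epoch_ae[ep] <- ae / nb
      if (!is.null(stop_class_below) && epoch_class[ep] < stop_class_below) {
        epoch_loss <- epoch_loss[seq_len(ep)]
        epoch_class <- epoch_class[seq_len(ep)]
        epoch_ae <- epoch_ae[seq_len(ep)]
        break
      }
    }
  })
  # recalibrate batch-norm running statistics: after a short schedule the
  # exponentially averaged statistics lag badly behind the trained network,
  # so re-estimate them as the exact average of batch statistics over the
  # (un-augmented) training crops
  p <- bn_recalibrate(p, cf, arch, crops, batch_size = cf$batch_size)
  model$params <- p
  model$log <- list(epoch_loss = epoch_loss, epoch_class = epoch_class,
                    epoch_ae = epoch_ae)
  model
}

# one pass over centre-cropped training data with cumulative-average momentum
bn_recalibrate <- function(p, cf, arch, crops, batch_size = 16L) {
  N <- dim(crops)[4]
  i <- 0L
  for (b0 in seq(1, N, by = batch_size)) {
    idx <- b0:min(b0 + batch_size - 1, N)
    i <- i + 1L
    x <- array(0, c(rep(cf$input_size, 3), length(idx), 1))
    for (ii in seq_along(idx))
      x[, , , ii, 1] <- center_crop(crops[, , , idx[ii]], cf$input_size)
    fw <- extractor_forward(p, x, cf, arch, train = TRUE,
                            need_recon = FALSE, bn_momentum = 1 / i)
    p <- fw$params
  }
  p
}

#' Extract GAP features from crops
#'
#' Deterministic evaluation-mode forward pass returning the feature vector
#' (global-average-pooled, length `feature_dim`) for each crop.  Crops larger
#' than the network input are centre-cropped first.
#'
#' @param model a `cnn_extractor`.
#' @param crops single 3D crop, list of crops, or array `(s, s, s, N)`.
#' @return matrix `feature_dim x N` (a vector for a single crop).
#' @export
extract_features <- function(model, crops) {
  cf <- model$config
  single <- FALSE
  if (is.array(crops) && length(dim(crops)) == 3) {
    crops <- list(crops); single <- TRUE
  }
  if (is.list(crops)) {
    N <- length(crops)
    arr <- array(0, c(rep(cf$input_size, 3), N, 1))
    for (i in seq_len(N))
      arr[, , , i, 1] <- center_crop(crops[[i]], cf$input_size)
  } else {
    N <- dim(crops)[4]
    arr <- array(0, c(rep(cf$input_size, 3), N, 1))
    for (i in seq_len(N))
      arr[, , , i, 1] <- center_crop(crops[, , , i], cf$input_size)
  }
  out <- matrix(0, cf$feature_dim, N)
  step <- 16L
  for (b0 in seq(1, N, by = step)) {
    idx <- b0:min(b0 + step - 1, N)
    fw <- extractor_forward(model$params, arr[, , , idx, , drop = FALSE],
                            cf, model$arch, train = FALSE,
                            need_recon = FALSE)
    out[, idx] <- fw$features
  }
  if (single) out[, 1] else out
}

#' SmoothGrad saliency of the pMCI logit
#'
#' Mean absolute input gradient of the pMCI logit over `n_samples`
#' evaluations with i.i.d. Gaussian input noise of standard deviation
#' `noise_sigma`; with `n_samples = 1` and `noise_sigma = 0` this is the
#' plain absolute gradient.
#'
#' @param model a `cnn_extractor`.
#' @param crop input crop (network input size, values in `[0, 1]`).
#' @param n_samples number of noisy evaluations (>= 1).
#' @param noise_sigma noise standard deviation.
#' @param seed RNG seed.
#' @return non-negative array of the crop's shape.
#' @export
smoothgrad <- function(model, crop, n_samples = 25L, noise_sigma = 0.1,
                       seed = 1L) {
  stopifnot(n_samples >= 1)
  cf <- model$config
  crop <- center_crop(crop, cf$input_size)
  acc <- array(0, dim(crop))
  withr_seed(seed, {
    for (s in seq_len(n_samples)) {
      noisy <- crop + if (noise_sigma > 0)
        array(stats::rnorm(length(crop), 0, noise_sigma), dim(crop)) else 0
      x <- array(noisy, c(dim(crop), 1, 1))
      fw <- extractor_forward(model$params, x, cf, model$arch, train = FALSE,
                              need_recon = FALSE)
      dlogits <- matrix(c(0, 1), 2, 1)
      bw <- extractor_backward(model$params, cf, model$arch, fw$cache,
                               dlogits, drecon = NULL)
      acc <- acc + abs(array(bw$dx, dim(crop)))
    }
  })
  acc / n_samples
}

#' Pool the crops of a segment group for training
#'
#' Training pools left and right segments of a group: left crops are
#' mirrored with [flip_lr()] so one network serves both hemispheres.
#'
#' @param stacks list of [segment_stack()]s.
#' @param group `"hippocampus"` or `"ant_temporal"`.
#' @return list with `crops` (length 2N list) and `subject_idx`.
#' @export
pool_segment_group <- function(stacks, group = c("hippocampus",
                                                 "ant_temporal")) {
  group <- match.arg(group)
  ln <- paste0(group, "_L"); rn <- paste0(group, "_R")
  crops <- c(lapply(stacks, function(s) flip_lr(s$crops[[ln]])),
             lapply(stacks, function(s) s$crops[[rn]]))
  list(crops = crops, subject_idx = rep(seq_along(stacks), 2))
}
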