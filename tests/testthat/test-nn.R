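# direct (loop-based) 3D convolution oracle, independent of the im2col path
conv3_oracle <- function(x, W, b, k, stride, pad) {
  d <- dim(x)
  C <- d[5]; N <- d[4]
  cout <- ncol(W)
  xp <- mciprog:::pad_spatial(x, pad)
  pd <- dim(xp)[1:3]
  od <- (pd - k) %/% stride + 1
  y <- array(0, c(od, N, cout))
  for (co in seq_len(cout)) for (n in seq_len(N))
    for (oz in seq_len(od[3])) for (oy in seq_len(od[2]))
      for (ox in seq_len(od[1])) {
        acc <- b[co]
        o <- 0
        for (dz in 0:(k - 1)) for (dy in 0:(k - 1)) for (dx in 0:(k - 1)) {
          o <- o + 1
          for (ci in seq_len(C))
            acc <- acc + xp[(ox - 1) * stride + dx + 1,
                            (oy - 1) * stride + dy + 1,
                            (oz - 1) * stride + dz + 1, n, ci] *
              W[(o - 1) * C + ci, co]
        }
        y[ox, oy, oz, n, co] <- acc
      }
  y
}

test_that("the convolution kernel agrees with a direct-loop oracle", {
  set.seed(1)
  for (cfg in list(list(k = 3, s = 1, p = 1, d = c(5, 4, 6), C = 2, N = 2,
                        co = 3),
                   list(k = 3, s = 2, p = 1, d = c(6, 6, 6), C = 1, N = 2,
                        co = 2))) {
    x <- array(rnorm(prod(cfg$d) * cfg$N * cfg$C), c(cfg$d, cfg$N, cfg$C))
    par <- mciprog:::conv3d_init(cfg$k, cfg$C, cfg$co)
    par$b <- rnorm(cfg$co)
    got <- mciprog:::conv3d_fwd(x, par, stride = cfg$s, pad = cfg$p)$y
    want <- conv3_oracle(x, par$W, par$b, cfg$k, cfg$s, cfg$p)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("analytic gradients of the full extractor match finite differences", {
  cf <- unit_config()
  model <- build_extractor(cf)
  # perturb biases away from 0 so no ReLU sits exactly at its kink
  set.seed(11)
  for (nm in grep("\\.b$", names(model$params), value = TRUE))
    model$params[[nm]] <- model$params[[nm]] +
      rnorm(length(model$params[[nm]]), 0, 0.05)
  set.seed(9)
  N <- 2
  x <- array(runif(16^3 * N), c(16, 16, 16, N, 1))
  labels <- c(1L, 2L)
  lossfn <- function(p) {
    fw <- mciprog:::extractor_forward(p, x, cf, model$arch, train = TRUE)
    mixed_loss(fw$logits, labels, fw$recon, x, cf$alpha)$total
  }
  fw <- mciprog:::extractor_forward(model$params, x, cf, model$arch,
                                    train = TRUE)
  ml <- mixed_loss(fw$logits, labels, fw$recon, x, cf$alpha)
  bw <- mciprog:::extractor_backward(model$params, cf, model$arch, fw$cache,
                                     ml$dlogits, ml$drecon)
  set.seed(21)
  groups <- c("stem.conv.W", "b1.l1.conv3.W", "b2.l1.conv1.W", "t1.conv.W",
              "b1.l1.bn1.gamma", "b2.l1.bn2.beta", "final.conv.W", "sa.Wf",
              "sa.gamma", "head.W", "dec.l1.W", "dec.l3.W", "dec.l5.b")
  h <- 1e-6
  for (nm in groups) {
    g <- bw$grads[[nm]]
    i <- sample(length(g), 1)
    p2 <- model$params; p2[[nm]][i] <- p2[[nm]][i] + h
    p3 <- model$params; p3[[nm]][i] <- p3[[nm]][i] - h
    num <- (lossfn(p2) - lossfn(p3)) / (2 * h)
    expect_equal(g[i], num, tolerance = 1e-4,
                 label = paste("grad", nm, "entry", i))
  }
})

test_that("the mixed loss follows its arithmetic exactly", {
  # near-zero classification loss and a smooth-L1 of exactly 1:
  # total = (1 - 0.8) * 0 + 0.8 * 1 = 0.8
  logits <- matrix(c(-30, 30), 2, 1)
  target <- array(0.2, c(3, 3, 3, 1, 1))
  recon <- target + 1.5            # |d| = 1.5 -> smooth L1 = 1.0
  ml <- mixed_loss(logits, 2L, recon, target, alpha = 0.8)
  expect_equal(ml$l_ae, 1.0, tolerance = 1e-12)
  expect_lt(ml$l_class, 1e-10)
  expect_equal(ml$total, 0.8, tolerance = 1e-9)

  # alpha = 0 reduces to the classification loss
  set.seed(2)
  lg <- matrix(rnorm(6), 2, 3)
  ml0 <- mixed_loss(lg, c(1L, 2L, 1L), recon, target, alpha = 0)
  expect_equal(ml0$total, ml0$l_class)

  # perfect prediction and reconstruction: total 0
  mlp <- mixed_loss(matrix(c(40, -40), 2, 1), 1L, target, target, 0.8)
  expect_lt(mlp$total, 1e-10)

  # the identity holds for arbitrary components
  for (a in c(0, 0.3, 0.8, 1)) {
    m <- mixed_loss(lg, c(2L, 1L, 2L), recon, target, a)
    expect_equal(m$total, (1 - a) * m$l_class + a * m$l_ae,
                 tolerance = 1e-12)
  }
  expect_error(mixed_loss(lg, c(1L, 1L, 2L), alpha = 1.2), "alpha")
})

test_that("augmentation samples stay inside the configured ranges", {
  spec <- augmentation_spec(out_size = 6L)
  set.seed(5)
  crop <- array(runif(10^3), c(10, 10, 10))
  pars <- replicate(1000, attr(augment(crop, spec), "aug_params"),
                    simplify = FALSE)
  rot <- t(vapply(pars, `[[`, numeric(3), "rotation"))
  scl <- t(vapply(pars, `[[`, numeric(3), "scale"))
  trn <- t(vapply(pars, `[[`, numeric(3), "translation"))
  slp <- vapply(pars, `[[`, 1, "gray_slope")
  sft <- vapply(pars, `[[`, 1, "gray_shift")
  expect_true(all(rot >= -2 & rot <= 2))
  expect_true(all(scl >= 0.95 & scl <= 1.05))
  expect_true(all(trn >= -4 & trn <= 4))
  expect_true(all(slp >= 0.95 & slp <= 1.05))
  expect_true(all(sft >= -0.05 & sft <= 0.05))
  # ranges actually explored
  expect_gt(max(rot) - min(rot), 3)
})

test_that("augmentation with collapsed ranges is the exact centre crop", {
  spec <- augmentation_spec(rotation_deg = 0, scale_range = c(1, 1),
                            translation_vox = 0, gray_slope = c(1, 1),
                            gray_shift = 0, out_size = 24L)
  set.seed(6)
  crop <- array(runif(32^3), c(32, 32, 32))
  out <- augment(crop, spec)
  expect_equal(dim(out), c(24, 24, 24))
  expect_equal(unclass(out)[, , ], crop[5:28, 5:28, 5:28],
               ignore_attr = TRUE)
})
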