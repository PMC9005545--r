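# ---------------------------------------------------------------------------
# Minimal 3D neural-network layer library.
#
# Feature maps are arrays (nx, ny, nz, N, C) — channels on the LAST axis, so
# that reshaping a spatial slice to a (voxels*N, C) matrix is a plain `dim<-`
# with no permutation.  Convolutions run as per-kernel-offset BLAS matrix
# products (shift-and-accumulate), which keeps memory at the size of the
# feature maps; every layer has a matched analytic backward pass (verified
# against numerical gradients in the test suite).  Linear features are (C, N)
# matrices.
# ---------------------------------------------------------------------------

pad_spatial <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1:3] + 2 * p, d[4], d[5]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ] <- x
  out
}

conv3d_init <- function(k, cin, cout) {
  list(W = matrix(stats::rnorm(k^3 * cin * cout, 0,
                               sqrt(2 / (k^3 * cin))), k^3 * cin, cout),
       b = numeric(cout), k = k)
}

# W row block for kernel offset o (1-based): rows (o-1)*C + 1:C.
conv3d_fwd <- function(x, par, stride = 1L, pad = 0L) {
  k <- par$k
  d <- dim(x)
  C <- d[5]; N <- d[4]
  cout <- ncol(par$W)
  if (k == 1L && stride == 1L) {
    X <- x; dim(X) <- c(prod(d[1:3]) * N, C)
    Y <- X %*% par$W
    Y <- Y + rep(par$b, each = nrow(Y))
    dim(Y) <- c(d[1:3], N, cout)
    return(list(y = Y, cache = list(xdim = d, stride = stride, pad = pad,
                                    odim = d[1:3], x = x)))
  }
  xpad <- pad_spatial(x, pad)
  pdim <- dim(xpad)[1:3]
  odim <- (pdim - k) %/% stride + 1L
  Y <- conv3_fwd_cpp(xpad, pdim, N, C, par$W, k, stride)
  Y <- Y + rep(par$b, each = nrow(Y))
  dim(Y) <- c(odim, N, cout)
  list(y = Y, cache = list(xdim = d, stride = stride, pad = pad, odim = odim,
                           pdim = pdim, x = x))
}

conv3d_bwd <- function(dy, par, cache) {
  k <- par$k
  d <- cache$xdim
  C <- d[5]; N <- d[4]
  cout <- ncol(par$W)
  V <- prod(cache$odim)
  dY <- dy; dim(dY) <- c(V * N, cout)
  db <- colSums(dY)
  if (k == 1L && cache$stride == 1L) {
    X <- cache$x; dim(X) <- c(V * N, C)
    dW <- crossprod(X, dY)
    dx <- tcrossprod(dY, par$W)
    dim(dx) <- d
    return(list(dx = dx, dW = dW, db = db))
  }
  xpad <- pad_spatial(cache$x, cache$pad)
  r <- conv3_bwd_cpp(xpad, cache$pdim, N, C, dY, par$W, k, cache$stride)
  dW <- r$dW
  dxpad <- r$dxpad
  dim(dxpad) <- c(cache$pdim, N, C)
  p <- cache$pad
  dx <- if (p > 0)
    dxpad[p + seq_len(d[1]), p + seq_len(d[2]), p + seq_len(d[3]), , ,
          drop = FALSE]
  else dxpad
  dim(dx) <- d
  list(dx = dx, dW = dW, db = db)
}

bn_init <- function(c) list(gamma = rep(1, c), beta = rep(0, c),
                            rmean = rep(0, c), rvar = rep(1, c))

bn_fwd <- function(x, par, train = TRUE, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  M <- x; dim(M) <- c(prod(d[1:4]), d[5])
  if (train) {
    mu <- colMeans(M)
    v <- colMeans(M^2) - mu^2
    par$rmean <- (1 - momentum) * par$rmean + momentum * mu
    par$rvar <- (1 - momentum) * par$rvar + momentum * v
  } else {
    mu <- par$rmean; v <- par$rvar
  }
  istd <- 1 / sqrt(v + eps)
  Xh <- sweep(sweep(M, 2, mu), 2, istd, `*`)
  Y <- sweep(sweep(Xh, 2, par$gamma, `*`), 2, par$beta, `+`)
  dim(Y) <- d
  list(y = Y, par = par,
       cache = list(Xh = Xh, istd = istd, d = d, train = train))
}

bn_bwd <- function(dy, par, cache) {
  d <- cache$d
  dY <- dy; dim(dY) <- c(prod(d[1:4]), d[5])
  dgamma <- colSums(dY * cache$Xh)
  dbeta <- colSums(dY)
  if (cache$train) {
    t1 <- sweep(dY, 2, colMeans(dY))
    t2 <- sweep(cache$Xh, 2, colMeans(dY * cache$Xh), `*`)
    dM <- sweep(t1 - t2, 2, par$gamma * cache$istd, `*`)
  } else {
    dM <- sweep(dY, 2, par$gamma * cache$istd, `*`)
  }
  dim(dM) <- d
  list(dx = dM, dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dy, cache) dy * cache

avgpool2_fwd <- function(x) {
  d <- dim(x)
  xs <- seq(1, d[1], 2); ys <- seq(1, d[2], 2); zs <- seq(1, d[3], 2)
  y <- array(0, c(d[1] %/% 2, d[2] %/% 2, d[3] %/% 2, d[4], d[5]))
  for (dz in 0:1) for (dy_ in 0:1) for (dx in 0:1)
    y <- y + x[xs + dx, ys + dy_, zs + dz, , , drop = FALSE]
  list(y = y / 8, cache = d)
}

avgpool2_bwd <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  xs <- seq(1, d[1], 2); ys <- seq(1, d[2], 2); zs <- seq(1, d[3], 2)
  g <- dy / 8
  for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1)
    dx[xs + dx_, ys + dy_, zs + dz, , ] <- g
  dx
}

upsample2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], 2 * d[3], d[4], d[5]))
  xs <- seq(1, 2 * d[1], 2); ys <- seq(1, 2 * d[2], 2); zs <- seq(1, 2 * d[3], 2)
  for (dz in 0:1) for (dy_ in 0:1) for (dx in 0:1)
    y[xs + dx, ys + dy_, zs + dz, , ] <- x
  list(y = y, cache = d)
}

upsample2_bwd <- function(dy, cache) {
  d <- cache
  dx <- array(0, d)
  xs <- seq(1, 2 * d[1], 2); ys <- seq(1, 2 * d[2], 2); zs <- seq(1, 2 * d[3], 2)
  for (dz in 0:1) for (dy_ in 0:1) for (dx_ in 0:1)
    dx <- dx + dy[xs + dx_, ys + dy_, zs + dz, , , drop = FALSE]
  dx
}

zero_up2_fwd <- function(x) {
  d <- dim(x)
  y <- array(0, c(2 * d[1], 2 * d[2], 2 * d[3], d[4], d[5]))
  y[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), seq(1, 2 * d[3], 2), , ] <- x
  list(y = y, cache = d)
}

zero_up2_bwd <- function(dy, cache) {
  d <- cache
  dy[seq(1, 2 * d[1], 2), seq(1, 2 * d[2], 2), seq(1, 2 * d[3], 2), , ,
     drop = FALSE]
}

# (nx,ny,nz,N,C) -> (C, N) feature matrix (spatial mean)
gap_fwd <- function(x) {
  d <- dim(x)
  V <- prod(d[1:3])
  M <- x; dim(M) <- c(V, d[4] * d[5])
  list(y = t(matrix(colMeans(M), d[4], d[5])), cache = d)
}

gap_bwd <- function(dy, cache) {
  d <- cache
  V <- prod(d[1:3])
  dx <- rep(as.vector(t(dy)) / V, each = V)
  dim(dx) <- d
  dx
}

linear_init <- function(cin, cout) {
  list(W = matrix(stats::rnorm(cin * cout, 0, sqrt(2 / cin)), cin, cout),
       b = numeric(cout))
}

linear_fwd <- function(x, par) {  # x: (Cin, N)
  list(y = crossprod(par$W, x) + par$b, cache = x)
}

linear_bwd <- function(dy, par, cache) {
  list(dx = par$W %*% dy, dW = cache %*% t(dy), db = rowSums(dy))
}

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- array(stats::runif(length(x)) >= rate, dim(x))
  list(y = x * keep / (1 - rate), cache = list(keep = keep, rate = rate))
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) return(dy)
  dy * cache$keep / (1 - cache$rate)
}

sigmoid_fwd <- function(x) {
  y <- 1 / (1 + exp(-x))
  list(y = y, cache = y)
}
sigmoid_bwd <- function(dy, cache) dy * cache * (1 - cache)

# --- self-attention (non-local) block on a (nx,ny,nz,N,C) map ---------------
sa_init <- function(C) {
  ci <- max(C %/% 8L, 1L)
  list(Wf = matrix(stats::rnorm(C * ci, 0, sqrt(1 / C)), C, ci),
       Wg = matrix(stats::rnorm(C * ci, 0, sqrt(1 / C)), C, ci),
       Wh = matrix(stats::rnorm(C * C, 0, sqrt(1 / C)), C, C),
       gamma = 0)
}

sa_fwd <- function(x, par) {
  d <- dim(x)
  V <- prod(d[1:3]); N <- d[4]; C <- d[5]
  scl <- 1 / sqrt(ncol(par$Wf))
  y <- x
  caches <- vector("list", N)
  for (n in seq_len(N)) {
    X <- x[, , , n, , drop = FALSE]; dim(X) <- c(V, C)
    f <- X %*% par$Wf; g <- X %*% par$Wg; h <- X %*% par$Wh
    L <- scl * tcrossprod(f, g)         # V x V
    L <- L - apply(L, 1, max)
    A <- exp(L); A <- A / rowSums(A)
    o <- A %*% h
    yn <- X + par$gamma * o
    dim(yn) <- c(d[1:3], 1, C)
    y[, , , n, ] <- yn
    caches[[n]] <- list(X = X, f = f, g = g, h = h, A = A, o = o)
  }
  list(y = y, cache = list(d = d, scl = scl, caches = caches))
}

sa_bwd <- function(dy, par, cache) {
  d <- cache$d
  V <- prod(d[1:3]); N <- d[4]; C <- d[5]
  scl <- cache$scl
  dx <- dy
  dWf <- par$Wf * 0; dWg <- par$Wg * 0; dWh <- par$Wh * 0; dgamma <- 0
  for (n in seq_len(N)) {
    cc <- cache$caches[[n]]
    dY <- dy[, , , n, , drop = FALSE]; dim(dY) <- c(V, C)
    dgamma <- dgamma + sum(dY * cc$o)
    dO <- par$gamma * dY
    dA <- tcrossprod(dO, cc$h)          # dO %*% t(h): V x V
    dh <- crossprod(cc$A, dO)
    dL <- cc$A * (dA - rowSums(dA * cc$A))
    df <- scl * dL %*% cc$g
    dg <- scl * crossprod(dL, cc$f)
    dX <- dY + df %*% t(par$Wf) + dg %*% t(par$Wg) + dh %*% t(par$Wh)
    dWf <- dWf + crossprod(cc$X, df)
    dWg <- dWg + crossprod(cc$X, dg)
    dWh <- dWh + crossprod(cc$X, dh)
    dim(dX) <- c(d[1:3], 1, C)
    dx[, , , n, ] <- dX
  }
  list(dx = dx, dWf = dWf, dWg = dWg, dWh = dWh, dgamma = dgamma)
}

# --- losses -----------------------------------------------------------------

# logits: (2, N); labels: integer 1/2.  Mean cross-entropy and its gradient.
softmax_ce <- function(logits, labels) {
  N <- ncol(logits)
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  p <- sweep(e, 2, colSums(e), `/`)
  idx <- cbind(labels, seq_len(N))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dlogits <- p
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / N, prob = p)
}

# mean smooth-L1 (Huber, transition point 1) and gradient
smooth_l1 <- function(pred, target) {
  d <- pred - target
  a <- abs(d)
  quad <- a < 1
  loss <- sum(ifelse(quad, 0.5 * d^2, a - 0.5)) / length(d)
  grad <- ifelse(quad, d, sign(d)) / length(d)
  list(loss = loss, grad = grad)
}

# --- Adam over a flat named list of arrays ----------------------------------
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
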